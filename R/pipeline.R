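# Diagnosis pipeline: detection (MI vs HC), localization (single multiclass
# head, or a group of one-vs-rest binary heads whose argmax positive
# probability decides), inter-patient cross-validation, and architecture
# transfer (frozen branches + learned genomes, LSE retrained on the target).

.localization_classes <- c("HC", "AMI", "ASMI", "ALMI", "IMI", "ILMI")

#' Pipeline configuration
#'
#' Scales for the search + head-training pipeline. The GA defaults mirror
#' [ga_config()]; `ga_pop`, `ga_generations` and the LSE epochs are the
#' knobs that trade search quality for runtime on small synthetic studies.
#'
#' @param ga a [ga_config()]; its `seed` drives the whole run.
#' @param lse_epochs Adam epochs for every LSE training.
#' @param lse_lr,lse_batch LSE optimizer settings.
#' @param test_fraction patient fraction held out as the final test split
#'   when a function needs to carve one internally.
#' @param val_fraction patient fraction the fitness evaluator holds out.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(ga = ga_config(), lse_epochs = 30L, lse_lr = 1e-2,
                            lse_batch = 32L, test_fraction = 0.25,
                            val_fraction = 0.2) {
  structure(
    list(ga = ga, lse_epochs = as.integer(lse_epochs), lse_lr = lse_lr,
         lse_batch = as.integer(lse_batch), test_fraction = test_fraction,
         val_fraction = val_fraction),
    class = "pipeline_config"
  )
}

.lse_cfg_from <- function(config, class_mode, positive_class = NULL,
                          seed = config$ga$seed) {
  lse_config(epochs = config$lse_epochs, lr = config$lse_lr,
             batch = config$lse_batch, seed = seed, class_mode = class_mode,
             positive_class = positive_class)
}

#' Collapse subcategory labels to the detection task
#'
#' Maps every MI subcategory to `"MI"` and leaves `"HC"` untouched.
#'
#' @param labels character or factor labels.
#' @return Character vector over `{MI, HC}`.
#' @export
collapse_to_detection <- function(labels) {
  labels <- as.character(labels)
  ifelse(labels == "HC", "HC", "MI")
}

#' MI detection: evolve one genome and evaluate it
#'
#' Collapses all MI subcategories to a single positive class, carves a
#' patient-wise train/test split from the bank, runs the GA (whose fitness
#' trains binary LSE heads on a further patient-held-out validation split of
#' the training beats), retrains the winning genome's LSE on the full
#' training fold, and scores it on the held-out test fold. MI is the
#' positive class.
#'
#' @param bank a `feature_bank` whose labels include `"HC"`.
#' @param config a [pipeline_config()].
#' @param train_idx,test_idx optional explicit beat splits (patient-disjoint);
#'   by default a stratified patient holdout of `config$test_fraction`.
#' @return List with `genome`, `model`, `report` (an `evaluation_report`),
#'   and `ga` (the [evolve()] result).
#' @export
run_detection <- function(bank, config = pipeline_config(),
                          train_idx = NULL, test_idx = NULL) {
  labels <- collapse_to_detection(bank$labels)
  if (!any(labels == "HC")) stop("detection requires HC beats in the bank")
  det_bank <- bank
  det_bank$labels <- factor(labels, levels = c("MI", "HC"))
  det_bank$class_set <- c("MI", "HC")
  if (is.null(train_idx) || is.null(test_idx)) {
    set.seed(config$ga$seed)
    split <- .patient_holdout(bank$patient_id, labels, config$test_fraction)
    train_idx <- split$train
    test_idx <- split$test
  }
  lse_cfg <- .lse_cfg_from(config, "binary", positive_class = "MI")
  evaluator <- lse_evaluator(det_bank, lse_cfg, idx = train_idx,
                             val_fraction = config$val_fraction,
                             seed = config$ga$seed)
  ga_res <- evolve(evaluator, config$ga)
  genome <- ga_res$best$genome
  final <- train_lse(det_bank, genome, config = lse_cfg, idx = train_idx)
  p <- predict_lse(final$model, det_bank, idx = test_idx)
  pred <- ifelse(p >= 0.5, "MI", "HC")
  cm <- confusion_matrix(labels[test_idx], pred, classes = c("MI", "HC"))
  list(genome = genome, model = final$model,
       report = compute_metrics(cm, positive = "MI"), ga = ga_res)
}

#' MI localization: multiclass head or a group of binary heads
#'
#' In `"multiclass"` mode one GA run evolves a single genome whose LSE
#' classifies all location classes jointly. In `"binary_group"` mode each
#' class gets its own GA run and one-vs-rest LSE head (so each genome can
#' specialize on the leads over its territory); the prediction is the class
#' of maximum positive probability, ties broken by the fixed class order
#' HC, AMI, ASMI, ALMI, IMI, ILMI. OMI beats, lacking a fixed territory, are
#' excluded from localization (they still participate in branch training).
#'
#' @param bank a `feature_bank`.
#' @param mode `"multiclass"` or `"binary_group"`.
#' @param config a [pipeline_config()].
#' @param train_idx,test_idx optional explicit patient-disjoint beat splits.
#' @return List with `genomes` (named list: one genome in multiclass mode,
#'   one per class in binary_group mode), `models`, `report`, `classes`.
#' @export
run_localization <- function(bank, mode = c("multiclass", "binary_group"),
                             config = pipeline_config(),
                             train_idx = NULL, test_idx = NULL) {
  mode <- match.arg(mode)
  labels <- as.character(bank$labels)
  keep_cls <- intersect(.localization_classes, unique(labels))
  if (length(keep_cls) < 2L) stop("localization needs at least 2 classes")
  keep <- which(labels %in% keep_cls)
  loc_bank <- bank
  loc_bank$class_set <- keep_cls
  if (is.null(train_idx) || is.null(test_idx)) {
    set.seed(config$ga$seed)
    split <- .patient_holdout(bank$patient_id[keep], labels[keep],
                              config$test_fraction)
    train_idx <- keep[split$train]
    test_idx <- keep[split$test]
  }
  if (mode == "multiclass") {
    lse_cfg <- .lse_cfg_from(config, "multiclass")
    evaluator <- lse_evaluator(loc_bank, lse_cfg, idx = train_idx,
                               val_fraction = config$val_fraction,
                               seed = config$ga$seed)
    ga_res <- evolve(evaluator, config$ga)
    genome <- ga_res$best$genome
    final <- train_lse(loc_bank, genome, config = lse_cfg, idx = train_idx)
    p <- predict_lse(final$model, loc_bank, idx = test_idx)
    pred <- colnames(p)[max.col(p, ties.method = "first")]
    genomes <- list(multiclass = genome)
    models <- list(multiclass = final$model)
  } else {
    genomes <- list(); models <- list()
    pos_prob <- matrix(0, length(test_idx), length(keep_cls),
                       dimnames = list(NULL, keep_cls))
    for (ci in seq_along(keep_cls)) {
      cls <- keep_cls[ci]
      cfg_c <- config
      cfg_c$ga$seed <- as.integer(config$ga$seed + 1000L * ci)
      lse_cfg <- .lse_cfg_from(cfg_c, "binary", positive_class = cls,
                               seed = cfg_c$ga$seed)
      evaluator <- lse_evaluator(loc_bank, lse_cfg, idx = train_idx,
                                 val_fraction = config$val_fraction,
                                 seed = cfg_c$ga$seed)
      ga_res <- evolve(evaluator, cfg_c$ga)
      genome <- ga_res$best$genome
      final <- train_lse(loc_bank, genome, config = lse_cfg, idx = train_idx)
      pos_prob[, cls] <- predict_lse(final$model, loc_bank, idx = test_idx)
      genomes[[cls]] <- genome
      models[[cls]] <- final$model
    }
    # argmax of positive probabilities; ties resolved by fixed class order
    pred <- keep_cls[max.col(pos_prob, ties.method = "first")]
  }
  cm <- confusion_matrix(labels[test_idx], pred, classes = keep_cls)
  list(genomes = genomes, models = models,
       report = compute_metrics(cm), classes = keep_cls, mode = mode)
}

#' Stratified inter-patient folds
#'
#' Partitions patients (never beats) into `k` folds, stratified by each
#' patient's class so every class is represented in every fold.
#'
#' @param patient_id per-beat patient identifiers.
#' @param labels per-beat class labels (one class per patient).
#' @param k number of folds.
#' @param seed RNG seed for the patient shuffle.
#' @return Integer vector of fold assignments (1..k), one per beat.
#' @export
make_patient_folds <- function(patient_id, labels, k = 5L, seed = 1L) {
  set.seed(seed)
  labels <- as.character(labels)
  pat_class <- tapply(labels, patient_id, function(x) x[1])
  fold_of <- integer(0)
  for (cls in unique(pat_class)) {
    pats <- sample(names(pat_class)[pat_class == cls])
    if (length(pats) < k) {
      stop("class ", cls, " has fewer than ", k, " patients")
    }
    f <- rep(seq_len(k), length.out = length(pats))
    fold_of[pats] <- f
  }
  unname(fold_of[patient_id])
}

#' Inter-patient cross-validation of the full search + diagnosis pipeline
#'
#' For each fold: the test fold's patients are completely excluded from
#' branch training, bank building, the GA search, and LSE training; the
#' fitted task model is then scored on the test fold's beats, and the fold
#' confusion matrices are summed into a pooled matrix.
#'
#' @param dataset a `beat_dataset`.
#' @param task `"detection"`, `"loc_multiclass"`, or `"loc_binary_group"`.
#' @param folds number of folds (default 5).
#' @param config a [pipeline_config()].
#' @param width_plan,schedule branch-network settings
#'   (see [train_branches()]).
#' @return List with `fold_reports`, `pooled` (an `evaluation_report` on the
#'   summed matrix), and `folds` (the per-beat fold vector).
#' @export
cross_validate <- function(dataset,
                           task = c("detection", "loc_multiclass", "loc_binary_group"),
                           folds = 5L, config = pipeline_config(),
                           width_plan = branch_width_plan(),
                           schedule = train_schedule()) {
  task <- match.arg(task)
  fold_of <- make_patient_folds(dataset$patient_id, dataset$labels, folds,
                                seed = config$ga$seed)
  fold_reports <- vector("list", folds)
  pooled_cm <- NULL
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f)
    te <- which(fold_of == f)
    stopifnot(length(intersect(dataset$patient_id[tr], dataset$patient_id[te])) == 0)
    train_ds <- .subset_dataset(dataset, tr)
    nets <- train_branches(train_ds, width_plan, schedule,
                           seed = config$ga$seed + 10L * f)
    bank <- build_feature_bank(nets, dataset)
    res <- switch(task,
      detection = run_detection(bank, config, train_idx = tr, test_idx = te),
      loc_multiclass = run_localization(bank, "multiclass", config,
                                        train_idx = .loc_subset(bank, tr),
                                        test_idx = .loc_subset(bank, te)),
      loc_binary_group = run_localization(bank, "binary_group", config,
                                          train_idx = .loc_subset(bank, tr),
                                          test_idx = .loc_subset(bank, te))
    )
    fold_reports[[f]] <- res$report
    pooled_cm <- if (is.null(pooled_cm)) res$report$confusion else
      pooled_cm + res$report$confusion
  }
  list(fold_reports = fold_reports, pooled = compute_metrics(pooled_cm),
       folds = fold_of)
}

.loc_subset <- function(bank, idx) {
  idx[as.character(bank$labels)[idx] %in% .localization_classes]
}

.subset_dataset <- function(dataset, idx) {
  structure(
    list(x = dataset$x[, , idx, drop = FALSE],
         labels = factor(as.character(dataset$labels)[idx],
                         levels = dataset$class_set),
         patient_id = dataset$patient_id[idx],
         lead_order = dataset$lead_order, class_set = dataset$class_set,
         fs = dataset$fs),
    class = "beat_dataset"
  )
}

#' Transfer learned architectures to a new dataset
#'
#' Reuses trained branch networks (frozen: no weight is touched) and the
#' genomes learned on the source data; builds a fresh feature bank on the
#' target dataset and retrains only the LSE heads there, then evaluates on a
#' patient-held-out test split of the target.
#'
#' @param genomes named list of genomes: `list(multiclass = L)` or one
#'   genome per class (binary group), as returned by [run_localization()];
#'   or a single genome for detection.
#' @param nets the 12 source-trained `branch_net`s.
#' @param new_dataset target `beat_dataset` (same lead order and beat
#'   length as the source).
#' @param task `"detection"`, `"loc_multiclass"`, or `"loc_binary_group"`.
#' @param config a [pipeline_config()].
#' @return List with `report`, `models`, and `bank` (the target bank).
#' @export
transfer_architecture <- function(genomes, nets, new_dataset,
                                  task = c("detection", "loc_multiclass",
                                           "loc_binary_group"),
                                  config = pipeline_config()) {
  task <- match.arg(task)
  if (!identical(new_dataset$lead_order, ecg_lead_names()) &&
      !identical(new_dataset$lead_order, nets[[1]]$lead_order %||% ecg_lead_names())) {
    stop("lead order of the target dataset does not match the source")
  }
  bank <- build_feature_bank(nets, new_dataset)
  set.seed(config$ga$seed)
  labels <- as.character(new_dataset$labels)
  if (task == "detection") {
    det_labels <- collapse_to_detection(labels)
    split <- .patient_holdout(new_dataset$patient_id, det_labels,
                              config$test_fraction)
    det_bank <- bank
    det_bank$labels <- factor(det_labels, levels = c("MI", "HC"))
    det_bank$class_set <- c("MI", "HC")
    genome <- if (is.list(genomes)) genomes[[1]] else genomes
    lse_cfg <- .lse_cfg_from(config, "binary", positive_class = "MI")
    final <- train_lse(det_bank, genome, config = lse_cfg, idx = split$train)
    p <- predict_lse(final$model, det_bank, idx = split$test)
    pred <- ifelse(p >= 0.5, "MI", "HC")
    cm <- confusion_matrix(det_labels[split$test], pred, classes = c("MI", "HC"))
    return(list(report = compute_metrics(cm, positive = "MI"),
                models = list(MI = final$model), bank = bank))
  }
  keep_cls <- intersect(.localization_classes, unique(labels))
  keep <- which(labels %in% keep_cls)
  split <- .patient_holdout(new_dataset$patient_id[keep], labels[keep],
                            config$test_fraction)
  train_idx <- keep[split$train]; test_idx <- keep[split$test]
  loc_bank <- bank
  loc_bank$class_set <- keep_cls
  models <- list()
  if (task == "loc_multiclass") {
    lse_cfg <- .lse_cfg_from(config, "multiclass")
    final <- train_lse(loc_bank, genomes[[1]], config = lse_cfg, idx = train_idx)
    p <- predict_lse(final$model, loc_bank, idx = test_idx)
    pred <- colnames(p)[max.col(p, ties.method = "first")]
    models$multiclass <- final$model
  } else {
    pos_prob <- matrix(0, length(test_idx), length(keep_cls),
                       dimnames = list(NULL, keep_cls))
    for (cls in keep_cls) {
      if (is.null(genomes[[cls]])) stop("missing genome for class ", cls)
      lse_cfg <- .lse_cfg_from(config, "binary", positive_class = cls)
      final <- train_lse(loc_bank, genomes[[cls]], config = lse_cfg,
                         idx = train_idx)
      pos_prob[, cls] <- predict_lse(final$model, loc_bank, idx = test_idx)
      models[[cls]] <- final$model
    }
    pred <- keep_cls[max.col(pos_prob, ties.method = "first")]
  }
  cm <- confusion_matrix(labels[test_idx], pred, classes = keep_cls)
  list(report = compute_metrics(cm), models = models, bank = bank)
}
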