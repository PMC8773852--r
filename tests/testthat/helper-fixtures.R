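# Shared fixtures, built once per test run. Sizes are deliberately small:
# narrow (8-channel) branches, 2 epochs, a few dozen beats — enough for the
# separable synthetic classes to be learnable while keeping the suite fast.

# two-class (HC vs IMI) dataset, trained desk branches, and a feature bank
fixture_env <- new.env()

get_tiny_bank <- function() {
  if (is.null(fixture_env$bank)) {
    ds <- generate_beat_dataset(25, c("HC", "IMI"), n_patients = 10,
                                noise_sd = 0.05, seed = 7)
    nets <- train_branches(ds, branch_width_plan("desk"),
                           train_schedule("desk", epochs = 2), seed = 1)
    fixture_env$dataset <- ds
    fixture_env$nets <- nets
    fixture_env$bank <- build_feature_bank(nets, ds)
  }
  list(dataset = fixture_env$dataset, nets = fixture_env$nets,
       bank = fixture_env$bank)
}

# a hand-built separable feature bank: only lead `signal_lead` carries class
# information; all other leads are pure noise. Lets LSE tests run without
# any branch training.
make_toy_bank <- function(n = 80, signal_lead = 2, d = 4, seed = 1,
                          levels = c(2, 17)) {
  set.seed(seed)
  labels <- rep(c("A", "B"), length.out = n)
  feats <- lapply(1:12, function(lead) {
    per_level <- lapply(levels, function(l) {
      f <- matrix(rnorm(n * d), n, d)
      if (lead == signal_lead) {
        f <- f + outer(ifelse(labels == "A", 2, -2), rep(1, d))
      }
      f
    })
    names(per_level) <- as.character(levels)
    per_level
  })
  structure(
    list(features = feats, labels = factor(labels, levels = c("A", "B")),
         patient_id = sprintf("P%02d", rep(1:8, length.out = n)),
         level_set = as.integer(levels), lead_order = ecg_lead_names(),
         class_set = c("A", "B"),
         manifest = list(n_beats = n, synthetic = TRUE)),
    class = "feature_bank"
  )
}

# deterministic mock fitness: a fixed pseudo-random score per genome
mock_evaluator <- function(salt = 0) {
  function(genome) {
    v <- sum(sin(genome * (seq_len(12) + salt)))
    list(f1 = (v - floor(v)), accuracy = 0.5)
  }
}
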