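# Genetic-algorithm search over 12-integer genomes. Each genome L assigns a
# feature level to each lead: even levels 2..16 or the top level 17. The GA
# is elitist: the top n_parents individuals survive unchanged, offspring are
# produced by one-point crossover at the limb/precordial boundary (after
# position 6) and by a reset mutation, and the loop stops early when the
# population's maximum fitness stalls.

#' Allowed feature levels for a genome element
#'
#' Even basic-unit indices 2..16 plus the top level 17.
#'
#' @return Integer vector of 9 admissible values.
#' @export
allowed_levels <- function() c(seq.int(2L, 16L, by = 2L), 17L)

#' Validate an architecture genome
#'
#' Checks the search-space constraints: length 12; every element at most 17,
#' at least 2, and even or equal to 17.
#'
#' @param L integer vector.
#' @return Character vector of violations; `character(0)` if the genome is
#'   valid.
#' @export
#' @examples
#' validate_genome(c(2, 4, 4, 6, 6, 6, 8, 8, 10, 10, 14, 17))  # valid
validate_genome <- function(L) {
  v <- character(0)
  if (length(L) != 12L) {
    v <- c(v, sprintf("length is %d, must be 12", length(L)))
    return(v)
  }
  if (any(is.na(L)) || any(L != round(L))) {
    v <- c(v, "elements must be integers")
    return(v)
  }
  bad_hi <- which(L > 17)
  if (length(bad_hi)) {
    v <- c(v, sprintf("element(s) %s exceed 17", paste(bad_hi, collapse = ",")))
  }
  bad_lo <- which(L < 2)
  if (length(bad_lo)) {
    v <- c(v, sprintf("element(s) %s below 2", paste(bad_lo, collapse = ",")))
  }
  bad_par <- which(L %% 2 != 0 & L != 17)
  if (length(bad_par)) {
    v <- c(v, sprintf("element(s) %s odd and not 17", paste(bad_par, collapse = ",")))
  }
  v
}

.is_valid_genome <- function(L) length(validate_genome(L)) == 0L

#' GA configuration
#'
#' Defaults are the full-size search settings: population 100, 10 parents,
#' one-point crossover probabilities p1/p2 = 0.8/0.2 for the reset values,
#' per-offspring mutation probability pm = 0.25 with k = 3 reset elements,
#' at most 10 generations, early stop after 2 stagnant generations, and
#' fitness weights alpha = 1, beta = 0.1, eta = 1e-5.
#'
#' @param pop_size population size.
#' @param n_parents elites kept each generation.
#' @param p1,p2 probabilities that a mutated element resets to 2 / to 17
#'   (must sum to 1).
#' @param pm probability that an offspring is mutated.
#' @param k number of elements reset by one mutation.
#' @param max_generations iteration cap.
#' @param patience generations of unchanged maximum fitness before stopping.
#' @param alpha,beta,eta fitness weights (see [ga_fitness()]).
#' @param seed integer seed driving all the GA's randomness.
#' @return A `ga_config` list.
#' @export
ga_config <- function(pop_size = 100L, n_parents = 10L, p1 = 0.8, p2 = 0.2,
                      pm = 0.25, k = 3L, max_generations = 10L,
                      patience = 2L, alpha = 1, beta = 0.1, eta = 1e-5,
                      seed = 1L) {
  if (abs(p1 + p2 - 1) > 1e-12) stop("p1 + p2 must equal 1")
  if (pm <= 0 || pm >= 1) stop("pm must be in (0, 1)")
  if (n_parents >= pop_size) stop("n_parents must be smaller than pop_size")
  if (k > 12L || k < 1L) stop("k must be in 1..12")
  if (alpha <= 0 || beta <= 0 || eta <= 0) stop("fitness weights must be positive")
  structure(
    list(pop_size = as.integer(pop_size), n_parents = as.integer(n_parents),
         p1 = p1, p2 = p2, pm = pm, k = as.integer(k),
         max_generations = as.integer(max_generations),
         patience = as.integer(patience),
         alpha = alpha, beta = beta, eta = eta, seed = as.integer(seed)),
    class = "ga_config"
  )
}

#' Draw a random valid genome
#'
#' Each element sampled uniformly from [allowed_levels()].
#'
#' @param n number of genomes.
#' @return A single integer vector if `n = 1`, else a list of genomes.
#' @export
random_genome <- function(n = 1L) {
  draw <- function() sample(allowed_levels(), 12L, replace = TRUE)
  if (n == 1L) draw() else replicate(n, draw(), simplify = FALSE)
}

#' Initialize a GA population
#'
#' `pop_size` individuals with uniformly sampled valid genomes and
#' unevaluated fitness. Call [set.seed()] (or use [evolve()], which seeds
#' from its config) for reproducibility.
#'
#' @param config a [ga_config()].
#' @return List of individuals: `list(genome, fitness = NA, f1 = NA,
#'   accuracy = NA)`.
#' @export
init_population <- function(config = ga_config()) {
  lapply(seq_len(config$pop_size), function(i) {
    list(genome = random_genome(), fitness = NA_real_,
         f1 = NA_real_, accuracy = NA_real_)
  })
}

#' Architecture fitness
#'
#' `alpha * F1 + beta * Accuracy - eta * sum(L)`: classification performance
#' (F1 weighted first, accuracy second) minus a depth-sum complexity
#' penalty, so among equally performing architectures the shallowest wins.
#' F1 and Accuracy are on the 0..1 scale.
#'
#' @param f1,accuracy performance of the decoded model, both in `[0, 1]`.
#' @param L the genome (its element sum is the complexity measure).
#' @param alpha,beta,eta positive weights.
#' @return Scalar fitness.
#' @export
#' @examples
#' ga_fitness(0.8, 0.9, c(17, 12, 17, 2, 2, 16, 14, 2, 2, 14, 16, 17))
#' # 0.8 + 0.09 - 1e-5 * 131 = 0.88869
ga_fitness <- function(f1, accuracy, L, alpha = 1, beta = 0.1, eta = 1e-5) {
  alpha * f1 + beta * accuracy - eta * sum(L)
}

#' Select the parent individuals
#'
#' The `n_parents` individuals of highest fitness; ties broken by smaller
#' genome sum (lighter model), then by position in the population.
#'
#' @param population list of evaluated individuals.
#' @param n_parents number to keep.
#' @return List of the selected individuals, best first.
#' @export
select_parents <- function(population, n_parents) {
  fit <- vapply(population, function(i) i$fitness, numeric(1))
  if (any(is.na(fit))) stop("all individuals must be evaluated before selection")
  sums <- vapply(population, function(i) sum(i$genome), numeric(1))
  ord <- order(-fit, sums, seq_along(population))
  population[ord[seq_len(min(n_parents, length(population)))]]
}

#' One-point crossover at the limb/precordial boundary
#'
#' Splits both parents after position 6 — exactly the boundary between the
#' six limb leads and the six precordial leads — and exchanges the halves,
#' so each child keeps one parent's complete limb-lead plan and the other's
#' complete precordial plan.
#'
#' @param a,b parent genomes.
#' @return List of two child genomes.
#' @export
crossover_genomes <- function(a, b) {
  stopifnot(length(a) == 12L, length(b) == 12L)
  list(c(a[1:6], b[7:12]), c(b[1:6], a[7:12]))
}

#' Reset mutation
#'
#' Selects `k` distinct positions (without replacement) and resets each one
#' to 2 with probability `p1` or to 17 with probability `p2 = 1 - p1`,
#' independently. A reset landing on the element's current value still
#' counts as a mutated element. Output is always a valid genome.
#'
#' @param L genome to mutate.
#' @param k number of positions to reset.
#' @param p1 probability of resetting to 2 (else 17).
#' @return Mutated genome.
#' @export
mutate_genome <- function(L, k = 3L, p1 = 0.8) {
  if (k > length(L)) stop("k cannot exceed the genome length")
  pos <- sample.int(length(L), k)
  L[pos] <- ifelse(runif(k) < p1, 2L, 17L)
  L
}

#' Apply the mutation operator to a set of offspring
#'
#' Each offspring is independently mutated with probability `pm`
#' (the per-individual mutation rate); a mutated offspring has `k` of its
#' elements reset via [mutate_genome()].
#'
#' @param genomes list of offspring genomes.
#' @param config a [ga_config()] supplying `pm`, `k`, `p1`.
#' @return List with `genomes` (after mutation) and `mutated` (logical
#'   vector marking which offspring the operator touched).
#' @export
mutate_offspring <- function(genomes, config = ga_config()) {
  mutated <- runif(length(genomes)) < config$pm
  genomes <- lapply(seq_along(genomes), function(i) {
    if (mutated[i]) mutate_genome(genomes[[i]], config$k, config$p1)
    else genomes[[i]]
  })
  list(genomes = genomes, mutated = mutated)
}

#' Evolve an architecture genome
#'
#' The full GA loop: evaluate every individual (with caching, so a genome
#' seen before costs no new evaluator call), keep the `n_parents` elites,
#' fill the population back up with crossover offspring of uniformly drawn
#' distinct parent pairs, mutate each offspring independently with
#' probability `pm`, and iterate. Stops at `max_generations` or as soon as
#' the maximum fitness has not changed (within 1e-12) for `patience`
#' consecutive generations. Because elites survive unchanged, the maximum
#' fitness is non-decreasing across generations.
#'
#' @param evaluator `function(genome) -> list(f1 =, accuracy =)`, both in
#'   `[0, 1]`; see [lse_evaluator()] for the feature-bank-backed one. An
#'   evaluator error gives that individual fitness `-Inf` with a warning.
#' @param config a [ga_config()].
#' @return List with `best` (the best individual), `history` (per-generation
#'   data frame: generation, max/mean fitness, best genome string),
#'   `population` (final), `cache_hits`, `n_evaluations`.
#' @export
evolve <- function(evaluator, config = ga_config()) {
  set.seed(config$seed)
  pop <- init_population(config)
  cache <- new.env(parent = emptyenv())
  cache_hits <- 0L
  n_eval <- 0L
  eval_ind <- function(ind) {
    key <- paste(ind$genome, collapse = ",")
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) {
      cache_hits <<- cache_hits + 1L
      ind$f1 <- hit$f1; ind$accuracy <- hit$accuracy; ind$fitness <- hit$fitness
      return(ind)
    }
    res <- tryCatch(evaluator(ind$genome), error = function(e) {
      warning("evaluator failed on [", key, "]: ", conditionMessage(e))
      NULL
    })
    n_eval <<- n_eval + 1L
    if (is.null(res)) {
      ind$fitness <- -Inf
    } else {
      ind$f1 <- res$f1
      ind$accuracy <- res$accuracy
      ind$fitness <- ga_fitness(res$f1, res$accuracy, ind$genome,
                                config$alpha, config$beta, config$eta)
    }
    assign(key, list(f1 = ind$f1, accuracy = ind$accuracy, fitness = ind$fitness),
           envir = cache)
    ind
  }
  history <- data.frame()
  best_prev <- -Inf
  stalled <- 0L
  gen <- 0L
  repeat {
    gen <- gen + 1L
    stopifnot(length(pop) == config$pop_size)
    stopifnot(all(vapply(pop, function(i) .is_valid_genome(i$genome), logical(1))))
    pop <- lapply(pop, eval_ind)
    fit <- vapply(pop, function(i) i$fitness, numeric(1))
    best_ind <- select_parents(pop, 1L)[[1]]
    history <- rbind(history, data.frame(
      generation = gen, max_fitness = max(fit),
      mean_fitness = mean(fit[is.finite(fit)]),
      best_genome = paste(best_ind$genome, collapse = ",")
    ))
    if (is.finite(best_prev) && abs(max(fit) - best_prev) <= 1e-12) {
      stalled <- stalled + 1L
    } else {
      stalled <- 0L
    }
    best_prev <- max(fit)
    if (stalled >= config$patience || gen >= config$max_generations) break
    parents <- select_parents(pop, config$n_parents)
    n_off <- config$pop_size - config$n_parents
    offspring <- list()
    while (length(offspring) < n_off) {
      pair <- sample.int(length(parents), 2L)
      ch <- crossover_genomes(parents[[pair[1]]]$genome, parents[[pair[2]]]$genome)
      offspring <- c(offspring, ch)
    }
    offspring <- offspring[seq_len(n_off)]
    offspring <- mutate_offspring(offspring, config)$genomes
    pop <- c(parents, lapply(offspring, function(g) {
      list(genome = g, fitness = NA_real_, f1 = NA_real_, accuracy = NA_real_)
    }))
  }
  list(best = select_parents(pop, 1L)[[1]], history = history,
       population = pop, cache_hits = cache_hits, n_evaluations = n_eval)
}

#' Feature-bank fitness evaluator
#'
#' The production evaluator behind [evolve()]: for a candidate genome it
#' trains an LSE head on a patient-held-out 80/20 split of the bank's
#' training beats and returns the validation F1 (macro-averaged for
#' multiclass, positive-class for binary) and accuracy. Deterministic given
#' genome + seed: each genome derives its own substream seed.
#'
#' @param bank a `feature_bank`.
#' @param lse_cfg an [lse_config()] used for the head training.
#' @param idx beat subset defining the training fold (default all beats).
#' @param val_fraction patient fraction held out for validation.
#' @param seed base seed.
#' @return `function(genome) -> list(f1, accuracy)`.
#' @export
lse_evaluator <- function(bank, lse_cfg = lse_config(), idx = NULL,
                          val_fraction = 0.2, seed = 1L) {
  idx <- idx %||% seq_along(bank$labels)
  labels <- as.character(bank$labels)[idx]
  pids <- bank$patient_id[idx]
  function(genome) {
    gseed <- (seed * 7919L + sum(as.integer(genome) * seq_len(12L) * 131L)) %% 2147483647L
    set.seed(gseed)
    split <- .patient_holdout(pids, labels, val_fraction)
    fit_idx <- idx[split$train]
    val_idx <- idx[split$test]
    cfg <- lse_cfg
    cfg$seed <- as.integer(gseed %% 1000003L)
    trained <- train_lse(bank, genome, config = cfg, idx = fit_idx)
    p <- predict_lse(trained$model, bank, idx = val_idx)
    truth <- labels[split$test]
    if (cfg$class_mode == "binary") {
      pred_pos <- p >= 0.5
      truth_pos <- truth == cfg$positive_class
      list(f1 = .binary_f1(truth_pos, pred_pos),
           accuracy = mean(pred_pos == truth_pos))
    } else {
      pred <- colnames(p)[max.col(p, ties.method = "first")]
      list(f1 = .macro_f1(truth, pred, trained$model$class_set),
           accuracy = mean(pred == truth))
    }
  }
}

# patient-wise stratified holdout: returns beat index masks
.patient_holdout <- function(pids, labels, test_fraction) {
  pat_class <- tapply(labels, pids, function(x) x[1])
  pats <- names(pat_class)
  test_pats <- character(0)
  for (cls in unique(pat_class)) {
    p_cls <- pats[pat_class == cls]
    n_test <- max(1L, round(length(p_cls) * test_fraction))
    if (n_test >= length(p_cls)) n_test <- length(p_cls) - 1L
    if (n_test >= 1L) {
      test_pats <- c(test_pats, sample(p_cls, n_test))
    }
  }
  test <- pids %in% test_pats
  if (!any(test) || all(test)) {
    # degenerate fallback: single-patient classes; hold out beats instead
    test <- seq_along(pids) %in% sample(seq_along(pids), max(1L, round(length(pids) * test_fraction)))
  }
  list(train = which(!test), test = which(test))
}

.binary_f1 <- function(truth, pred) {
  tp <- sum(truth & pred); fp <- sum(!truth & pred); fn <- sum(truth & !pred)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

.macro_f1 <- function(truth, pred, classes) {
  f1s <- vapply(classes, function(cl) {
    .binary_f1(truth == cl, pred == cl)
  }, numeric(1))
  mean(f1s)
}
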