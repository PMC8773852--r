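test_that("genome validation enforces the search-space constraints", {
  expect_length(validate_genome(c(2, 4, 4, 6, 6, 6, 8, 8, 10, 10, 14, 17)), 0L)
  v <- validate_genome(c(3, 4, 4, 6, 6, 6, 8, 8, 10, 10, 14, 17))
  expect_match(v, "odd", all = FALSE)
  expect_match(validate_genome(rep(2, 11)), "length")
  expect_match(validate_genome(c(rep(2, 11), 18)), "exceed")
  expect_match(validate_genome(c(rep(2, 11), 0)), "below")
  expect_identical(allowed_levels(), c(2L, 4L, 6L, 8L, 10L, 12L, 14L, 16L, 17L))
})

test_that("initialization is uniform over the 9 admissible levels", {
  cfg <- ga_config()
  set.seed(1)
  pop <- init_population(cfg)
  expect_length(pop, 100L)
  expect_true(all(vapply(pop, function(i) length(validate_genome(i$genome)) == 0,
                         logical(1))))
  set.seed(2)
  draws <- unlist(random_genome(ceiling(1e5 / 12)))
  freq <- table(factor(draws, levels = allowed_levels())) / length(draws)
  expect_true(all(abs(freq - 1 / 9) < 0.01))
  set.seed(3); a <- init_population(cfg)
  set.seed(3); b <- init_population(cfg)
  expect_identical(a, b)
})

test_that("fitness matches the weighted performance-minus-complexity form", {
  L <- c(17, 12, 17, 2, 2, 16, 14, 2, 2, 14, 16, 17)
  expect_equal(sum(L), 131)
  expect_equal(ga_fitness(0.8, 0.9, L), 0.88869, tolerance = 1e-9)
  expect_equal(ga_fitness(0, 0, rep(2, 12)), -2.4e-4, tolerance = 1e-12)
  expect_gt(ga_fitness(0.5, 0.5, rep(2, 12)), ga_fitness(0.5, 0.5, rep(17, 12)))
})

test_that("selection keeps the fittest with lighter-genome tie-breaks", {
  pop <- lapply(1:100, function(i) {
    list(genome = rep(2L, 12), fitness = i, f1 = NA, accuracy = NA)
  })
  sel <- select_parents(pop, 10)
  expect_equal(sort(vapply(sel, `[[`, numeric(1), "fitness")), 91:100)
  expect_length(select_parents(pop, 100), 100L)
  tied <- list(
    list(genome = c(17, 12, 17, 2, 2, 16, 14, 2, 2, 14, 16, 17), fitness = 1),
    list(genome = rep(2L, 12), fitness = 1)
  )
  expect_equal(sum(select_parents(tied, 1)[[1]]$genome), 24)
  pop[[5]]$fitness <- NA_real_
  expect_error(select_parents(pop, 10), "evaluated")
})

test_that("crossover splices at the limb/precordial boundary and is an involution", {
  A <- c(2, 4, 4, 6, 6, 6, 8, 8, 10, 10, 14, 17)
  B <- rep(17, 12)
  ch <- crossover_genomes(A, B)
  expect_equal(ch[[1]], c(2, 4, 4, 6, 6, 6, 17, 17, 17, 17, 17, 17))
  expect_equal(ch[[2]], c(17, 17, 17, 17, 17, 17, 8, 8, 10, 10, 14, 17))
  expect_equal(crossover_genomes(A, A), list(A, A))
  back <- crossover_genomes(ch[[1]], ch[[2]])
  expect_setequal(list(back[[1]], back[[2]]), list(A, B))
})

test_that("mutation resets exactly k positions to the extreme levels", {
  set.seed(1)
  L <- rep(8L, 12)
  m1 <- mutate_genome(L, k = 3, p1 = 1.0)
  expect_equal(sum(m1 == 2L), 3L)
  expect_equal(sum(m1 == 8L), 9L)
  m0 <- mutate_genome(L, k = 3, p1 = 0.0)
  expect_equal(sum(m0 == 17L), 3L)
  mall <- mutate_genome(L, k = 12, p1 = 0.5)
  expect_true(all(mall %in% c(2L, 17L)))
  expect_error(mutate_genome(L, k = 13), "exceed")
  expect_length(validate_genome(mutate_genome(L, 3, 0.8)), 0L)
})

test_that("mutation-rate and reset-value frequencies are calibrated", {
  set.seed(42)
  off <- random_genome(10000)
  mo <- mutate_offspring(off, ga_config())
  expect_equal(mean(mo$mutated), 0.25, tolerance = 0.02)
  set.seed(43)
  resets <- unlist(replicate(4000, {
    m <- mutate_genome(rep(4L, 12), 3, 0.8)
    m[m != 4L]
  }, simplify = FALSE))
  expect_gte(length(resets), 10000)
  expect_equal(mean(resets == 2L), 0.8, tolerance = 0.02)
})

test_that("the generation loop stops early on stagnation and late on progress", {
  res <- evolve(function(g) list(f1 = 0.5, accuracy = 0.5),
                ga_config(pop_size = 20, n_parents = 5, eta = 1e-16, seed = 1))
  expect_equal(nrow(res$history), 1L + 2L)  # 1 + patience
  counter <- new.env(); counter$i <- 0
  impr <- function(g) {
    counter$i <- counter$i + 1
    list(f1 = counter$i * 1e-3, accuracy = 0)
  }
  res2 <- evolve(impr, ga_config(eta = 1e-16, seed = 1))
  expect_equal(nrow(res2$history), 10L)
})

test_that("elitism, closure and population size hold over random mock runs", {
  for (run in 1:20) {
    cfg <- ga_config(pop_size = 24, n_parents = 6, max_generations = 5,
                     patience = 5, seed = run)
    res <- evolve(mock_evaluator(salt = run), cfg)
    expect_false(is.unsorted(res$history$max_fitness))
    expect_length(res$population, 24L)
    expect_true(all(vapply(res$population, function(i)
      length(validate_genome(i$genome)) == 0, logical(1))))
  }
})

test_that("fitness caching avoids duplicate evaluator calls", {
  calls <- new.env(); calls$keys <- character(0)
  ev <- function(g) {
    calls$keys <- c(calls$keys, paste(g, collapse = ","))
    list(f1 = 0.5, accuracy = 0.5)
  }
  res <- evolve(ev, ga_config(pop_size = 30, n_parents = 8, seed = 4,
                              max_generations = 4, patience = 10))
  expect_equal(res$n_evaluations, length(unique(calls$keys)))
  expect_equal(res$n_evaluations, length(calls$keys))  # no genome evaluated twice
  expect_gt(res$cache_hits, 0L)
})

test_that("a failing evaluator demotes the individual instead of aborting", {
  ev <- function(g) {
    if (g[1] == 2) stop("boom")
    list(f1 = 0.5, accuracy = 0.5)
  }
  w <- capture_warnings(
    res <- evolve(ev, ga_config(pop_size = 15, n_parents = 4,
                                max_generations = 2, patience = 10, seed = 2))
  )
  expect_true(any(grepl("failed", w)))
  expect_true(is.finite(res$best$fitness))
})

test_that("the GA beats a same-budget random-search baseline on a planted optimum", {
  wins <- 0L
  for (s in 1:5) {
    target <- local({ set.seed(100 + s); sample(allowed_levels(), 12, TRUE) })
    ev <- function(g) list(f1 = 1 - sum(abs(g - target)) / 180, accuracy = 0)
    ga <- evolve(ev, ga_config(seed = s))
    set.seed(s)
    rnd <- random_genome(1000)
    rbest <- max(vapply(rnd, function(g)
      ga_fitness(1 - sum(abs(g - target)) / 180, 0, g), numeric(1)))
    if (ga$best$fitness >= rbest) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})
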