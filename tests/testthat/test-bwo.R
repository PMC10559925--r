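test_that("config enforces the population-size closure", {
  cfg <- bwo_config()
  expect_equal(cfg$n_procreate, 6)   # even(round(0.6*10))
  expect_equal(cfg$n_mutate, 4)      # round(0.4*10)
  expect_error(bwo_config(pop_size = 10, pr = 0.5, mr = 0.3), "closure")
  expect_error(bwo_config(pr = 1.5), "pr and mr")
  full <- bwo_config(pop_size = 10, pr = 1, mr = 0)
  expect_equal(full$n_procreate, 10)
  expect_equal(full$n_mutate, 0)
})

test_that("population initialization respects bounds and seed", {
  cfg <- bwo_config()
  pop <- stream_do(rng_stream(5), init_population(cfg, 100))
  expect_length(pop, 10)
  for (w in pop) {
    expect_length(w$genotype, 100)
    expect_true(all(w$genotype >= 0 & w$genotype <= 1))
  }
  pop2 <- stream_do(rng_stream(5), init_population(cfg, 100))
  expect_identical(pop, pop2)
  degen <- stream_do(rng_stream(1),
                     init_population(bwo_config(lb = 0.7, ub = 0.7), 10))
  expect_true(all(vapply(degen, function(w) all(w$genotype == 0.7),
                         logical(1))))
})

test_that("selection probabilities normalize fitness values", {
  expect_equal(selection_probability(2), 1)
  expect_equal(selection_probability(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_equal(selection_probability(c(0.1, 0.3, 0.6)), c(0.1, 0.3, 0.6))
  expect_equal(selection_probability(c(0, 0)), c(0.5, 0.5))  # degenerate
  expect_error(selection_probability(c(-1, 2)), ">= 0")
})

test_that("procreation is convex crossover with exact conservation", {
  x1 <- c(0, 1); x2 <- c(1, 0)
  # identity and swap limit cases
  kids <- procreate(x1, x2, alpha = c(1, 1))
  expect_equal(kids[[1]]$genotype, x1)
  expect_equal(kids[[2]]$genotype, x2)
  kids <- procreate(x1, x2, alpha = c(0, 0))
  expect_equal(kids[[1]]$genotype, x2)
  expect_equal(kids[[2]]$genotype, x1)
  kids <- procreate(x1, x2, alpha = c(0.5, 0.5))
  expect_equal(kids[[1]]$genotype, c(0.5, 0.5))
  expect_equal(kids[[2]]$genotype, c(0.5, 0.5))
  expect_error(procreate(c(0, 1), c(1, 0, 0)), "length")

  # conservation y1 + y2 == x1 + x2 over 1000 random matings
  set.seed(123)
  for (i in 1:1000) {
    a <- runif(20); b <- runif(20)
    kids <- procreate(a, b)
    expect_true(max(abs(kids[[1]]$genotype + kids[[2]]$genotype -
                          (a + b))) < 1e-12)
    expect_true(all(kids[[1]]$genotype >= 0 & kids[[1]]$genotype <= 1))
    expect_true(all(kids[[2]]$genotype >= 0 & kids[[2]]$genotype <= 1))
  }
})

test_that("cannibalism keeps the better parent and child with fixed ties", {
  mk <- function(fit, size) {
    new_widow(rep(1, 4), structure(list(mask = rep(1L, 4), error_rate = fit,
                                        n_selected = size, fitness = fit),
                                   class = "evaluated_solution"))
  }
  ev <- function(g) stop("should not evaluate pre-evaluated widows")
  surv <- cannibalize_pair(mk(0.2, 2), mk(0.5, 2), mk(0.3, 2), mk(0.1, 2), ev)
  expect_equal(surv[[1]]$eval$fitness, 0.2)
  expect_equal(surv[[2]]$eval$fitness, 0.1)
  # all equal -> first arguments survive
  a <- mk(0.4, 2); b <- mk(0.4, 2)
  surv <- cannibalize_pair(a, b, a, b, ev)
  expect_identical(surv[[1]], a)
  # equal fitness, second parent smaller subset -> second parent survives
  small <- mk(0.4, 1)
  surv <- cannibalize_pair(a, small, a, b, ev)
  expect_identical(surv[[1]], small)
})

test_that("swap mutation exchanges exactly two entries", {
  m <- mutate_swap(c(1, 2, 3, 4), positions = c(1, 4))
  expect_equal(m$genotype, c(4, 2, 3, 1))
  set.seed(7)
  for (i in 1:50) {
    g <- runif(15)
    m <- mutate_swap(g)$genotype
    expect_equal(sort(m), sort(g))            # multiset preserved
    expect_lte(sum(m != g), 2)
  }
  expect_error(mutate_swap(3.2), "length >= 2")
})

test_that("one generation keeps the population at Npop with valid genotypes", {
  ds <- tiny_fixture()$dataset
  spec <- tiny_spec()
  evaluator <- make_evaluator(ds, spec)
  cfg <- bwo_config()
  pop <- stream_do(rng_stream(2), init_population(cfg, 8))
  pop <- lapply(pop, function(w) { w$eval <- evaluator(w$genotype); w })
  pop <- pop[order(vapply(pop, function(w) w$eval$fitness, numeric(1)))]
  nxt <- stream_do(rng_stream(3), bwo_iteration(pop, cfg, evaluator))
  expect_length(nxt, 10)
  for (w in nxt) {
    expect_false(is.null(w$eval))
    expect_true(all(w$genotype >= 0 & w$genotype <= 1))
  }
  # pr = 1: all survivors come from procreation
  cfg_full <- bwo_config(pop_size = 10, pr = 1, mr = 0)
  nxt_full <- stream_do(rng_stream(3), bwo_iteration(pop, cfg_full, evaluator))
  expect_length(nxt_full, 10)
  # constant evaluator: size invariant holds under a degenerate objective
  const_eval <- size_penalty_evaluator(8, error = 0.5)
  nxt_const <- stream_do(rng_stream(4), bwo_iteration(pop, cfg, const_eval))
  expect_length(nxt_const, 10)
})

test_that("run_bwo traces are monotone, bounded and deterministic", {
  ds <- generate_synthetic(synthetic_spec(30, 25, 3, 2, effect_size = 2,
                                          seed = 3))$dataset
  spec <- fitness_spec(cv_folds = 5)
  cfg <- bwo_config(max_iterations = 15, seed = 11)
  tr <- run_bwo(ds, cfg, spec)
  expect_s3_class(tr, "run_trace")
  expect_length(tr$best_fitness_history, 16)
  expect_true(all(diff(tr$best_fitness_history) <= 0))
  expect_equal(tr$best_widow$eval$fitness,
               tr$best_fitness_history[length(tr$best_fitness_history)])
  expect_true(all(tr$best_widow$genotype >= 0 & tr$best_widow$genotype <= 1))
  tr2 <- run_bwo(ds, cfg, spec)
  expect_identical(tr$best_fitness_history, tr2$best_fitness_history)
  expect_identical(tr$best_widow, tr2$best_widow)
  # zero-iteration run records only the initial population's best
  tr0 <- run_bwo(ds, bwo_config(max_iterations = 0, seed = 11), spec)
  expect_length(tr0$best_fitness_history, 1)
})

test_that("patience stops a stagnant run early", {
  ds <- tiny_fixture()$dataset
  cfg <- bwo_config(max_iterations = 100, seed = 2, patience = 5,
                    patience_tol = 1e-6)
  tr <- run_bwo(ds, cfg, tiny_spec())
  expect_lt(tr$iterations, 100)
  expect_true(all(diff(tr$best_fitness_history) <= 0))
})
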