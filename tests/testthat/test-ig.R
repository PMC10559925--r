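test_that("constant temperature is the scaled mean expression over ten", {
  const <- expression_dataset(matrix(0.3, 4, 3), c("A", "A", "B", "B"),
                              paste0("g", 1:3), normalized = TRUE)
  expect_equal(compute_temperature(const), 0.3 / 10)
  # raw 2x3 matrix [[1,2,3],[4,5,6]] fed directly: T = 21/60
  # (two samples is below the >=2-per-class constructor floor, so built by
  # hand; compute_temperature only reads the values)
  raw <- structure(list(values = matrix(as.numeric(1:6), 2, 3, byrow = TRUE),
                        labels = factor(c("A", "B")),
                        gene_ids = paste0("g", 1:3), name = "raw",
                        normalized = FALSE),
                   class = "expression_dataset")
  expect_equal(compute_temperature(raw), 21 / 60)
  zero <- structure(list(values = matrix(0, 4, 3),
                         labels = factor(c("A", "A", "B", "B")),
                         gene_ids = paste0("g", 1:3), name = "z",
                         normalized = TRUE),
                    class = "expression_dataset")
  expect_equal(compute_temperature(zero), 0)
  expect_equal(compute_temperature(const, t_scale = 2), 0.06)
})

test_that("destruction removes d genes without repetition and caps at one left", {
  g <- rep(0, 20); g[c(2, 5, 9, 14, 17)] <- 1
  w <- new_widow(g, structure(list(mask = decode_mask(g), error_rate = 0,
                                   n_selected = 5L, fitness = 0.1),
                              class = "evaluated_solution"))
  res <- stream_do(rng_stream(1), destruct(w, 2))
  expect_length(res$removed, 2)
  expect_false(anyDuplicated(res$removed) > 0)
  sel_after <- which(res$partial$genotype > 0.5)
  expect_length(sel_after, 3)
  expect_length(intersect(sel_after, res$removed), 0)
  expect_setequal(c(sel_after, res$removed), c(2, 5, 9, 14, 17))

  # d larger than the subset: capped so one gene remains
  res_cap <- stream_do(rng_stream(2), destruct(w, 10))
  expect_length(res_cap$removed, 4)
  expect_length(which(res_cap$partial$genotype > 0.5), 1)

  # single selected gene: signal, not an exception
  g1 <- rep(0, 20); g1[7] <- 1
  w1 <- new_widow(g1)
  res1 <- destruct(w1, 3)
  expect_length(res1$removed, 0)
  expect_identical(res1$partial, w1)
})

test_that("greedy construction re-adds only strictly improving genes", {
  # pure size penalty: re-adding always raises fitness, nothing comes back
  ev <- size_penalty_evaluator(20, error = 0.5)
  g <- rep(0, 20); g[c(1, 2, 3)] <- 1
  partial <- new_widow(g)
  out <- construct_greedy(partial, removed = c(10, 11), evaluator = ev)
  expect_equal(which(out$genotype > 0.5), c(1, 2, 3))

  # tiny fixture with the informative gene removed: the error drop from
  # re-adding it (0.99 * error) dominates the size cost (0.01 / 8)
  fix <- tiny_fixture()
  evaluator <- make_evaluator(fix$dataset, tiny_spec())
  g2 <- rep(0, 8); g2[c(1, 5)] <- 1
  err_without <- knn_cv_error(fix$dataset, decode_mask(g2), tiny_spec())
  g2_with <- g2; g2_with[3] <- 1
  err_with <- knn_cv_error(fix$dataset, decode_mask(g2_with), tiny_spec())
  expect_gt(0.99 * (err_without - err_with), 0.01 / 8)  # oracle inequality
  out2 <- construct_greedy(new_widow(g2), removed = 3, evaluator = evaluator)
  expect_true(3 %in% which(out2$genotype > 0.5))

  # nothing removed: output is the evaluated partial
  out3 <- construct_greedy(new_widow(g2), removed = integer(0),
                           evaluator = evaluator)
  expect_equal(out3$genotype, g2)
})

test_that("destruct/construct round-trips under an always-improving objective", {
  # evaluator that rewards every selected gene: all removed genes re-added
  nvar <- 15
  f <- function(genotype) {
    n_sel <- sum(decode_mask(genotype))
    structure(list(mask = decode_mask(genotype), error_rate = 0,
                   n_selected = as.integer(n_sel),
                   fitness = 1 - n_sel / nvar),
              class = "evaluated_solution")
  }
  attr(f, "state") <- new.env()
  g <- rep(0, nvar); g[c(2, 4, 8, 11, 13)] <- 1
  w <- eval_widow(new_widow(g), f)
  res <- stream_do(rng_stream(3), destruct(w, 3))
  rebuilt <- construct_greedy(res$partial, res$removed, f)
  expect_setequal(which(rebuilt$genotype > 0.5), c(2, 4, 8, 11, 13))
})

test_that("acceptance is improve-always, reject-at-zero-T, calibrated at dE = T", {
  expect_true(accept_candidate(0.2, 0.1, 0))
  expect_true(accept_candidate(0.2, 0.1, 5))
  stream_do(rng_stream(1), {
    for (i in 1:50) expect_false(accept_candidate(0.1, 0.2, 0))
  })
  # dE == T: empirical acceptance over 10,000 draws near exp(-1)
  acc <- stream_do(rng_stream(42), {
    mean(vapply(1:10000, function(i) accept_candidate(0.1, 0.1 + 0.05, 0.05),
                logical(1)))
  })
  expect_lt(abs(acc - exp(-1)), 0.01)
  expect_error(accept_candidate(0.1, 0.2, -1), "temperature")
})

test_that("IG refinement never degrades and tracks best-so-far monotonically", {
  fix <- tiny_fixture()
  evaluator <- make_evaluator(fix$dataset, tiny_spec())
  # start at the exhaustive optimum: the returned best matches it
  opt <- tiny_optimum()
  g_opt <- as.numeric(opt$mask)
  start <- eval_widow(new_widow(g_opt), evaluator)
  res <- stream_do(rng_stream(5),
                   run_ig(start, fix$dataset, ig_config(), evaluator))
  expect_equal(res$best$eval$fitness, opt$fitness)
  # random starts: output fitness <= input fitness, best trace non-increasing
  for (s in 1:5) {
    w <- eval_widow(random_widow(8, s), evaluator)
    r <- stream_do(rng_stream(s),
                   run_ig(w, fix$dataset, ig_config(), evaluator))
    expect_lte(r$best$eval$fitness, w$eval$fitness)
    expect_true(all(diff(r$best_fitness_history) <= 0))
    # every incumbent worsening coincides with a logged SA acceptance
    ups <- which(diff(r$incumbent_fitness_history) > 0)
    expect_true(all(ups %in% r$sa_accepts))
  }
  # one selected gene, nothing to destroy: best == start
  g1 <- rep(0, 8); g1[3] <- 1
  w1 <- eval_widow(new_widow(g1), evaluator)
  r1 <- stream_do(rng_stream(1),
                  run_ig(w1, fix$dataset, ig_config(ig_iterations = 1),
                         evaluator))
  expect_equal(r1$best$eval, w1$eval)
})

test_that("ig config validates its fields", {
  expect_error(ig_config(d = 0), "d must")
  expect_error(ig_config(ig_iterations = 0), "ig_iterations")
  expect_error(ig_config(t_scale = -1), "t_scale")
  expect_error(ig_config(destruct_frac = 0), "destruct_frac")
})
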