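# Shared fixtures, built in code. Heavyweight objects are memoized so each
# is constructed once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# 20 samples x 8 genes, gene 3 perfectly separates the two classes.
tiny_fixture <- function() {
  memo("tiny", function() generate_tiny_separable(20, 8,
                                                  informative_index = 3,
                                                  seed = 1))
}

tiny_spec <- function() fitness_spec(cv_folds = "loo")

# Exhaustive-search optimum over all 255 non-empty masks of the fixture.
tiny_optimum <- function() {
  memo("tiny_opt", function() exhaustive_search(tiny_fixture()$dataset,
                                                tiny_spec()))
}

# Four 1-D samples at 0, 1/3, 2/3, 1 with alternating labels: under LOOCV
# 1-NN every sample's nearest neighbour (ties to the lower index) carries
# the opposite label.
adversarial_4sample <- function() {
  expression_dataset(matrix(c(0, 1 / 3, 2 / 3, 1), ncol = 1),
                     c("A", "B", "A", "B"), "g1",
                     name = "adversarial", normalized = TRUE)
}

# A deterministic evaluator that scores a genotype purely by subset size
# (constant error term): used to test size-monotone behaviour in isolation.
size_penalty_evaluator <- function(nvar, error = 0.5, alpha = 0.99) {
  f <- function(genotype) {
    mask <- decode_mask(genotype)
    n_sel <- sum(mask)
    fit <- if (n_sel == 0) 1 else alpha * error + (1 - alpha) * n_sel / nvar
    structure(list(mask = mask, error_rate = if (n_sel == 0) 1 else error,
                   n_selected = as.integer(n_sel), fitness = fit),
              class = "evaluated_solution")
  }
  state <- new.env(parent = emptyenv())
  state$count <- 0L
  attr(f, "state") <- state
  attr(f, "spec") <- fitness_spec(alpha = alpha)
  f
}

random_widow <- function(nvar, seed) {
  stream_do(rng_stream(seed), new_widow(stats::runif(nvar)))
}
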