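# Rate-based core model: branch nonlinearity, tree outputs, WTA readout,
# margins, leak calibration.

test_that("branch nonlinearity is a thresholded square", {
  expect_equal(branch_nonlinearity(5, 5), 0)   # boundary inactive
  expect_equal(branch_nonlinearity(2, 5), 0)
  expect_equal(branch_nonlinearity(8, 5), 9)
  # nonnegative, zero below the leak, strictly increasing above it
  z <- seq(-3, 10, by = 0.25)
  b <- branch_nonlinearity(z, 2)
  expect_true(all(b >= 0))
  expect_true(all(b[z <= 2] == 0))
  above <- b[z > 2]
  expect_true(all(diff(above) > 0))
})

test_that("tree output sums branch nonlinearities over dendrites", {
  expect_equal(tree_output(matrix(c(1, 1, 0), 1), 0, c(0, 0, 0)), 0)
  expect_equal(tree_output(matrix(c(2, 1, 0), 1), 0, c(1, 0, 1)), 4)
  W <- rbind(c(1, 1, 0), c(0, 1, 1))
  expect_equal(tree_output(W, c(1, 1), c(1, 1, 1)), 2)
  expect_error(tree_output(W, c(1, 1), c(1, 1)), "length")
})

test_that("class scores are PDT minus NDT and vanish under symmetry", {
  W <- rbind(c(1, 1, 0), c(0, 1, 1))
  sym <- make_toy_model(list(list(pdt = W, ndt = W),
                             list(pdt = W, ndt = W)), k = 2)
  for (x in list(c(0, 0, 0), c(1, 0, 1), c(1, 1, 1))) {
    expect_equal(class_scores(sym, x), c(0, 0))
  }
  # PDT from the two-dendrite example, silent NDT -> o = its tree output
  W0 <- rbind(c(2, 0, 0), c(0, 2, 0))        # never matches x below
  mod <- make_toy_model(list(list(pdt = W, ndt = W0),
                             list(pdt = W0, ndt = W0)), k = 2,
                        zleak = c(1, 1))
  x <- c(1, 1, 1)
  # pdt: (2-1)^2 + (2-1)^2 = 2 ; ndt: (2-1)^2+(2-1)^2 = 2 with zleak 1
  expect_equal(class_scores(mod, x)[1],
               tree_output(W, c(1, 1), x) - tree_output(W0, c(1, 1), x))
})

test_that("WTA decision is one-hot with lowest-index tie breaking", {
  expect_equal(wta_decision(c(3, 1, 0)), c(1L, 0L, 0L))
  expect_equal(wta_decision(c(2, 2, 0)), c(1L, 0L, 0L))
  expect_equal(wta_decision(c(0, 0, 0)), c(1L, 0L, 0L))
  expect_error(wta_decision(numeric(0)), "empty")
  # invariant under adding a constant to all scores
  set.seed(42)
  for (i in 1:25) {
    o <- rnorm(5)
    expect_equal(wta_decision(o), wta_decision(o + runif(1, -10, 10)))
  }
})

test_that("margin output function matches the ramp definition", {
  expect_equal(g_margin(0.4, 0.4), 1)
  expect_equal(g_margin(0, 0.4), 0.5)
  expect_equal(g_margin(-0.4, 0.4), 0)
  expect_equal(g_margin(1, 2), 0.75)
  # delta = 0 degenerates to the hard threshold with g(0) = 0.5
  expect_equal(g_margin(c(-1, 0, 1), 0), c(0, 0.5, 1))
  # nondecreasing, bounded, pointwise convergence to hard g as delta -> 0
  a <- seq(-2, 2, by = 0.1)
  for (delta in c(2, 0.5, 0.01)) {
    y <- g_margin(a, delta)
    expect_true(all(diff(y) >= 0))
    expect_true(all(y >= 0 & y <= 1))
  }
  nz <- a[a != 0]
  expect_equal(g_margin(nz, 1e-12), as.numeric(nz > 0))
})

test_that("margin outputs ramp between the true class and its competitor", {
  W1 <- matrix(c(2, 0), 1)   # responds to afferent 1
  W2 <- matrix(c(0, 2), 1)   # responds to afferent 2
  W0 <- matrix(c(1, 1), 1)
  mod <- make_toy_model(list(list(pdt = W1, ndt = W0),
                             list(pdt = W2, ndt = W0)), k = 2)
  x <- c(1, 0)
  o <- class_scores(mod, x)           # (4 - 1, 0 - 1) = (3, -1)
  expect_equal(o, c(3, -1))
  # outside the margin: crisp outputs
  mod$delta <- c(2, 2)
  expect_equal(margin_outputs(mod, x, 1), c(1, 0))
  # inside the margin: ramp values 0.5 * alpha/delta + 0.5
  mod$delta <- c(8, 8)
  expect_equal(margin_outputs(mod, x, 1), c(0.75, 0.25))
  # tie case gives 0.5 / 0.5
  xt <- c(1, 1)
  expect_equal(class_scores(mod, xt)[1], class_scores(mod, xt)[2])
  expect_equal(margin_outputs(mod, xt, 1), c(0.5, 0.5))
})

test_that("leak levels are mean synaptic drives of the initial wiring", {
  W <- matrix(c(1, 1), 1)
  X <- rbind(c(1, 0), c(1, 1))
  expect_equal(compute_zleak(W, X), 1.5)
  expect_equal(compute_zleak(W, matrix(0, 3, 2)), 0)
  expect_error(compute_zleak(W, X[0, , drop = FALSE]), "empty")
  expect_error(compute_zleak(rbind(c(1, 1), c(0, 0)), X), "empty dendrite")
})

test_that("connection matrices enforce the fixed row-sum wiring rule", {
  expect_error(connection_matrix(rbind(c(1, 1, 0), c(1, 1, 1)), k = 2),
               "exactly k")
  expect_error(connection_matrix(matrix(c(-1, 3), 1), k = 2), "nonnegative")
  expect_silent(connection_matrix(matrix(c(2, 1, 0), 1), k = 3))
  set.seed(7)
  for (i in 1:20) {
    W <- random_connections(m = 5, k = 4, d = 12)
    expect_equal(unname(rowSums(W)), rep(4, 5))
  }
})

test_that("models serialize to JSON and back without changing predictions", {
  set.seed(11)
  ps <- synth_patterns(n_per_class = 10, seed = 3)
  fit <- dendnet_fit(ps$X, ps$labels, m = 3, k = 4, seed = 5,
                     params = learn_params(n_min = 5))
  path <- tempfile(fileext = ".json")
  write_dendnet_model(fit$model, path, seed = 5)
  back <- read_dendnet_model(path)
  expect_equal(back$delta, fit$model$delta)
  expect_equal(predict(back, ps$X), predict(fit$model, ps$X))
  expect_equal(score_matrix(back, ps$X), score_matrix(fit$model, ps$X))
})
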