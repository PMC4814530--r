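# Structural-plasticity learning rule: correlation maps, target/replacement
# selection, margin calibration, and the full training loop.

test_that("correlation map matches the per-pattern loop oracle", {
  set.seed(21)
  for (rep in 1:5) {
    d <- sample(4:10, 1)
    P <- sample(5:20, 1)
    nc <- sample(2:3, 1)
    ps <- synth_patterns(n_classes = nc, d = d, n_per_class = ceiling(P / nc),
                         prototypes = 1, noise = 0.2)
    X <- ps$X[seq_len(P), , drop = FALSE]
    labels <- ps$labels[seq_len(P)]
    model <- set_leak(dendnet_model(d, nc, m = 2, k = 2), X)
    model$delta <- runif(nc, 0, 2)   # exercise the margin readout too
    for (mu in seq_len(nc)) {
      for (side in c("pdt", "ndt")) {
        expect_equal(correlation_map(model, X, labels, mu, side),
                     oracle_correlation(model, X, labels, mu, side),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("correlation map trivial structure: zero on solved batches and silent columns", {
  W1 <- matrix(c(3, 0, 0), 1); W2 <- matrix(c(0, 3, 0), 1)
  W0 <- matrix(c(0, 0, 3), 1)
  mod <- make_toy_model(list(list(pdt = W1, ndt = W0),
                             list(pdt = W2, ndt = W0)), k = 3)
  X <- rbind(c(1, 0, 0), c(0, 1, 0))
  labels <- c(1, 2)
  # both patterns solved crisply -> sgn = 0 everywhere -> map identically 0
  for (mu in 1:2) {
    expect_equal(correlation_map(mod, X, labels, mu, "pdt"),
                 matrix(0, 1, 3))
  }
  # an afferent never active contributes a zero column even when unsolved
  labels_bad <- c(2, 1)
  cmap <- correlation_map(mod, X, labels_bad, 1, "pdt")
  expect_equal(cmap[, 3], 0)
  # direct hand value: pattern 1 (x_1 = 1) has b = 9, y_d^1 = 0, y^1 = 1
  # -> sgn = -1 -> c_PDT[1,1] = mean(-9, 0) = -4.5; NDT negates
  expect_equal(cmap[1, 1], -4.5)
  # the inhibitory tree's own branch is silent for that pattern (b = 0),
  # so its negated correlation is zero here
  expect_equal(correlation_map(mod, X, labels_bad, 1, "ndt")[1, 1], 0)
})

test_that("target picking finds the worst sampled synapse deterministically", {
  W <- rbind(c(2, 1, 0), c(0, 1, 2))
  C <- rbind(c(0.5, -0.2, 9), c(9, 0.3, -0.7))
  # n_T = s = 6 samples every active slot: global minimum is (2, 3)
  set.seed(1)
  tgt <- pick_target(W, C, n_T = 6)
  expect_equal(tgt$dendrite, 2)
  expect_equal(tgt$afferent, 3)
  # single-synapse matrix returns that synapse
  tgt1 <- pick_target(matrix(c(0, 1), 1), matrix(c(0, 0), 1), n_T = 1)
  expect_equal(tgt1$afferent, 2)
  expect_error(pick_target(W, C, n_T = 7), "exceeds")
  # same seed, same selection
  set.seed(99); a <- pick_target(W, C, 3)
  set.seed(99); b <- pick_target(W, C, 3)
  expect_identical(a, b)
})

test_that("replacement picking takes the argmax silent candidate", {
  C <- matrix(c(0.1, 0.9, 0.4), 1)
  expect_equal(propose_replacement(C, 1, n_R = 3), 2)
  # all-equal correlations: first candidate index wins
  Ceq <- matrix(c(0.2, 0.2, 0.2), 1)
  expect_equal(propose_replacement(Ceq, 1, n_R = 3), 1)
  # n_R = 1 returns the sole candidate
  set.seed(5)
  r <- propose_replacement(C, 1, n_R = 1)
  expect_true(r %in% 1:3)
})

test_that("margins are the largest adversarial score excursions", {
  W1 <- matrix(c(2, 0), 1); W2 <- matrix(c(0, 2), 1)
  W0 <- matrix(c(0, 0) + c(1, 1), 1)
  mod <- make_toy_model(list(list(pdt = W1, ndt = W0),
                             list(pdt = W2, ndt = W0)), k = 2)
  # perfectly classified validation set -> all margins zero
  Xok <- rbind(c(1, 0), c(0, 1))
  m0 <- set_margins(mod, Xok, c(1, 2))
  expect_equal(m0$delta, c(0, 0))
  # mislabeled copies: class 1 loses by alpha = o2 - o1 = 3 - (-1) = 4
  m1 <- set_margins(mod, rbind(c(0, 1), c(0, 1)), c(1, 1))
  expect_equal(m1$delta, c(4, 0))
  expect_error(set_margins(mod, Xok[0, , drop = FALSE], integer(0)), "empty")
})

test_that("training memorizes orthogonal patterns and respects budgets", {
  set.seed(31)
  X <- matrix(0, 4, 16); for (i in 1:4) X[i, (i - 1) * 4 + 1:4] <- 1
  labels <- 1:4
  model <- set_leak(dendnet_model(16, 4, m = 2, k = 2), X)
  fit <- train_structural(model, X, labels,
                          learn_params(n_T = 4, n_R = 8, n_min = 150))
  expect_equal(fit$error, 0)
  expect_equal(misclassification_rate(fit$model, X, labels, margin = FALSE), 0)
  # n_min = 0: the loop never runs, wiring is returned unchanged
  model2 <- set_leak(dendnet_model(16, 4, m = 2, k = 2), X)
  fit0 <- train_structural(model2, X, labels, learn_params(n_min = 0))
  expect_equal(fit0$model$trees, model2$trees)
  expect_equal(nrow(fit0$history), 0)
})

test_that("row sums stay at k through every accepted and forced swap", {
  set.seed(41)
  ps <- synth_patterns(n_per_class = 15, noise = 0.25, seed = 8)
  model <- set_leak(dendnet_model(64, 4, m = 3, k = 5), ps$X)
  fit <- train_structural(model, ps$X, ps$labels,
                          learn_params(n_min = 10, n_ch = 10))
  expect_gt(nrow(fit$events), 0)
  for (mu in 1:4) {
    for (side in c("pdt", "ndt")) {
      expect_equal(unname(rowSums(fit$model$trees[[mu]][[side]]$W)),
                   rep(5, 3))
    }
  }
  # best-so-far error is non-increasing; forced escapes are logged
  expect_true(all(diff(fit$history$best_error) <= 0))
  if (fit$minima > 0) expect_true(any(fit$events$forced))
})

test_that("training is reproducible and usually solves separable two-class data", {
  ps <- synth_patterns(n_classes = 2, d = 32, n_per_class = 20,
                       prototypes = 1, noise = 0.05, seed = 12)
  solved <- 0
  for (s in 1:10) {
    fit <- dendnet_fit(ps$X, ps$labels, m = 6, k = 4, seed = s,
                       margin = FALSE)
    if (fit$error == 0) solved <- solved + 1
  }
  expect_gte(solved, 9)
  # identical seeds give identical trajectories
  f1 <- dendnet_fit(ps$X, ps$labels, m = 4, k = 4, seed = 77)
  f2 <- dendnet_fit(ps$X, ps$labels, m = 4, k = 4, seed = 77)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model, f2$model)
})

test_that("exhaustive candidate sets reduce to greedy best-swap on tiny instances", {
  # with n_T = s and n_R = d the target is the global minimum of C over
  # active slots and the replacement the global argmax on that dendrite;
  # verify against an exhaustive search over all (slot, afferent) pairs
  set.seed(51)
  for (rep in 1:10) {
    d <- 6
    W <- random_connections(2, 2, d)
    C <- matrix(rnorm(2 * d), 2, d)
    tgt <- pick_target(W, C, n_T = sum(W))
    slots <- which(W > 0, arr.ind = TRUE)
    vals <- C[slots]
    expect_equal(C[tgt$dendrite, tgt$afferent], min(vals))
    r <- propose_replacement(C, tgt$dendrite, n_R = d)
    expect_equal(C[tgt$dendrite, r], max(C[tgt$dendrite, ]))
  }
})
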