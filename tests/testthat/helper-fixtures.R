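# Shared fixtures: tiny hand-constructed models and the synthetic study
# benchmarks used across the suite.

# a model with fully specified wiring (no randomness): W_list is a list of
# per-class lists(pdt = W, ndt = W), zleak defaults to zero
make_toy_model <- function(W_list, k, zleak = NULL) {
  d <- ncol(W_list[[1]]$pdt)
  nc <- length(W_list)
  model <- structure(
    list(trees = lapply(W_list, function(tp) {
      lapply(tp, function(W) {
        list(W = W, zleak = if (is.null(zleak)) rep(0, nrow(W)) else zleak)
      })
    }),
    delta = rep(0, nc), d = d, k = k, n_classes = nc),
    class = "dendnet_model")
  model
}

# the package's standard synthetic benchmark: 4 classes, d = 64,
# 2 prototypes per class, 5% flip noise, 50 patterns per class
bench_train <- function(seed) synth_patterns(seed = seed)
bench_test <- function(protos, seed) {
  synth_patterns(proto_list = protos, seed = seed)
}

# benchmark with one deliberately harder class: class 1 is an 8-prototype,
# high-variability (25% flip) category with more samples; classes 2-4 are
# clean unimodal categories
bench_hard_class <- function(seed) {
  synth_patterns(n_classes = 4, d = 40, n_per_class = c(200, 50, 50, 50),
                 prototypes = c(8, 1, 1, 1), noise = c(0.25, 0, 0, 0),
                 seed = seed)
}

# brute-force per-pattern correlation oracle (independent of the matrix
# implementation): c[j,i] = mean_p x_i * b_j(x) * sgn(yd - y), sign flipped
# for the negative tree, y from the margin readout
oracle_correlation <- function(model, X, labels, mu, side) {
  P <- nrow(X)
  tree <- model$trees[[mu]][[side]]
  m <- nrow(tree$W); d <- ncol(tree$W)
  C <- matrix(0, m, d)
  for (p in seq_len(P)) {
    x <- X[p, ]
    y <- margin_outputs(model, x, labels[p])
    sgn <- sign((labels[p] == mu) - y[mu])
    if (side == "ndt") sgn <- -sgn
    z <- as.vector(tree$W %*% x)
    b <- branch_nonlinearity(z, tree$zleak)
    C <- C + sgn * outer(b, x)
  }
  C / P
}

# exact event-driven LIF oracle for piecewise-constant input: between
# spikes the linear system has the closed-form solution
#   V(t) = I + B exp(-t/tau_u) + C exp(-t/tau_V),  B = u0 tau_u/(tau_u-tau_V)
# and threshold crossings are found by root bracketing
oracle_lif_constant <- function(I, duration, p) {
  t <- 0; V <- 0; u <- 0; n <- 0
  while (t < duration) {
    B <- u * p$tau_u / (p$tau_u - p$tau_V)
    C <- V - I - B
    f <- function(s) I + B * exp(-s / p$tau_u) + C * exp(-s / p$tau_V) - p$V_thr
    ss <- seq(1e-6, duration - t, length.out = 4000)
    vals <- f(ss)
    idx <- which(vals >= 0)[1]
    if (is.na(idx)) break
    s_cross <- if (idx == 1) ss[1] else
      stats::uniroot(f, c(ss[idx - 1], ss[idx]))$root
    t <- t + s_cross
    if (t >= duration) break
    V <- p$V_reset; u <- p$u_reset; n <- n + 1
  }
  n
}
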