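#' dendnet: neurons with nonlinear dendrites and binary synapses
#'
#' A multiclass classifier whose neurons carry `m` dendritic branches with
#' `k` synaptic contacts each, drawn from `d` input afferents. Each branch
#' applies a lumped quadratic nonlinearity to its summed synaptic drive; a
#' class score is the output of an excitatory ("positive") dendritic tree
#' minus that of an inhibitory ("negative") tree, and the decision is
#' winner-take-all over class scores. Learning modifies which connections
#' exist (structural plasticity), never analog weights.
#'
#' @keywords internal
"_PACKAGE"

# ---- connection matrices ----------------------------------------------------

#' Validate a connection matrix
#'
#' A connection matrix is an `m x d` matrix of nonnegative integer
#' multiplicities with every row summing exactly to `k`: each dendrite holds
#' exactly `k` synaptic contacts, possibly several from the same afferent.
#'
#' @param W integer matrix, dendrites in rows, afferents in columns.
#' @param k synapses per dendrite.
#' @return `W` invisibly, with a `"k"` attribute set.
#' @export
connection_matrix <- function(W, k) {
  W <- as.matrix(W)
  if (any(W < 0) || any(W != round(W)))
    stop("connection matrix entries must be nonnegative integers")
  rs <- rowSums(W)
  if (any(rs != k))
    stop("every dendrite row must hold exactly k = ", k, " synapses")
  storage.mode(W) <- "double"
  attr(W, "k") <- k
  invisible(W)
}

#' Draw a random connection matrix
#'
#' Initial wiring: each of the `m` dendrites receives `k` unit contacts from
#' afferents drawn uniformly without replacement from the `d` input lines
#' (all multiplicities start at 1). Multiplicities above 1 arise later, when
#' learning re-targets a contact onto an afferent already present.
#'
#' @param m dendrites, @param k synapses per dendrite, @param d afferents.
#' @return an `m x d` connection matrix with row sums `k`.
#' @export
random_connections <- function(m, k, d) {
  W <- matrix(0, m, d)
  for (j in seq_len(m)) {
    aff <- sample.int(d, k, replace = k > d)
    W[j, ] <- tabulate(aff, nbins = d)
  }
  W
}

# ---- dendritic nonlinearity -------------------------------------------------

#' Branch nonlinearity
#'
#' The lumped dendritic nonlinearity `b(z) = g(z - zleak) * (z - zleak)^2`,
#' where `g` is a Heaviside step that is 1 where its argument is strictly
#' positive (so the boundary `z == zleak` is inactive) and `zleak` is the
#' branch's resting activation, the mean synaptic drive of the branch's
#' initial random wiring.
#'
#' @param z synaptic activation (scalar or vector).
#' @param zleak branch leak level(s), recycled against `z`.
#' @return nonnegative squared supra-leak activation.
#' @export
branch_nonlinearity <- function(z, zleak) {
  a <- z - zleak
  out <- ifelse(a > 0, a * a, 0)
  out
}

#' Dendritic tree output for one binary pattern
#'
#' Sums the branch nonlinearity over all dendrites of one tree:
#' `a(x) = sum_j b(sum_i W[j,i] x[i])`.
#'
#' @param W connection matrix (`m x d`).
#' @param zleak length-`m` branch leak levels.
#' @param x binary input vector of length `d`.
#' @return scalar tree output, `>= 0`.
#' @export
tree_output <- function(W, zleak, x) {
  if (length(x) != ncol(W)) stop("input length does not match afferent count")
  if (length(zleak) != nrow(W)) stop("zleak length does not match dendrite count")
  z <- as.vector(W %*% x)
  sum(branch_nonlinearity(z, zleak))
}

# internal: branch outputs for all patterns at once.
# Xt is the d x P transposed pattern matrix; returns m x P matrix of b values.
branch_matrix <- function(W, zleak, Xt) {
  Z <- W %*% Xt
  A <- Z - zleak
  A[A <= 0] <- 0
  A * A
}

#' Branch leak levels from initial wiring
#'
#' The leak of branch `j` is the average synaptic activation
#' `mean_p sum_i W[j,i] x_p[i]` over the training patterns, computed once
#' from the tree's initial random connections and then frozen for the rest
#' of training. It balances excitation by subtracting the branch's mean
#' drive, playing the role of tonic inhibition.
#'
#' @param W the tree's initial connection matrix.
#' @param X `P x d` binary pattern matrix.
#' @return length-`m` vector of leak levels.
#' @export
compute_zleak <- function(W, X) {
  X <- as.matrix(X)
  if (nrow(X) < 1) stop("empty pattern set")
  if (ncol(X) != ncol(W)) stop("pattern width does not match afferent count")
  if (any(rowSums(W) == 0)) stop("connection matrix has an empty dendrite row")
  as.vector(W %*% colMeans(X))
}

# ---- model ------------------------------------------------------------------

#' Construct a randomly wired multiclass dendritic classifier
#'
#' One pair of dendritic trees per class: a positive (excitatory, PDT) and a
#' negative (inhibitory, NDT) tree, each with `m` dendrites of `k` synapses
#' wired at random from the `d` afferents. Branch leak levels are zero until
#' [set_leak()] fixes them against a training set. Per-class margins `delta`
#' start at zero (hard decisions).
#'
#' @param d afferent count.
#' @param n_classes number of classes (>= 2).
#' @param m dendrites per tree; scalar or per-class vector.
#' @param k synapses per dendrite.
#' @return an object of class `"dendnet_model"`.
#' @export
dendnet_model <- function(d, n_classes, m, k) {
  if (n_classes < 2) stop("need at least two classes")
  m <- rep_len(m, n_classes)
  trees <- lapply(seq_len(n_classes), function(mu) {
    list(
      pdt = list(W = random_connections(m[mu], k, d), zleak = rep(0, m[mu])),
      ndt = list(W = random_connections(m[mu], k, d), zleak = rep(0, m[mu]))
    )
  })
  structure(
    list(trees = trees, delta = rep(0, n_classes),
         d = d, k = k, n_classes = n_classes),
    class = "dendnet_model"
  )
}

#' Fix branch leak levels from a training set
#'
#' @param model a `dendnet_model`.
#' @param X `P x d` binary training patterns.
#' @return the model with `zleak` set on every tree.
#' @export
set_leak <- function(model, X) {
  for (mu in seq_len(model$n_classes)) {
    for (side in c("pdt", "ndt")) {
      model$trees[[mu]][[side]]$zleak <-
        compute_zleak(model$trees[[mu]][[side]]$W, X)
    }
  }
  model
}

#' Class scores for one pattern
#'
#' `o_mu(x) = a_PDT(x) - a_NDT(x)` for every class `mu`.
#'
#' @param model a `dendnet_model`.
#' @param x binary input vector of length `d`.
#' @return numeric vector of `n_classes` scores.
#' @export
class_scores <- function(model, x) {
  if (length(x) != model$d) stop("input length does not match afferent count")
  vapply(model$trees, function(tp) {
    tree_output(tp$pdt$W, tp$pdt$zleak, x) -
      tree_output(tp$ndt$W, tp$ndt$zleak, x)
  }, numeric(1))
}

#' Class-score matrix for a pattern set
#'
#' @param model a `dendnet_model`.
#' @param X `P x d` binary pattern matrix.
#' @return `n_classes x P` score matrix.
#' @export
score_matrix <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$d) stop("pattern width does not match afferent count")
  Xt <- t(X)
  O <- matrix(0, model$n_classes, nrow(X))
  for (mu in seq_len(model$n_classes)) {
    tp <- model$trees[[mu]]
    O[mu, ] <- colSums(branch_matrix(tp$pdt$W, tp$pdt$zleak, Xt)) -
      colSums(branch_matrix(tp$ndt$W, tp$ndt$zleak, Xt))
  }
  O
}

# ---- readout ----------------------------------------------------------------

#' Winner-take-all decision
#'
#' Returns a one-hot vector with the 1 at the maximal score; ties are broken
#' deterministically in favour of the lowest class index.
#'
#' @param o score vector.
#' @return one-hot integer vector of the same length.
#' @export
wta_decision <- function(o) {
  if (length(o) == 0) stop("empty score vector")
  y <- integer(length(o))
  y[which.max(o)] <- 1L
  y
}

#' Margin output function
#'
#' Training-time soft readout `g_margin(alpha)`: 1 for `alpha >= delta`,
#' 0 for `alpha <= -delta`, and the linear ramp `0.5 * alpha/delta + 0.5`
#' in between. At `delta == 0` it degenerates to a hard threshold with
#' value 0.5 at `alpha == 0`.
#'
#' @param alpha score difference(s).
#' @param delta margin half-width, `>= 0`.
#' @return value(s) in `[0, 1]`.
#' @export
g_margin <- function(alpha, delta) {
  if (delta < 0) stop("delta must be nonnegative")
  if (delta == 0) return(ifelse(alpha > 0, 1, ifelse(alpha < 0, 0, 0.5)))
  pmin(1, pmax(0, 0.5 * alpha / delta + 0.5))
}

#' Margin-thresholded output vector for one pattern
#'
#' With `mu` the pattern's true class and `nu` its strongest competitor,
#' the `mu` and `nu` components pass through [g_margin()] with the class-`mu`
#' margin; all other components follow the hard winner-take-all rule (and are
#' therefore 0, since they cannot strictly exceed `nu`).
#'
#' @param model a `dendnet_model` with margins set.
#' @param x binary input vector.
#' @param true_class index of the pattern's class.
#' @return numeric vector in `[0, 1]^n_classes`.
#' @export
margin_outputs <- function(model, x, true_class) {
  o <- class_scores(model, x)
  y <- numeric(model$n_classes)
  others <- setdiff(seq_len(model$n_classes), true_class)
  nu <- others[which.max(o[others])]
  delta <- model$delta[true_class]
  y[true_class] <- g_margin(o[true_class] - o[nu], delta)
  y[nu] <- g_margin(o[nu] - o[true_class], delta)
  y
}

# internal: vectorized per-pattern correctness under the margin metric.
# A pattern is correct iff its full margin output vector equals the one-hot
# teacher: alpha = o_true - max_other must reach delta (strictly exceed 0
# when delta == 0).
margin_correct <- function(O, labels, delta) {
  P <- ncol(O)
  idx <- cbind(labels, seq_len(P))
  o_true <- O[idx]
  O2 <- O
  O2[idx] <- -Inf
  o_comp <- apply(O2, 2, max)
  alpha <- o_true - o_comp
  dl <- delta[labels]
  ifelse(dl > 0, alpha >= dl, alpha > 0)
}

#' Misclassification rate of a model on a pattern set
#'
#' With `margin = TRUE` (the training-time metric) a pattern counts as
#' correct only when its margin output vector reproduces the one-hot teacher
#' signal, i.e. the true class beats its best competitor by at least the
#' class margin. With `margin = FALSE` (the test-time metric) the hard
#' winner-take-all argmax is compared with the label.
#'
#' @param model a `dendnet_model`.
#' @param X `P x d` binary patterns.
#' @param labels length-`P` class indices.
#' @param margin use the margin metric (default) or hard WTA.
#' @return fraction of misclassified patterns.
#' @export
misclassification_rate <- function(model, X, labels, margin = TRUE) {
  O <- score_matrix(model, X)
  if (margin) {
    mean(!margin_correct(O, labels, model$delta))
  } else {
    pred <- max.col(t(O), ties.method = "first")
    mean(pred != labels)
  }
}

#' Predict class labels with hard winner-take-all readout
#'
#' @param object a `dendnet_model`.
#' @param X `P x d` binary pattern matrix.
#' @param ... unused.
#' @return integer vector of predicted class indices.
#' @export
predict.dendnet_model <- function(object, X, ...) {
  O <- score_matrix(object, X)
  max.col(t(O), ties.method = "first")
}

#' @export
print.dendnet_model <- function(x, ...) {
  m <- vapply(x$trees, function(tp) nrow(tp$pdt$W), numeric(1))
  cat("Dendritic classifier:", x$n_classes, "classes,", x$d, "afferents\n")
  cat("  dendrites per tree:", paste(m, collapse = " "),
      " (k =", x$k, "synapses/dendrite)\n")
  cat("  total synapses:", sum(2 * m * x$k), "\n")
  cat("  margins:", paste(signif(x$delta, 3), collapse = " "), "\n")
  invisible(x)
}
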