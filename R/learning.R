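# Correlation-based structural plasticity: learning modifies which afferent
# each synaptic contact touches, never an analog weight. Per tree and
# iteration one poorly correlated contact is re-targeted to the best of a
# random set of silent candidate synapses; swaps that raise the training
# error are reverted, and a stretch of n_ch consecutive rejections counts as
# a local minimum, escaped by forcing the last candidate swap through.

#' Learning-rule parameters
#'
#' @param n_T candidate-set size: active synapses sampled per replacement
#'   attempt (the worst-correlated of these is targeted).
#' @param n_R replacement-set size: silent synapses placed on the target
#'   dendrite as candidates (must be < `d`).
#' @param n_ch consecutive rejected replacements that define a local
#'   minimum (default 50).
#' @param n_min local-minima budget before training stops (default 150).
#' @param decay_factor margin shrink factor applied when training keeps
#'   revisiting the same minimum (default 0.8).
#' @param decay_runs number of consecutive identical minima that trigger
#'   the margin decay (default 5).
#' @param max_iter hard cap on training iterations (safety valve).
#' @return a list of class `"dendnet_params"`.
#' @export
learn_params <- function(n_T = 25, n_R = 25, n_ch = 50, n_min = 150,
                         decay_factor = 0.8, decay_runs = 5,
                         max_iter = 50000) {
  if (n_ch < 1 || n_min < 0) stop("n_ch must be >= 1 and n_min >= 0")
  if (n_T < 1 || n_R < 1) stop("n_T and n_R must be positive")
  structure(list(n_T = n_T, n_R = n_R, n_ch = n_ch, n_min = n_min,
                 decay_factor = decay_factor, decay_runs = decay_runs,
                 max_iter = max_iter),
            class = "dendnet_params")
}

# vectorized margin function with per-pattern delta
gm_vec <- function(alpha, delta) {
  hard <- ifelse(alpha > 0, 1, ifelse(alpha < 0, 0, 0.5))
  ifelse(delta > 0, pmin(1, pmax(0, 0.5 * alpha / delta + 0.5)), hard)
}

# per-pattern score of the best competitor to the true class, plus its index
competitor_scores <- function(O, labels) {
  P <- ncol(O)
  A <- O
  A[cbind(labels, seq_len(P))] <- -Inf
  o_comp <- A[1, ]
  for (cc in seq_len(nrow(A))[-1]) o_comp <- pmax(o_comp, A[cc, ])
  nu <- max.col(t(A), ties.method = "first")
  list(o_comp = o_comp, nu = nu)
}

# margin-metric error computed directly from a score matrix
margin_error <- function(O, labels, delta) {
  comp <- competitor_scores(O, labels)
  alpha <- O[cbind(labels, seq_len(ncol(O)))] - comp$o_comp
  dl <- delta[labels]
  mean(!ifelse(dl > 0, alpha >= dl, alpha > 0))
}

# sign of the teacher error sgn(y_d^mu - y^mu) per pattern, for class mu,
# with y from the margin readout
margin_sgn <- function(O, labels, delta, mu) {
  P <- ncol(O)
  comp <- competitor_scores(O, labels)
  o_true <- O[cbind(labels, seq_len(P))]
  alpha <- o_true - comp$o_comp
  dl <- delta[labels]
  y_mu <- numeric(P)
  own <- labels == mu
  y_mu[own] <- gm_vec(alpha[own], dl[own])
  is_nu <- !own & comp$nu == mu
  y_mu[is_nu] <- gm_vec(-alpha[is_nu], dl[is_nu])
  yd <- as.numeric(own)
  sign(yd - y_mu)
}

#' Correlation map of a dendritic tree
#'
#' The structural-plasticity fitness of every (dendrite, afferent) slot:
#' `c[j, i] = < x_i * b_j(x) * sgn(y_d - y) >` averaged over the batch,
#' negated for the negative (inhibitory) tree. `b_j` is the branch output of
#' the *active* connections only, so the same map also scores silent
#' candidate synapses, which by construction do not contribute to `b_j`.
#' The output `y` is the margin readout of the current model.
#'
#' @param model a `dendnet_model`.
#' @param X `P x d` binary patterns.
#' @param labels length-`P` class indices.
#' @param class class index `mu` whose tree is scored.
#' @param side `"pdt"` or `"ndt"`.
#' @return `m x d` correlation matrix.
#' @export
correlation_map <- function(model, X, labels, class, side = c("pdt", "ndt")) {
  side <- match.arg(side)
  X <- as.matrix(X)
  O <- score_matrix(model, X)
  s <- margin_sgn(O, labels, model$delta, class)
  if (side == "ndt") s <- -s
  tree <- model$trees[[class]][[side]]
  B <- branch_matrix(tree$W, tree$zleak, t(X))
  (B %*% (X * s)) / nrow(X)
}

#' Pick the replacement target among randomly sampled active synapses
#'
#' Samples `n_T` active synapse slots (counting multiplicity) uniformly
#' without replacement and returns the one with the lowest correlation;
#' ties fall to the first in sampling order.
#'
#' @param W connection matrix.
#' @param C correlation map of the same tree.
#' @param n_T candidate-set size.
#' @return list with `afferent` (i*) and `dendrite` (j_T).
#' @export
pick_target <- function(W, C, n_T) {
  nz <- which(W > 0)
  counts <- W[nz]
  jj <- rep(((nz - 1L) %% nrow(W)) + 1L, counts)
  ii <- rep(((nz - 1L) %/% nrow(W)) + 1L, counts)
  s <- length(jj)
  if (n_T > s) stop("n_T exceeds the number of active synapses")
  pick <- sample.int(s, n_T)
  cv <- C[cbind(jj[pick], ii[pick])]
  w <- which.min(cv)
  list(afferent = ii[pick][w], dendrite = jj[pick][w])
}

#' Pick the best silent replacement synapse on a dendrite
#'
#' Places `n_R` silent candidate synapses on dendrite `j_T`, drawn uniformly
#' without replacement from the `d` input lines, and returns the afferent
#' with the highest correlation (first index on ties). The candidate may
#' duplicate an afferent already connected, in which case its multiplicity
#' will be incremented.
#'
#' @param C correlation map of the tree.
#' @param j_T target dendrite index.
#' @param n_R replacement-set size (< number of afferents).
#' @return the chosen afferent index.
#' @export
propose_replacement <- function(C, j_T, n_R) {
  d <- ncol(C)
  if (n_R >= d + 1) stop("n_R must not exceed the number of afferents")
  cand <- if (n_R >= d) seq_len(d) else sample.int(d, n_R)
  cand[which.max(C[j_T, cand])]
}

#' Set per-class margins from a validation set
#'
#' Presents the validation patterns to a model pre-trained with the hard
#' readout, records `alpha = o^nu - o^mu` for every pattern of class `mu`
#' misclassified as `nu`, and sets `delta^mu` to the largest such excursion
#' (0 when class `mu` has no validation errors).
#'
#' @param model a `dendnet_model`.
#' @param X `P x d` validation patterns.
#' @param labels validation class indices.
#' @return the model with its `delta` vector set.
#' @export
set_margins <- function(model, X, labels) {
  X <- as.matrix(X)
  if (nrow(X) < 1) stop("empty validation set")
  O <- score_matrix(model, X)
  pred <- max.col(t(O), ties.method = "first")
  delta <- numeric(model$n_classes)
  wrong <- which(pred != labels)
  for (p in wrong) {
    mu <- labels[p]
    alpha <- O[pred[p], p] - O[mu, p]
    if (alpha > delta[mu]) delta[mu] <- alpha
  }
  model$delta <- delta
  model
}

# internal: mutable training state with cached per-tree branch activations
# Z (m x P synaptic drive), B (m x P branch outputs) and the score matrix O.
build_state <- function(model, X) {
  Xt <- t(X)
  trees <- lapply(model$trees, function(tp) {
    lapply(tp, function(tr) {
      Z <- tr$W %*% Xt
      A <- Z - tr$zleak
      A[A <= 0] <- 0
      list(W = tr$W, zleak = tr$zleak, Z = Z, B = A * A)
    })
  })
  O <- matrix(0, model$n_classes, nrow(X))
  for (mu in seq_len(model$n_classes)) {
    O[mu, ] <- colSums(trees[[mu]]$pdt$B) - colSums(trees[[mu]]$ndt$B)
  }
  list(trees = trees, O = O, Xt = Xt)
}

state_to_model <- function(model, st) {
  for (mu in seq_len(model$n_classes)) {
    for (side in c("pdt", "ndt")) {
      model$trees[[mu]][[side]]$W <- st$trees[[mu]][[side]]$W
      model$trees[[mu]][[side]]$zleak <- st$trees[[mu]][[side]]$zleak
    }
  }
  model
}

#' Train a dendritic classifier by structural plasticity
#'
#' Runs the replacement loop on an initialized (and leak-calibrated) model:
#' per iteration each dendritic tree (classes in order, positive tree before
#' negative) gets one replacement attempt. A swap is kept when it does not
#' increase the margin-metric training error and reverted otherwise; `n_ch`
#' consecutive rejections on a tree mark a local minimum, escaped by forcing
#' the last candidate swap through. Training stops when every pattern is
#' memorized or `n_min` local minima have been met, and returns the
#' connection state of the best minimum encountered. When margins are
#' nonzero and the same minimum error recurs `decay_runs` times in a row,
#' all margins shrink to `decay_factor` of their value.
#'
#' @param model a `dendnet_model` (random wiring, leaks set).
#' @param X `P x d` binary training patterns.
#' @param labels length-`P` class indices.
#' @param params a [learn_params()] list.
#' @param growth optional internal growth hook (used by [adaptive_fit()]).
#' @return list with `model` (best checkpoint), `history` (per-iteration
#'   data.frame), `events` (accepted/forced replacement log), `minima`,
#'   and `error` (training error of the returned model).
#' @export
train_structural <- function(model, X, labels, params = learn_params(),
                             growth = NULL) {
  X <- as.matrix(X)
  P <- nrow(X)
  if (length(labels) != P) stop("labels length must match pattern count")
  n_classes <- model$n_classes
  st <- build_state(model, X)
  delta <- model$delta
  err_cur <- margin_error(st$O, labels, delta)
  best_err <- err_cur
  best_snap <- list(trees = st$trees, delta = delta)
  reject <- matrix(0L, n_classes, 2)
  minima <- 0L
  last_min_err <- NA_real_
  same_min <- 0L
  iter <- 0L
  hist_it <- integer(0); hist_err <- numeric(0)
  hist_best <- numeric(0); hist_min <- integer(0)
  ev <- list()
  sides <- c("pdt", "ndt")

  if (!is.null(growth)) growth$init(st, labels, delta)

  while (err_cur > 0 && minima < params$n_min && iter < params$max_iter) {
    iter <- iter + 1L
    stopnow <- FALSE
    for (mu in seq_len(n_classes)) {
      for (si in 1:2) {
        side <- sides[si]
        tree <- st$trees[[mu]][[side]]
        s <- margin_sgn(st$O, labels, delta, mu)
        if (side == "ndt") s <- -s
        C <- (tree$B %*% (X * s)) / P
        # candidate sets cannot exceed the tree's synapse count / input lines
        tgt <- pick_target(tree$W, C, min(params$n_T, sum(tree$W)))
        rstar <- propose_replacement(C, tgt$dendrite, min(params$n_R, ncol(C)))
        jT <- tgt$dendrite; istar <- tgt$afferent
        # tentative swap: one contact moves from istar to rstar on row jT
        z_new <- tree$Z[jT, ] - st$Xt[istar, ] + st$Xt[rstar, ]
        a <- z_new - tree$zleak[jT]
        b_new <- ifelse(a > 0, a * a, 0)
        dO <- b_new - tree$B[jT, ]
        if (side == "ndt") dO <- -dO
        O_new <- st$O
        O_new[mu, ] <- O_new[mu, ] + dO
        err_new <- margin_error(O_new, labels, delta)
        commit <- function(forced) {
          tree$W[jT, istar] <<- tree$W[jT, istar] - 1
          tree$W[jT, rstar] <<- tree$W[jT, rstar] + 1
          tree$Z[jT, ] <<- z_new
          tree$B[jT, ] <<- b_new
          st$trees[[mu]][[side]] <<- tree
          st$O <<- O_new
          err_cur <<- err_new
          ev[[length(ev) + 1L]] <<- data.frame(
            iteration = iter, class = mu, side = side, dendrite = jT,
            removed = istar, added = rstar, forced = forced,
            error = err_new)
        }
        if (err_new <= err_cur) {
          commit(FALSE)
          reject[mu, si] <- 0L
          if (err_cur < best_err) {
            best_err <- err_cur
            best_snap <- list(trees = st$trees, delta = delta)
          }
          if (err_cur == 0) { stopnow <- TRUE; break }
        } else {
          reject[mu, si] <- reject[mu, si] + 1L
          if (reject[mu, si] >= params$n_ch) {
            # local minimum: checkpoint, then force the escape swap through
            if (err_cur <= best_err) {
              best_err <- err_cur
              best_snap <- list(trees = st$trees, delta = delta)
            }
            minima <- minima + 1L
            if (!is.na(last_min_err) && err_cur == last_min_err) {
              same_min <- same_min + 1L
            } else {
              same_min <- 1L
            }
            last_min_err <- err_cur
            if (same_min >= params$decay_runs && any(delta > 0)) {
              delta <- delta * params$decay_factor
              same_min <- 0L
              err_new <- margin_error(O_new, labels, delta)
            }
            commit(TRUE)
            reject[mu, si] <- 0L
            if (minima >= params$n_min) { stopnow <- TRUE; break }
          }
        }
      }
      if (stopnow) break
    }
    hist_it <- c(hist_it, iter); hist_err <- c(hist_err, err_cur)
    hist_best <- c(hist_best, best_err); hist_min <- c(hist_min, minima)
    if (!stopnow && !is.null(growth)) {
      g <- growth$step(st, delta, err_cur)
      if (!is.null(g)) {
        st <- g$st
        err_cur <- g$err
        if (g$stop) stopnow <- TRUE
      }
    }
    if (stopnow) break
  }

  if (err_cur <= best_err) {
    best_err <- err_cur
    best_snap <- list(trees = st$trees, delta = delta)
  }
  out_model <- model
  out_model$delta <- best_snap$delta
  for (mu in seq_len(n_classes)) {
    for (side in sides) {
      out_model$trees[[mu]][[side]]$W <- best_snap$trees[[mu]][[side]]$W
      out_model$trees[[mu]][[side]]$zleak <- best_snap$trees[[mu]][[side]]$zleak
    }
  }
  history <- data.frame(iteration = hist_it, error = hist_err,
                        best_error = hist_best, minima = hist_min)
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(iteration = integer(0), class = integer(0),
               side = character(0), dendrite = integer(0),
               removed = integer(0), added = integer(0),
               forced = logical(0), error = numeric(0))
  list(model = out_model, history = history, events = events,
       minima = minima, error = best_err)
}

#' Fit a dendritic classifier (full margin-calibrated pipeline)
#'
#' Convenience front end: initializes a randomly wired model, fixes branch
#' leaks on the training set, pre-trains with the hard readout, sets
#' per-class margins from a validation set, and trains again with the margin
#' readout (margins decaying when learning revisits the same minimum).
#'
#' @param X `P x d` binary training patterns.
#' @param labels length-`P` class indices in `1..n_classes`.
#' @param n_classes number of classes (default `max(labels)`).
#' @param m dendrites per tree.
#' @param k synapses per dendrite.
#' @param params a [learn_params()] list.
#' @param margin run the margin-calibration phase (default TRUE).
#' @param X_val,labels_val validation set for margin determination;
#'   defaults to the training set.
#' @param seed optional RNG seed for reproducible wiring and sampling.
#' @return list of class `"dendnet_fit"` with `model`, `history`
#'   (per-phase), `error` (final training error, hard readout).
#' @export
dendnet_fit <- function(X, labels, n_classes = max(labels), m = 10, k = 10,
                        params = learn_params(), margin = TRUE,
                        X_val = NULL, labels_val = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  model <- dendnet_model(ncol(X), n_classes, m, k)
  model <- set_leak(model, X)
  fit1 <- train_structural(model, X, labels, params)
  model <- fit1$model
  history <- list(pretrain = fit1$history)
  if (margin && fit1$error > 0) {
    if (is.null(X_val)) { X_val <- X; labels_val <- labels }
    model <- set_margins(model, X_val, labels_val)
    fit2 <- train_structural(model, X, labels, params)
    model <- fit2$model
    history$margin <- fit2$history
  }
  structure(list(
    model = model, history = history,
    error = misclassification_rate(model, X, labels, margin = FALSE)
  ), class = "dendnet_fit")
}

#' @export
print.dendnet_fit <- function(x, ...) {
  cat("Structural-plasticity fit\n")
  print(x$model)
  cat("  training error (hard WTA):", signif(x$error, 4), "\n")
  invisible(x)
}
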