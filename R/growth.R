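# Class-specific dendrite growth: when a class's learning stalls, a fresh
# randomly wired dendrite (k contacts) is appended to both of its trees, so
# synaptic resources follow the difficulty of each class. Growth stops when
# held-out validation error has risen at each of the last three additions.

# per-class margin-metric error: fraction of class-mu patterns whose margin
# output vector differs from the teacher
class_errors_from_scores <- function(O, labels, delta) {
  ok <- margin_correct(O, labels, delta)
  vapply(seq_len(nrow(O)), function(mu) {
    sel <- labels == mu
    if (!any(sel)) 0 else mean(!ok[sel])
  }, numeric(1))
}

#' Grow one dendrite on a class's tree pair, if eligible
#'
#' Appends a new dendrite (one fresh row of `k` random unit contacts, leak
#' set to the row's own mean drive over `X`) to both the positive and
#' negative tree of class `class`, provided the class is eligible under the
#' growth scheme: scheme 2 grows any class offered to it, scheme 1 only
#' classes currently ranking among the `n_worst` highest per-class errors.
#'
#' @param model a `dendnet_model`.
#' @param X `P x d` training patterns (for the new branch's leak).
#' @param class_errors per-class error vector used for scheme-1 eligibility.
#' @param class class index to grow.
#' @param scheme growth scheme, 1 or 2.
#' @param n_worst scheme-1 eligibility pool size (default 5).
#' @return list `model` (grown or unchanged) and `grown` flag.
#' @export
maybe_add_dendrite <- function(model, X, class_errors, class,
                               scheme = 2, n_worst = 5) {
  if (scheme == 1) {
    worst <- order(class_errors, decreasing = TRUE)[seq_len(min(n_worst, length(class_errors)))]
    if (!(class %in% worst)) return(list(model = model, grown = FALSE))
  }
  X <- as.matrix(X)
  for (side in c("pdt", "ndt")) {
    tr <- model$trees[[class]][[side]]
    new_row <- random_connections(1, model$k, model$d)
    zl <- as.vector(new_row %*% colMeans(X))
    tr$W <- rbind(tr$W, new_row)
    tr$zleak <- c(tr$zleak, zl)
    model$trees[[class]][[side]] <- tr
  }
  list(model = model, grown = TRUE)
}

# growth hook plugged into train_structural(); closes over a mutable
# environment holding stagnation counters and the validation series
make_growth_hook <- function(X, labels, X_val, labels_val, scheme,
                             n_ch, n_worst = 5, patience = 3) {
  e <- new.env(parent = emptyenv())
  e$m_series <- list()
  e$additions <- list()
  e$val_series <- numeric(0)
  e$stalled <- NULL
  e$best_cls <- NULL
  colmX <- colMeans(X)
  d <- ncol(X)

  val_error <- function(st) {
    Xvt <- t(X_val)
    O <- matrix(0, length(st$trees), nrow(X_val))
    for (mu in seq_along(st$trees)) {
      tp <- st$trees[[mu]]
      O[mu, ] <- colSums(branch_matrix(tp$pdt$W, tp$pdt$zleak, Xvt)) -
        colSums(branch_matrix(tp$ndt$W, tp$ndt$zleak, Xvt))
    }
    pred <- max.col(t(O), ties.method = "first")
    mean(pred != labels_val)
  }

  list(
    e = e,
    init = function(st, labs, delta) {
      nc <- length(st$trees)
      e$stalled <- integer(nc)
      e$best_cls <- class_errors_from_scores(st$O, labels, delta)
      e$val_series <- val_error(st)
      e$iter <- 0L
      e$k <- sum(st$trees[[1]]$pdt$W[1, ])
    },
    step = function(st, delta, err_cur) {
      e$iter <- e$iter + 1L
      errs <- class_errors_from_scores(st$O, labels, delta)
      nc <- length(errs)
      improved <- errs < e$best_cls
      e$best_cls[improved] <- errs[improved]
      e$stalled[improved] <- 0L
      e$stalled[!improved] <- e$stalled[!improved] + 1L
      ripe <- which(e$stalled >= n_ch & errs > 0)
      if (!length(ripe)) return(NULL)
      if (scheme == 1) {
        # eligibility pool: the n_worst highest-error classes
        worst <- order(errs, decreasing = TRUE)[seq_len(min(n_worst, nc))]
        grow_set <- intersect(ripe, worst)
        e$stalled[setdiff(ripe, worst)] <- 0L
      } else {
        # a stalled class grows only while its error is the highest of all
        # classes; blocked classes stay ripe until they rank worst
        grow_set <- ripe[errs[ripe] >= max(errs) - 1e-12]
      }
      if (!length(grow_set)) return(NULL)
      changed <- FALSE
      stop_growth <- FALSE
      for (mu in grow_set) {
        for (side in c("pdt", "ndt")) {
          tr <- st$trees[[mu]][[side]]
          new_row <- random_connections(1, e$k, d)
          zl <- sum(new_row * colmX)
          z_new <- as.vector(new_row %*% st$Xt)
          a <- z_new - zl
          a[a <= 0] <- 0
          b_new <- a * a
          tr$W <- rbind(tr$W, new_row)
          tr$zleak <- c(tr$zleak, zl)
          tr$Z <- rbind(tr$Z, z_new)
          tr$B <- rbind(tr$B, b_new)
          st$trees[[mu]][[side]] <- tr
          st$O[mu, ] <- st$O[mu, ] + if (side == "pdt") b_new else -b_new
        }
        e$stalled[mu] <- 0L
        ve <- val_error(st)
        e$val_series <- c(e$val_series, ve)
        e$additions[[length(e$additions) + 1L]] <- data.frame(
          iteration = e$iter, class = mu,
          m = nrow(st$trees[[mu]]$pdt$W), val_error = ve)
        changed <- TRUE
        n <- length(e$val_series)
        if (n >= 4 && all(diff(e$val_series[(n - 3):n]) > 0)) {
          stop_growth <- TRUE
          break
        }
      }
      if (!changed) return(NULL)
      list(st = st, err = margin_error(st$O, labels, delta),
           stop = stop_growth)
    }
  )
}

#' Adaptively grown structural-plasticity fit
#'
#' Trains with the structural rule while letting each class's dendritic
#' trees grow: a class whose error has not improved for `n_ch` iterations
#' receives one new randomly wired dendrite on both trees (scheme 2 grows
#' any such class; scheme 1 only classes among the 5 worst). A held-out
#' validation split is scored after every addition and growth stops once
#' validation error has increased at each of the last 3 additions; training
#' otherwise stops on memorization or the local-minima budget.
#'
#' @param X `P x d` binary patterns.
#' @param labels class indices in `1..n_classes`.
#' @param n_classes number of classes (default `max(labels)`).
#' @param m initial dendrites per tree (default 5).
#' @param k synapses per dendrite.
#' @param scheme growth scheme, 1 or 2 (default 2).
#' @param params a [learn_params()] list.
#' @param val_frac fraction of patterns held out for validation (default 0.2).
#' @param seed optional RNG seed.
#' @return list of class `"dendnet_adaptive"` with `model`, `growth`
#'   (additions log, validation series, final per-class dendrite counts),
#'   `history`, and `error` (training error, hard readout).
#' @export
adaptive_fit <- function(X, labels, n_classes = max(labels), m = 5, k = 10,
                         scheme = 2, params = learn_params(),
                         val_frac = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (val_frac <= 0 || val_frac >= 1) stop("val_frac must be in (0, 1)")
  X <- as.matrix(X)
  P <- nrow(X)
  idx_val <- sample.int(P, max(1, round(val_frac * P)))
  X_tr <- X[-idx_val, , drop = FALSE]
  lab_tr <- labels[-idx_val]
  X_val <- X[idx_val, , drop = FALSE]
  lab_val <- labels[idx_val]

  model <- dendnet_model(ncol(X), n_classes, m, k)
  model <- set_leak(model, X_tr)
  hook <- make_growth_hook(X_tr, lab_tr, X_val, lab_val, scheme,
                           n_ch = params$n_ch)
  fit <- train_structural(model, X_tr, lab_tr, params, growth = hook)
  adds <- if (length(hook$e$additions)) do.call(rbind, hook$e$additions) else
    data.frame(iteration = integer(0), class = integer(0),
               m = integer(0), val_error = numeric(0))
  m_final <- vapply(fit$model$trees, function(tp) nrow(tp$pdt$W), numeric(1))
  structure(list(
    model = fit$model,
    growth = list(additions = adds, val_series = hook$e$val_series,
                  m = m_final, scheme = scheme),
    history = fit$history,
    minima = fit$minima,
    error = misclassification_rate(fit$model, X_tr, lab_tr, margin = FALSE)
  ), class = "dendnet_adaptive")
}

#' @export
print.dendnet_adaptive <- function(x, ...) {
  cat("Adaptively grown dendritic classifier (scheme", x$growth$scheme, ")\n")
  cat("  final dendrites per class:", paste(x$growth$m, collapse = " "), "\n")
  cat("  additions:", nrow(x$growth$additions),
      " training error:", signif(x$error, 4), "\n")
  invisible(x)
}
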