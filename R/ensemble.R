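# Ensemble of independently seeded dendritic classifiers. Members share the
# architecture but start from different random wirings; at test time the
# per-class intermediate scores o_n^mu(x) are summed across members before
# the winner-take-all comparison.

#' Combine trained classifiers into an ensemble
#'
#' @param members list of trained `dendnet_model` objects sharing `d` and
#'   the class count.
#' @return an object of class `"dendnet_ensemble"`.
#' @export
dendnet_ensemble <- function(members) {
  members <- lapply(members, function(mm) {
    if (inherits(mm, "dendnet_fit") || inherits(mm, "dendnet_adaptive"))
      mm$model else mm
  })
  if (!length(members)) stop("empty ensemble")
  d <- unique(vapply(members, function(mm) mm$d, numeric(1)))
  nc <- unique(vapply(members, function(mm) mm$n_classes, numeric(1)))
  if (length(d) != 1 || length(nc) != 1)
    stop("ensemble members must share afferent and class counts")
  structure(list(members = members, n = length(members),
                 d = d, n_classes = nc),
            class = "dendnet_ensemble")
}

#' Summed class scores of an ensemble
#'
#' `O^mu(x) = sum_n o_n^mu(x)` over the `n` member classifiers.
#'
#' @param ens a `dendnet_ensemble`.
#' @param X `P x d` binary patterns.
#' @return `n_classes x P` matrix of summed scores.
#' @export
ensemble_scores <- function(ens, X) {
  X <- as.matrix(X)
  O <- matrix(0, ens$n_classes, nrow(X))
  for (mm in ens$members) O <- O + score_matrix(mm, X)
  O
}

#' Ensemble decision for a single pattern
#'
#' Winner-take-all over the member-summed class scores, with the standard
#' lowest-index tie rule.
#'
#' @param ens a `dendnet_ensemble`.
#' @param x binary input vector.
#' @return one-hot integer vector over classes.
#' @export
ensemble_decide <- function(ens, x) {
  wta_decision(as.vector(ensemble_scores(ens, matrix(x, nrow = 1))))
}

#' Predict class labels with an ensemble
#'
#' @param object a `dendnet_ensemble`.
#' @param X `P x d` binary pattern matrix.
#' @param ... unused.
#' @return integer vector of predicted class indices.
#' @export
predict.dendnet_ensemble <- function(object, X, ...) {
  O <- ensemble_scores(object, X)
  max.col(t(O), ties.method = "first")
}

#' @export
print.dendnet_ensemble <- function(x, ...) {
  m_tot <- sum(vapply(x$members, function(mm)
    sum(vapply(mm$trees, function(tp) 2 * nrow(tp$pdt$W), numeric(1))),
    numeric(1)))
  cat("Ensemble of", x$n, "dendritic classifiers (",
      x$n_classes, "classes,", m_tot, "dendrites total )\n")
  invisible(x)
}

#' Train an ensemble of independently seeded classifiers
#'
#' Members differ only in the RNG seed of their initial random wiring (and
#' hence their training trajectory).
#'
#' @param X,labels training data.
#' @param n_members ensemble size.
#' @param seeds member seeds (default `seed + 0:(n_members-1)`).
#' @param seed base seed when `seeds` is not given.
#' @param ... passed to [dendnet_fit()].
#' @return a `dendnet_ensemble`.
#' @export
ensemble_fit <- function(X, labels, n_members = 5, seeds = NULL,
                         seed = 1, ...) {
  if (is.null(seeds)) seeds <- seed + seq_len(n_members) - 1
  members <- lapply(seeds, function(s)
    dendnet_fit(X, labels, seed = s, ...)$model)
  dendnet_ensemble(members)
}
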