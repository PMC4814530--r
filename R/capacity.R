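# Combinatorial storage capacity of a neuron with nonlinear dendrites.
# Counting distinguishable wirings: with d afferents and k contacts per
# dendrite there are f = C(k+d-1, k) distinct branch functions, and a
# neuron with m interchangeable dendrites realizes C(f+m-1, m) distinct
# input-output functions, giving a capacity of 2*log2 C(f+m-1, m) bits.
# At fixed synapse budget s = m*k the capacity has an interior maximum in
# m, so a perceptron-like topology (m = 1) is sub-optimal.

#' Theoretical capacity of a nonlinear-dendrite neuron, in bits
#'
#' `C_NL = 2 * log2 C(f + m - 1, m)` with `f = C(k + d - 1, k)` the number
#' of distinct branch functions. Evaluated in the log domain (via
#' `lchoose`) so that astronomically large counts do not overflow.
#'
#' @param m dendrites per tree.
#' @param k synapses per dendrite.
#' @param d input afferents.
#' @return capacity in bits.
#' @export
capacity_bits <- function(m, k, d) {
  if (any(c(m, k, d) < 1)) stop("m, k, d must be positive")
  log2f <- lchoose(k + d - 1, k) / log(2)
  # C(f+m-1, m) with f known only through log2f: exact via lchoose when f
  # is representable, i.e. always here because f <= 2^1023 is not needed --
  # lchoose takes f itself, so recover f carefully in log space instead.
  f <- choose(k + d - 1, k)
  if (is.finite(f)) {
    2 * lchoose(f + m - 1, m) / log(2)
  } else {
    # f overflows double precision: use log Gamma with Stirling-free
    # summation, log C(f+m-1, m) = sum_{i=1..m} log(f+m-i) - log(i),
    # and log(f + c) ~= log f for c << f (here f > 1e308 >> m)
    logf <- log2f * log(2)
    (2 / log(2)) * (m * logf - lgamma(m + 1))
  }
}

#' Optimal dendritic topology at fixed synapse count
#'
#' Exhaustively scores every integer factorization `m * k = s` with
#' [capacity_bits()] and returns the maximizer; ties resolve to the larger
#' `m` (more, thinner dendrites).
#'
#' @param s total synapses per tree.
#' @param d input afferents.
#' @return list with `m_opt`, `k_opt`, `capacity` (bits), and the full
#'   search `table` (data.frame of m, k, capacity).
#' @export
optimal_topology <- function(s, d) {
  if (s < 1) stop("s must be positive")
  divs <- which(s %% seq_len(s) == 0)
  tab <- data.frame(m = divs, k = s / divs)
  tab$capacity <- mapply(capacity_bits, tab$m, tab$k, MoreArgs = list(d = d))
  # ties to larger m: scan in increasing m, keep >=
  best <- 1
  for (i in seq_len(nrow(tab))) if (tab$capacity[i] >= tab$capacity[best]) best <- i
  list(m_opt = tab$m[best], k_opt = tab$k[best],
       capacity = tab$capacity[best], table = tab)
}

#' Optimal per-class topology for a trained (grown) model
#'
#' For each class, takes the synapse count reached by adaptive growth
#' (`s = m_adapt * k`) and returns the capacity-maximizing factorization
#' `(m_opt, k_opt)` with `m_opt * k_opt = s`, the dimensions at which the
#' class's trees should be retrained from scratch.
#'
#' @param model a trained `dendnet_model` (e.g. from [adaptive_fit()]).
#' @return data.frame with one row per class: `m_adapt`, `k`, `s`,
#'   `m_opt`, `k_opt`, `capacity_adapt`, `capacity_opt`.
#' @export
convert_model_topology <- function(model) {
  if (inherits(model, "dendnet_adaptive")) model <- model$model
  d <- model$d
  rows <- lapply(seq_len(model$n_classes), function(mu) {
    m_a <- nrow(model$trees[[mu]]$pdt$W)
    k <- model$k
    s <- m_a * k
    opt <- optimal_topology(s, d)
    data.frame(class = mu, m_adapt = m_a, k = k, s = s,
               m_opt = opt$m_opt, k_opt = opt$k_opt,
               capacity_adapt = capacity_bits(m_a, k, d),
               capacity_opt = opt$capacity)
  })
  do.call(rbind, rows)
}
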