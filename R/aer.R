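# Two-tier address-event connectivity memory. A first memory of d pointer
# entries (CSR-style cumulative synapse counts, with a_0 = 0 implicit)
# indexes a second memory of H*k dendrite addresses grouped by afferent, so
# an incoming spike address is routed to its n_i = a_{i+1} - a_i target
# dendrites with two lookups. Bit and area accounting compares this layout
# with a conventional dense crossbar.

#' Encode stacked connection matrices into the two-tier AER layout
#'
#' All dendritic trees of the network are stacked to `H` global dendrites;
#' connection multiplicities expand into repeated destination entries. The
#' layout stores, per afferent, the cumulative connection count (pointer
#' array, `d` entries) and the grouped destination dendrite indices
#' (dendrite-address array, sized `H * k` regardless of fill).
#'
#' @param W_list list of connection matrices (each `m_t x d`), or a single
#'   matrix; stacked in order to form the global dendrite index.
#' @param k synapses per dendrite (for the second memory's nominal size).
#' @return object of class `"dendnet_aer"` with `pointers` (length `d`,
#'   cumulative counts), `destinations` (0-based dendrite addresses in
#'   stored order), `d`, `H`, `k`.
#' @export
aer_encode <- function(W_list, k = NULL) {
  if (is.matrix(W_list)) W_list <- list(W_list)
  d <- unique(vapply(W_list, ncol, numeric(1)))
  if (length(d) != 1) stop("all connection matrices must share afferent count")
  H <- sum(vapply(W_list, nrow, numeric(1)))
  if (is.null(k)) k <- max(vapply(W_list, function(W) max(rowSums(W)), numeric(1)))
  Wall <- do.call(rbind, W_list)
  if (sum(Wall) > H * k) stop("total connections exceed the H*k memory size")
  dest <- vector("list", d)
  for (i in seq_len(d)) {
    col <- Wall[, i]
    nz <- which(col > 0)
    dest[[i]] <- rep(nz - 1L, col[nz])   # 0-based dendrite addresses
  }
  n_i <- lengths(dest)
  structure(list(pointers = cumsum(n_i), destinations = unlist(dest),
                 d = d, H = H, k = k),
            class = "dendnet_aer")
}

#' Decode a two-tier AER layout back to the dense connection matrix
#'
#' @param layout a `dendnet_aer` object.
#' @return the `H x d` stacked integer connection matrix.
#' @export
aer_decode <- function(layout) {
  W <- matrix(0, layout$H, layout$d)
  a_prev <- 0
  for (i in seq_len(layout$d)) {
    a_i <- layout$pointers[i]
    if (a_i > a_prev) {
      dd <- layout$destinations[(a_prev + 1):a_i] + 1L
      for (j in dd) W[j, i] <- W[j, i] + 1
    }
    a_prev <- a_i
  }
  W
}

#' Route one address event through the layout
#'
#' Reads the consecutive pointer pair (with the implicit leading 0), and
#' returns the `n_i` destination dendrite addresses for afferent `i`
#' (0-based, in stored order); empty when the afferent has no connections.
#'
#' @param layout a `dendnet_aer` object.
#' @param i afferent index (1-based).
#' @return integer vector of 0-based destination dendrite addresses.
#' @export
route_event <- function(layout, i) {
  if (i < 1 || i > layout$d) stop("afferent index out of range")
  p <- if (i == 1) 0 else layout$pointers[i - 1]
  q <- layout$pointers[i]
  if (q == p) integer(0) else layout$destinations[(p + 1):q]
}

#' Memory bits of a conventional dense crossbar
#'
#' `NOB_conv = b*H*d + b*H*C`: `b`-bit weights from `d` inputs to `H`
#' hidden units plus `H` to `C` output units.
#'
#' @param b bits per weight.
#' @param H hidden units (dendrites).
#' @param d inputs.
#' @param C output classes.
#' @return list with `bits` and `weight_count` (`H*d + H*C`).
#' @export
nob_conventional <- function(b, H, d, C) {
  wc <- H * d + H * C
  list(bits = b * wc, weight_count = wc)
}

#' Memory bits of the proposed two-tier sparse layout
#'
#' `NOB_prop = d * ceil(log2(H*k)) + H*k * ceil(log2 H)`: the pointer array
#' plus the dendrite-address array.
#'
#' @param d inputs.
#' @param H dendrites.
#' @param k synapses per dendrite.
#' @return bits.
#' @export
nob_proposed <- function(d, H, k) {
  d * ceiling(log2(H * k)) + H * k * ceiling(log2(H))
}

#' Stored bits of a concrete AER layout
#'
#' The layout's actual footprint at its nominal sizing: `d` pointer entries
#' at `ceil(log2(H*k))` bits and `H*k` destination slots at `ceil(log2 H)`
#' bits — equal to [nob_proposed()] by construction.
#'
#' @param layout a `dendnet_aer` object.
#' @return bits.
#' @export
aer_bits <- function(layout) {
  layout$d * ceiling(log2(layout$H * layout$k)) +
    layout$H * layout$k * ceiling(log2(layout$H))
}

#' Memory and silicon-area comparison of the two layouts
#'
#' Conventional area uses the crossbar approximation `b*H*d` (valid for
#' `C << d`); proposed area is `NOB_prop` times the per-bit area.
#'
#' @param d inputs.
#' @param H dendrites / hidden units.
#' @param k synapses per dendrite.
#' @param b bits per conventional weight (default 4).
#' @param C output classes (default 10).
#' @param area_per_bit silicon area per bit, um^2 (default 0.15).
#' @return list of class `"dendnet_memreport"`: `nob_conv`, `nob_prop`,
#'   `weight_count_conv`, `area_conv`, `area_prop` (um^2), `ratio`.
#' @export
area_report <- function(d, H, k, b = 4, C = 10, area_per_bit = 0.15) {
  if (area_per_bit <= 0) stop("area_per_bit must be positive")
  conv <- nob_conventional(b, H, d, C)
  np <- nob_proposed(d, H, k)
  area_conv <- b * H * d * area_per_bit
  area_prop <- np * area_per_bit
  structure(list(nob_conv = conv$bits, nob_prop = np,
                 weight_count_conv = conv$weight_count,
                 area_conv = area_conv, area_prop = area_prop,
                 ratio = area_conv / area_prop),
            class = "dendnet_memreport")
}

#' @export
print.dendnet_memreport <- function(x, ...) {
  cat("Connectivity memory comparison\n")
  cat(sprintf("  conventional: %s bits (%s weights), %.0f um^2\n",
              format(x$nob_conv, big.mark = ","),
              format(x$weight_count_conv, big.mark = ","), x$area_conv))
  cat(sprintf("  proposed AER: %s bits, %.0f um^2\n",
              format(x$nob_prop, big.mark = ","), x$area_prop))
  cat(sprintf("  area reduction: %.2fx\n", x$ratio))
  invisible(x)
}

#' Crossover input dimension between the two memory layouts
#'
#' The smallest `d` at which the proposed layout needs no more bits than a
#' conventional `b`-bit crossbar, found by scanning `d` upward.
#'
#' @param H dendrites.
#' @param k synapses per dendrite.
#' @param b crossbar bits per weight (default 4).
#' @param C output classes (default 10).
#' @param d_max scan bound (default 2000).
#' @return the crossover `d` (NA if none up to `d_max`).
#' @export
aer_crossover_d <- function(H, k, b = 4, C = 10, d_max = 2000) {
  for (d in seq_len(d_max)) {
    if (nob_proposed(d, H, k) <= nob_conventional(b, H, d, C)$bits) return(d)
  }
  NA_integer_
}
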