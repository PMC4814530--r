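# Synthetic inputs and image utilities: prototype-based binary pattern
# generation (the package's stand-in for thresholded digit images), image
# thresholding, IDX digit-file reading, DVS-style event accumulation and
# cropping, and dendrite weight-map rendering.

#' Generate a prototype-based binary pattern set
#'
#' Draws `prototypes` random binary prototype vectors per class (each bit
#' Bernoulli(density)) and emits noisy copies by independent bit flips at
#' rate `noise`. Patterns cycle over the class's prototypes, so classes
#' with several prototypes are multi-modal and harder to learn.
#'
#' @param n_classes number of classes.
#' @param d pattern dimension.
#' @param n_per_class patterns generated per class; scalar or per-class
#'   vector.
#' @param prototypes prototypes per class; scalar or per-class vector.
#' @param noise bit-flip probability in `[0, 0.5)`; scalar or per-class
#'   vector (a high-noise class is a deliberately harder, high-variability
#'   category).
#' @param density prototype bit density (default 0.5).
#' @param proto_list reuse an existing list of per-class prototype matrices
#'   (e.g. to draw a test set from the same class structure as a training
#'   set); overrides `prototypes`, `d` and `density`.
#' @param seed optional RNG seed.
#' @return list with `X` (`P x d` 0/1 matrix), `labels`, and `prototypes`
#'   (list of per-class prototype matrices).
#' @export
synth_patterns <- function(n_classes = 4, d = 64, n_per_class = 50,
                           prototypes = 2, noise = 0.05, density = 0.5,
                           proto_list = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(noise < 0) || any(noise >= 0.5)) stop("noise must be in [0, 0.5)")
  if (!is.null(proto_list)) {
    n_classes <- length(proto_list)
    d <- ncol(proto_list[[1]])
    protos <- proto_list
    prototypes <- vapply(protos, nrow, integer(1))
  } else {
    if (d < 1 || n_classes < 2) stop("degenerate pattern-set specification")
    prototypes <- rep_len(prototypes, n_classes)
    protos <- lapply(prototypes, function(np)
      matrix(stats::rbinom(np * d, 1, density), np, d))
  }
  n_per_class <- rep_len(n_per_class, n_classes)
  noise <- rep_len(noise, n_classes)
  X <- matrix(0L, sum(n_per_class), d)
  labels <- integer(sum(n_per_class))
  r <- 0
  for (mu in seq_len(n_classes)) {
    for (i in seq_len(n_per_class[mu])) {
      r <- r + 1
      base <- protos[[mu]][((i - 1) %% prototypes[mu]) + 1, ]
      flip <- stats::rbinom(d, 1, noise[mu])
      X[r, ] <- ifelse(flip == 1, 1L - base, base)
      labels[r] <- mu
    }
  }
  list(X = X, labels = labels, prototypes = protos)
}

#' Threshold a grayscale image to a binary vector
#'
#' Pixels strictly above `threshold` map to 1, the rest to 0; the image is
#' flattened row-major (by image rows) into a length `nrow*ncol` vector.
#'
#' @param img numeric matrix (grayscale image).
#' @param threshold cut level; default is the midpoint of the image range.
#' @return integer 0/1 vector of length `prod(dim(img))`.
#' @export
threshold_image <- function(img, threshold = NULL) {
  img <- as.matrix(img)
  if (!length(img)) stop("empty image")
  if (is.null(threshold)) threshold <- (max(img) + min(img)) / 2
  as.integer(t(img) > threshold)   # t(): row-major flattening
}

#' Read IDX-format images or labels
#'
#' Minimal reader for the de facto digit-dataset binary container: a magic
#' number (data type and rank), big-endian dimension sizes, then raw data.
#' Only unsigned-byte payloads (type code 0x08) are supported.
#'
#' @param path file path.
#' @return for rank-3 files, a list of image matrices; for rank-1 files, an
#'   integer vector of labels.
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 4, size = 1, signed = FALSE)
  if (magic[1] != 0 || magic[2] != 0 || magic[3] != 8)
    stop("unsupported IDX file (only unsigned-byte payloads)")
  rank <- magic[4]
  dims <- readBin(con, "integer", rank, size = 4, endian = "big")
  data <- readBin(con, "integer", prod(dims), size = 1, signed = FALSE)
  if (rank == 1) return(as.integer(data))
  if (rank == 3) {
    n <- dims[1]; h <- dims[2]; w <- dims[3]
    return(lapply(seq_len(n), function(i) {
      matrix(data[((i - 1) * h * w + 1):(i * h * w)], h, w, byrow = TRUE)
    }))
  }
  stop("unsupported IDX rank: ", rank)
}

#' Synthetic DVS-style event stream
#'
#' Emits events at image locations with intensity-proportional Poisson
#' rates over the recording duration, emulating a dynamic vision sensor
#' watching a (moving) stimulus. Used to exercise the event-framing path
#' without real sensor recordings.
#'
#' @param img nonnegative numeric matrix; expected event count per pixel is
#'   `img * rate_scale`.
#' @param duration recording length, ms.
#' @param rate_scale expected events per unit intensity.
#' @param seed optional RNG seed.
#' @return data.frame of class `"dendnet_events"` with columns `x` (column),
#'   `y` (row), `t` (ms); attributes `dims` and `duration`.
#' @export
synth_events <- function(img, duration = 2000, rate_scale = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  img <- as.matrix(img)
  counts <- matrix(stats::rpois(length(img), img * rate_scale),
                   nrow(img), ncol(img))
  total <- sum(counts)
  ys <- rep(row(img)[counts > 0], counts[counts > 0])
  xs <- rep(col(img)[counts > 0], counts[counts > 0])
  ev <- data.frame(x = xs, y = ys,
                   t = if (total) sort(stats::runif(total, 0, duration)) else numeric(0))
  if (total) {
    ord <- sample.int(total)          # decouple pixel order from time order
    ev$x <- ev$x[ord]; ev$y <- ev$y[ord]
  }
  attr(ev, "dims") <- dim(img)
  attr(ev, "duration") <- duration
  class(ev) <- c("dendnet_events", "data.frame")
  ev
}

#' Accumulate an event stream into a count image
#'
#' Counts the events falling at each pixel within the time window.
#'
#' @param events a `dendnet_events` data.frame (or any with `x`,`y`,`t`).
#' @param window length-2 numeric `(t0, t1)` in ms; default the full stream.
#' @param dims sensor dimensions `(rows, cols)`; default from the stream.
#' @return integer count matrix of size `dims`.
#' @export
events_to_frame <- function(events, window = NULL, dims = NULL) {
  if (is.null(dims)) dims <- attr(events, "dims")
  if (is.null(window)) window <- c(0, attr(events, "duration"))
  if (window[2] <= window[1]) stop("empty time window")
  sel <- events$t >= window[1] & events$t <= window[2]
  frame <- matrix(0L, dims[1], dims[2])
  if (any(sel)) {
    idx <- cbind(events$y[sel], events$x[sel])
    for (r in seq_len(nrow(idx)))
      frame[idx[r, 1], idx[r, 2]] <- frame[idx[r, 1], idx[r, 2]] + 1L
  }
  frame
}

#' Crop the patch of maximal activity from a count image
#'
#' Exhaustive stride-1 scan over all `patch x patch` placements; returns
#' the placement with the largest total count, ties resolving to the
#' top-left-most placement (row-major scan order).
#'
#' @param frame count matrix.
#' @param patch patch side length.
#' @return list with `patch` (submatrix), `row`, `col` (top-left, 1-based).
#' @export
crop_max_activity <- function(frame, patch) {
  nr <- nrow(frame); nc <- ncol(frame)
  if (patch > nr || patch > nc) stop("patch larger than image")
  # summed-area table for O(1) window sums
  S <- matrix(0, nr + 1, nc + 1)
  for (r in seq_len(nr)) for (cc in seq_len(nc))
    S[r + 1, cc + 1] <- frame[r, cc] + S[r, cc + 1] + S[r + 1, cc] - S[r, cc]
  best <- -Inf; br <- 1; bc <- 1
  for (r in seq_len(nr - patch + 1)) {
    for (cc in seq_len(nc - patch + 1)) {
      tot <- S[r + patch, cc + patch] - S[r, cc + patch] -
        S[r + patch, cc] + S[r, cc]
      if (tot > best) { best <- tot; br <- r; bc <- cc }
    }
  }
  list(patch = frame[br:(br + patch - 1), bc:(bc + patch - 1), drop = FALSE],
       row = br, col = bc, total = best)
}

#' Render a dendrite weight vector as a 2-D map
#'
#' Reshapes a length-`d` weight (connection-multiplicity) vector to a
#' `side x side` matrix, row-major — the inverse of [threshold_image()]'s
#' flattening. With a matrix input, the mean across dendrite rows is
#' rendered (a class's mean feature map).
#'
#' @param w length-`d` vector, or an `m x d` connection matrix.
#' @param side map side length; default `sqrt(d)`.
#' @return numeric `side x side` matrix.
#' @export
render_weight_map <- function(w, side = NULL) {
  if (is.matrix(w)) w <- colMeans(w)
  d <- length(w)
  if (is.null(side)) side <- round(sqrt(d))
  if (side * side != d) stop("weight length is not compatible with the map side")
  matrix(w, side, side, byrow = TRUE)
}

#' Plot the per-class mean weight maps of a model
#'
#' One panel per class, positive-tree mean map minus nothing (PDT only).
#'
#' @param model a `dendnet_model`.
#' @param side map side length; default `sqrt(d)`.
#' @param ... passed to [graphics::image()].
#' @export
plot_weight_maps <- function(model, side = NULL, ...) {
  nc <- model$n_classes
  op <- graphics::par(mfrow = c(1, nc), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (mu in seq_len(nc)) {
    mp <- render_weight_map(model$trees[[mu]]$pdt$W, side)
    graphics::image(t(mp)[, nrow(mp):1], axes = FALSE,
                    main = paste("class", mu), ...)
  }
  invisible(model)
}

#' Write / read an event stream as CSV
#'
#' @param events a `dendnet_events` data.frame.
#' @param path file path.
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# dims: ", paste(attr(events, "dims"), collapse = "x")),
               paste0("# duration_ms: ", attr(events, "duration")),
               "x,y,t_ms"), con)
  if (nrow(events))
    writeLines(paste(events$x, events$y, format(events$t, digits = 10),
                     sep = ","), con)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  dims <- as.integer(strsplit(sub(".*dims: *", "", hdr[grep("dims", hdr)]), "x")[[1]])
  duration <- as.numeric(sub(".*duration_ms: *", "", hdr[grep("duration", hdr)]))
  body <- lines[!grepl("^#", lines)][-1]
  if (length(body)) {
    parts <- do.call(rbind, strsplit(body, ","))
    ev <- data.frame(x = as.integer(parts[, 1]), y = as.integer(parts[, 2]),
                     t = as.numeric(parts[, 3]))
  } else {
    ev <- data.frame(x = integer(0), y = integer(0), t = numeric(0))
  }
  attr(ev, "dims") <- dims
  attr(ev, "duration") <- duration
  class(ev) <- c("dendnet_events", "data.frame")
  ev
}
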