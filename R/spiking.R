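# Spike-domain evaluation path. Learned connections are mapped onto an
# equivalent spiking network: each input spike evokes a double-exponential
# postsynaptic current, dendrites apply the same quadratic nonlinearity to
# their time-resolved synaptic drive, and each class is read out by a pair
# of leaky integrate-and-fire neurons driven by opposite currents; the
# decision is winner-take-all over spike-count differences.

#' Postsynaptic-current kernel parameters
#'
#' Double-exponential PSC `K(t) = I0 (exp(-t/tau_f) - exp(-t/tau_r))` with
#' fall constant `tau_f` > rise constant `tau_r`. All times in ms.
#'
#' @param I0 normalization constant (default 2); sets the current gain so
#'   that unit class-score differences resolve into multiple spike-count
#'   units within the stimulus window.
#' @param tau_f fall time constant, ms (default 10).
#' @param tau_r rise time constant, ms (default 2).
#' @export
psc_params <- function(I0 = 2, tau_f = 10, tau_r = 2) {
  if (tau_f <= tau_r || tau_r <= 0) stop("need tau_f > tau_r > 0")
  list(I0 = I0, tau_f = tau_f, tau_r = tau_r)
}

#' Leaky integrate-and-fire parameters
#'
#' Membrane dynamics `tau_V dV/dt = (u - V) + I(t)` with slow
#' hyperpolarization `tau_u du/dt = -u`; on `V >= V_thr` the neuron spikes,
#' `V -> V_reset`, `u -> u_reset = V_reset < 0`. All times in ms.
#'
#' @param tau_V membrane time constant, ms (default 5).
#' @param tau_u hyperpolarization time constant, ms (default 200).
#' @param V_thr spike threshold, mV (default 0.1).
#' @param V_reset reset potential, mV, must be negative (default -0.1).
#' @param dt Euler integration step, ms (default 0.05, small enough that
#'   interspike intervals at the largest benchmark currents span many
#'   steps).
#' @export
lif_params <- function(tau_V = 5, tau_u = 200, V_thr = 0.1,
                       V_reset = -0.1, dt = 0.05) {
  if (dt <= 0) stop("dt must be positive")
  if (V_reset >= 0) stop("V_reset must be negative")
  list(tau_V = tau_V, tau_u = tau_u, V_thr = V_thr,
       V_reset = V_reset, u_reset = V_reset, dt = dt)
}

#' PSC kernel evaluated at time(s) t for a spike at t_spike
#'
#' Causal: zero for `t <= t_spike`. The kernel peaks at
#' `t_spike + tau_f*tau_r/(tau_f - tau_r) * log(tau_f/tau_r)`.
#'
#' @param t evaluation time(s), ms.
#' @param t_spike spike time, ms (default 0).
#' @param params a [psc_params()] list.
#' @return current value(s), nonnegative.
#' @export
psc_kernel <- function(t, t_spike = 0, params = psc_params()) {
  s <- t - t_spike
  out <- numeric(length(s))
  pos <- s > 0
  out[pos] <- params$I0 *
    (exp(-s[pos] / params$tau_f) - exp(-s[pos] / params$tau_r))
  out
}

#' Spike pattern container
#'
#' Per-afferent lists of spike times over a stimulus window `[0, duration]`.
#'
#' @param times list of numeric spike-time vectors, one per afferent.
#' @param duration stimulus duration T, ms.
#' @export
spike_pattern <- function(times, duration) {
  times <- lapply(times, function(v) sort(as.numeric(v)))
  bad <- vapply(times, function(v) length(v) && (min(v) < 0 || max(v) > duration),
                logical(1))
  if (any(bad)) stop("spike times must lie within [0, duration]")
  structure(list(times = times, duration = duration),
            class = "dendnet_spikes")
}

#' Encode a binary vector as (jittered) single spikes
#'
#' Component `x_i = 1` becomes one spike drawn uniformly from the window
#' `[T_syn - jitter/2, T_syn + jitter/2]` (exactly `T_syn` when
#' `jitter = 0`); `x_i = 0` produces no spike.
#'
#' @param x binary input vector.
#' @param T_syn nominal spike time, ms (default 100).
#' @param jitter window width Delta, ms (default 0).
#' @param duration stimulus duration T, ms (default 200).
#' @return a [spike_pattern()].
#' @export
encode_single_spike <- function(x, T_syn = 100, jitter = 0, duration = 200) {
  if (T_syn - jitter / 2 < 0 || T_syn + jitter / 2 > duration)
    stop("jitter window must lie within [0, duration]")
  times <- lapply(x, function(xi) {
    if (xi == 0) numeric(0)
    else if (jitter == 0) T_syn
    else stats::runif(1, T_syn - jitter / 2, T_syn + jitter / 2)
  })
  spike_pattern(times, duration)
}

#' Encode a binary vector as Poisson spike trains
#'
#' Homogeneous Poisson processes at rate `f_high` (Hz) for `x_i = 1` and
#' `f_low` for `x_i = 0`, over `[0, duration]` ms.
#'
#' @param x binary input vector.
#' @param f_high,f_low firing rates in Hz (defaults 250 and 1).
#' @param duration stimulus duration T, ms (default 200).
#' @return a [spike_pattern()].
#' @export
encode_poisson <- function(x, f_high = 250, f_low = 1, duration = 200) {
  if (duration < 0) stop("duration must be nonnegative")
  times <- lapply(x, function(xi) {
    rate <- if (xi == 1) f_high else f_low
    n <- stats::rpois(1, rate * duration / 1000)
    if (n == 0) numeric(0) else sort(stats::runif(n, 0, duration))
  })
  spike_pattern(times, duration)
}

# internal: per-afferent synaptic drive traces on the simulation grid.
# Returns a matrix (afferents-with-spikes x n_steps) plus the index map.
afferent_traces <- function(pattern, grid, psc) {
  active <- which(vapply(pattern$times, length, integer(1)) > 0)
  S <- matrix(0, length(active), length(grid))
  for (a in seq_along(active)) {
    for (ts in pattern$times[[active[a]]]) {
      S[a, ] <- S[a, ] + psc_kernel(grid, ts, psc)
    }
  }
  list(S = S, active = active)
}

#' Time-resolved input currents of one class's tree pair
#'
#' Computes `z_j(t)` from the spike pattern through the PSC kernel,
#' applies the branch nonlinearity against the time-resolved leak
#' `zleak_j(t) = zleak_j * K(t - T_syn)` (the branch's rate-model leak
#' carried on the canonical single-spike drive), sums dendrites into the
#' tree currents, and returns the push-pull pair
#' `I+ = I_PDT - I_NDT`, `I- = -I+`.
#'
#' @param treepair one element of `model$trees` (list with `pdt`, `ndt`).
#' @param pattern a [spike_pattern()].
#' @param psc a [psc_params()] list.
#' @param T_syn reference spike time used by the leak trace, ms.
#' @param dt time step, ms.
#' @return list with `t` (grid), `I_plus`, `I_minus`.
#' @export
input_current <- function(treepair, pattern, psc = psc_params(),
                          T_syn = 100, dt = 0.05) {
  grid <- seq(dt, pattern$duration, by = dt)
  tr <- afferent_traces(pattern, grid, psc)
  leak_trace <- psc_kernel(grid, T_syn, psc)
  tree_I <- function(side) {
    W <- treepair[[side]]$W
    zl <- treepair[[side]]$zleak
    if (length(pattern$times) != ncol(W))
      stop("pattern afferent count does not match the model")
    Z <- if (length(tr$active))
      W[, tr$active, drop = FALSE] %*% tr$S
    else matrix(0, nrow(W), length(grid))
    A <- Z - outer(zl, leak_trace)
    A[A <= 0] <- 0
    colSums(A * A)
  }
  Ip <- tree_I("pdt") - tree_I("ndt")
  list(t = grid, I_plus = Ip, I_minus = -Ip)
}

#' Leaky integrate-and-fire simulation (forward Euler)
#'
#' Integrates the membrane equation with a fixed step; threshold crossings
#' are handled at step boundaries (spike, reset of `V` and `u`, count).
#' `I` may be a vector (one neuron) or a matrix (neurons in rows, time in
#' columns) for a population driven in parallel.
#'
#' @param I input current trace(s).
#' @param params a [lif_params()] list.
#' @param trace return the membrane trace (single neuron only).
#' @return list with `n_spk` (integer count(s)) and, if requested, `V`.
#' @export
lif_simulate <- function(I, params = lif_params(), trace = FALSE) {
  single <- is.null(dim(I))
  if (single) I <- matrix(I, nrow = 1)
  n_units <- nrow(I); n_steps <- ncol(I)
  V <- numeric(n_units); u <- numeric(n_units)
  n_spk <- integer(n_units)
  aV <- params$dt / params$tau_V
  au <- params$dt / params$tau_u
  Vtr <- if (trace && single) numeric(n_steps) else NULL
  for (s in seq_len(n_steps)) {
    V <- V + aV * ((u - V) + I[, s])
    u <- u - au * u
    fired <- V >= params$V_thr
    if (any(fired)) {
      V[fired] <- params$V_reset
      u[fired] <- params$u_reset
      n_spk[fired] <- n_spk[fired] + 1L
    }
    if (!is.null(Vtr)) Vtr[s] <- V[1]
  }
  out <- list(n_spk = if (single) n_spk[1] else n_spk)
  if (!is.null(Vtr)) out$V <- Vtr
  out
}

#' Classify one spike pattern with the spiking network
#'
#' Simulates the (+) and (-) neuron of every class on the pattern's input
#' currents and applies winner-take-all to the spike-count differences
#' `o_spk^mu = n_spk^mu+ - n_spk^mu-` (lowest-index tie rule).
#'
#' @param model a trained `dendnet_model`.
#' @param pattern a [spike_pattern()].
#' @param lif a [lif_params()] list.
#' @param psc a [psc_params()] list.
#' @param T_syn reference spike time for the leak trace, ms.
#' @return list with `class` (predicted index), `o_spk`, `y` (one-hot).
#' @export
classify_spikes <- function(model, pattern, lif = lif_params(),
                            psc = psc_params(), T_syn = 100) {
  o_spk <- vapply(model$trees, function(tp) {
    cur <- input_current(tp, pattern, psc, T_syn, lif$dt)
    lif_simulate(cur$I_plus, lif)$n_spk -
      lif_simulate(cur$I_minus, lif)$n_spk
  }, numeric(1))
  y <- wta_decision(o_spk)
  list(class = which.max(y), o_spk = o_spk, y = y)
}

#' Spiking-path predictions for a set of binary patterns
#'
#' Encodes each row of `X` as spikes (single-spike with optional jitter, or
#' Poisson), simulates all class neurons, and returns the winner-take-all
#' labels. All LIF neurons of a batch are integrated in parallel.
#'
#' @param model a trained `dendnet_model`.
#' @param X `P x d` binary patterns.
#' @param encoder `"single"` or `"poisson"`.
#' @param jitter single-spike jitter window, ms.
#' @param f_high,f_low Poisson rates, Hz.
#' @param duration stimulus duration, ms.
#' @param T_syn nominal single-spike time, ms.
#' @param lif,psc parameter lists.
#' @return integer vector of predicted class indices.
#' @export
predict_spiking <- function(model, X, encoder = c("single", "poisson"),
                            jitter = 0, f_high = 250, f_low = 1,
                            duration = 200, T_syn = 100,
                            lif = lif_params(), psc = psc_params()) {
  encoder <- match.arg(encoder)
  X <- as.matrix(X)
  P <- nrow(X)
  nc <- model$n_classes
  grid <- seq(lif$dt, duration, by = lif$dt)
  n_steps <- length(grid)
  # current matrix: rows are (pattern, class, +/-) units
  I <- matrix(0, P * nc * 2, n_steps)
  for (p in seq_len(P)) {
    pat <- if (encoder == "single")
      encode_single_spike(X[p, ], T_syn, jitter, duration)
    else encode_poisson(X[p, ], f_high, f_low, duration)
    for (mu in seq_len(nc)) {
      cur <- input_current(model$trees[[mu]], pat, psc, T_syn, lif$dt)
      base <- ((p - 1) * nc + (mu - 1)) * 2
      I[base + 1, ] <- cur$I_plus
      I[base + 2, ] <- cur$I_minus
    }
  }
  n_spk <- lif_simulate(I, lif)$n_spk
  pred <- integer(P)
  for (p in seq_len(P)) {
    base <- (p - 1) * nc * 2
    o_spk <- n_spk[base + 2 * seq_len(nc) - 1] - n_spk[base + 2 * seq_len(nc)]
    pred[p] <- which.max(o_spk)
  }
  pred
}

#' Write / read a spike pattern as two-column CSV
#'
#' Plain-text interchange: rows of `(afferent_id, time_ms)` with the
#' stimulus duration and afferent count in `# key: value` header lines.
#'
#' @param pattern a [spike_pattern()].
#' @param path file path.
#' @export
write_spike_pattern <- function(pattern, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# duration_ms: ", pattern$duration),
               paste0("# afferents: ", length(pattern$times)),
               "afferent_id,time_ms"), con)
  for (i in seq_along(pattern$times)) {
    for (ts in pattern$times[[i]])
      writeLines(paste0(i, ",", format(ts, digits = 12)), con)
  }
  invisible(path)
}

#' @rdname write_spike_pattern
#' @param path file path.
#' @export
read_spike_pattern <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  duration <- as.numeric(sub(".*duration_ms: *", "", hdr[grep("duration_ms", hdr)]))
  d <- as.integer(sub(".*afferents: *", "", hdr[grep("afferents", hdr)]))
  body <- lines[!grepl("^#", lines)][-1]
  times <- rep(list(numeric(0)), d)
  if (length(body)) {
    parts <- strsplit(body, ",")
    for (pp in parts) {
      i <- as.integer(pp[1])
      times[[i]] <- c(times[[i]], as.numeric(pp[2]))
    }
  }
  spike_pattern(times, duration)
}
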