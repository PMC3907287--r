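#' Feed-forward chain configuration
#'
#' Architecture of the nearest-neighbour feed-forward chain: cell i receives
#' `g * x[i-1]`. The first `n_stim` cells form the early/persistent block
#' that is loaded with the stimulus; cells `n_stim+1 ... N` are the late
#' block, held quiescent until the executive input arrives. From that moment
#' a single designated late cell (`feedback_source`) feeds back with
#' strength `c` onto every cell of the stimulated block, which amplifies the
#' decayed activity at rate `a = amplification_rate(g, c)` (approximately
#' `g + c - 1`).
#'
#' Defaults put the chain in the slightly-detuned regime used throughout:
#' decay rate `d = 1 - g = 0.005` per time constant and matched
#' amplification `a = 0.005` (feedback calibrated via
#' [feedback_strength()]), with noise `sigma = 0.005`.
#'
#' @param N number of cells (`>= 2`).
#' @param n_stim number of initially stimulated cells, `0 < n_stim < N`.
#' @param g feed-forward coupling (the non-zero entries of W), `>= 0`.
#' @param c feedback strength from the designated late cell, `>= 0`.
#'   `NULL` calibrates `c` so the amplification rate equals the decay rate
#'   `1 - g` (and 0 when `g >= 1`).
#' @param sigma noise strength: scale of the Wiener increments.
#' @param dt Euler-Maruyama step (time constants).
#' @param tau membrane time constant; fixed at 1 and defining the time unit.
#' @param feedback_source index of the late cell providing feedback;
#'   default the first late cell.
#' @param feedback_init what the executive input does to the feedback
#'   source when the gate opens: `"wave"` (default) sets it onto the
#'   travelling-wave solution `g * x[n_stim] / (1 + a)`, the level a late
#'   cell assumes when it joins the amplifying wave; `"zero"` leaves it to
#'   charge from rest through the chain.
#' @return an object of class `wavemem_chain`.
#' @export
chain_config <- function(N = 150, n_stim = 100, g = 0.995, c = NULL,
                         sigma = 0.005, dt = 0.01, tau = 1,
                         feedback_source = n_stim + 1,
                         feedback_init = c("wave", "zero")) {
  feedback_init <- match.arg(feedback_init)
  if (!(N >= 2)) stop("chain_config: N must be >= 2", call. = FALSE)
  if (!(n_stim > 0 && n_stim < N))
    stop("chain_config: need 0 < n_stim < N", call. = FALSE)
  if (is.null(c)) c <- if (g < 1) feedback_strength(g, 1 - g) else 0
  if (g < 0 || c < 0 || sigma < 0 || dt <= 0 || tau != 1)
    stop("chain_config: need g >= 0, c >= 0, sigma >= 0, dt > 0, tau = 1",
         call. = FALSE)
  if (feedback_source < 1 || feedback_source > N)
    stop("chain_config: feedback_source out of range", call. = FALSE)
  structure(list(N = as.integer(N), n_stim = as.integer(n_stim), g = g,
                 c = c, sigma = sigma, dt = dt, tau = 1,
                 feedback_source = as.integer(feedback_source),
                 feedback_init = feedback_init),
            class = "wavemem_chain")
}

#' @export
print.wavemem_chain <- function(x, ...) {
  cat(sprintf(
    "<chain: N = %d (stimulated 1..%d), g = %g, c = %g, sigma = %g, dt = %g>\n",
    x$N, x$n_stim, x$g, x$c, x$sigma, x$dt))
  invisible(x)
}

#' Feed-forward nearest-neighbour connection matrix
#'
#' Entry `(i, i-1)` equals `g` for `i = 2..N`; every other entry is zero, so
#' the first cell receives no recurrent input.
#'
#' @param N number of cells (`>= 2`).
#' @param g coupling strength (`>= 0`).
#' @return an `N x N` numeric matrix.
#' @export
build_chain_weights <- function(N, g) {
  if (!(is.numeric(N) && N >= 2))
    stop("build_chain_weights: N must be >= 2", call. = FALSE)
  if (g < 0) stop("build_chain_weights: g must be >= 0", call. = FALSE)
  W <- matrix(0, N, N)
  W[cbind(2:N, 1:(N - 1))] <- g
  W
}

#' Derive a per-trial seed from a base seed
#'
#' Counter-based splitting rule used by all ensemble and sweep runners:
#' a fixed-multiplier congruential step of the base seed plus an
#' index-dependent offset, reduced modulo 2^31 - 1 (so the result is always
#' a valid, positive 32-bit integer seed). Distinct indices give distinct
#' seeds for any practical index range.
#'
#' @param base_seed integer base seed.
#' @param index trial counter (vectorised).
#' @return integer seed(s) in `1 .. 2^31 - 2`.
#' @export
derive_seed <- function(base_seed, index) {
  m <- 2147483647
  as.integer((((as.numeric(base_seed) %% m) * 48271 +
                 as.numeric(index) * 69621) %% (m - 1)) + 1)
}

# per-cell gain parameter vectors for fast vectorised evaluation
.gain_vectors <- function(spec, n) {
  list(q = rep(spec$mode == "quiescent", n),
       th = rep(spec$threshold, n),
       sl = rep(spec$slope, n),
       M = rep(spec$saturation, n))
}

# comparison gain whose unstable fixed point under loop coupling g sits at
# x_sep: slope 2, threshold x_sep (2g - 1) / 2
.comparison_gain <- function(x_sep, g) {
  gain_spec("comparison", threshold = max(x_sep * (2 * g - 1) / 2, 0),
            slope = 2)
}

#' Simulate the stochastic feed-forward chain
#'
#' Euler-Maruyama integration of
#' `dx_i = (-x_i + F_i(g x_{i-1} + feedback_i)) dt + sigma dB_i`
#' under a task schedule. The stimulated block starts at the loaded level
#' `x0 = load_level(map, f1)`; the late block starts at rest and is held in
#' quiescent mode until `t_exec`, after which it switches to maintenance
#' mode and the designated feedback cell contributes `c * x_fb` to the
#' summed input of every stimulated cell. If `include_comparison` is TRUE,
#' integration continues past `T` for `t_cmp_len` with the stimulated block
#' switched to the comparison configuration (separatrix at
#' `load_level(map, f2)`). The state itself is never clipped: only the gain
#' is rectified, so noise can drive activity slightly negative.
#'
#' @param config a [chain_config()].
#' @param schedule a [task_schedule()].
#' @param seed integer seed; with `sigma = 0` the trajectory is
#'   deterministic and identical for every seed.
#' @param gain per-block gain plan: list with components `main` (stimulated
#'   block during the delay), `late_closed`, `late_open`, and optionally
#'   `comparison` (default: separatrix gain derived from `f2`).
#' @param map a [stimulus_map()] translating `f1`/`f2` into activity levels.
#' @param x0 optional explicit loaded level, overriding
#'   `load_level(map, f1)`.
#' @param init `"block"` loads cells `1..n_stim` (the default);
#'   `"uniform_all"` loads every cell, giving the boundary-free exact line
#'   attractor when `g = 1`.
#' @param record_every store every k-th step (thinning; the integration
#'   step is always `dt`).
#' @param include_comparison extend the run through the comparison window.
#' @return an object of class `wavemem_sim`: list with `times` (recorded
#'   grid), `activity` (cells x times matrix), `seed`, `config`, `schedule`,
#'   `map`, `x0`.
#' @export
simulate_chain <- function(config, schedule, seed = 1L, gain = NULL,
                           map = stimulus_map(), x0 = NULL,
                           init = c("block", "uniform_all"),
                           record_every = 1L, include_comparison = FALSE) {
  stopifnot(inherits(config, "wavemem_chain"),
            inherits(schedule, "wavemem_schedule"))
  init <- match.arg(init)
  if (is.null(gain)) gain <- list()
  g_main <- gain$main %||% gain_spec("maintenance")
  g_closed <- gain$late_closed %||% gain_spec("quiescent")
  g_open <- gain$late_open %||% gain_spec("maintenance")
  N <- config$N; ns <- config$n_stim; dt <- config$dt
  g <- config$g; cf <- config$c; sig <- config$sigma
  fb <- config$feedback_source
  if (is.null(x0)) x0 <- load_level(map, schedule$f1)

  t_end <- schedule$T + if (include_comparison) schedule$t_cmp_len else 0
  nstep <- as.integer(round(t_end / dt))
  gate_step <- if (is.finite(schedule$t_exec))
    as.integer(ceiling(schedule$t_exec / dt - 1e-9)) else NA_integer_
  cmp_step <- as.integer(round(schedule$T / dt))  # comparison dynamics after T

  idx_main <- seq_len(ns); idx_late <- if (ns < N) (ns + 1L):N else integer(0)
  x <- numeric(N)
  if (init == "block") x[idx_main] <- x0 else x[] <- x0

  gv_main <- .gain_vectors(g_main, ns)
  gv_late <- .gain_vectors(g_closed, N - ns)
  q <- c(gv_main$q, gv_late$q); th <- c(gv_main$th, gv_late$th)
  sl <- c(gv_main$sl, gv_late$sl); M <- c(gv_main$M, gv_late$M)

  keep <- seq.int(0L, nstep, by = as.integer(record_every))
  if (keep[length(keep)] != nstep) keep <- c(keep, nstep)
  out <- matrix(NA_real_, N, length(keep))
  out[, 1L] <- x
  ki <- 2L
  gate <- FALSE   # feedback + late-maintenance active
  opened <- FALSE # one-time gate-opening actions done
  sq <- sig * sqrt(dt)
  a_eff <- if (cf > 0 && g < 1) amplification_rate(g, cf) else cf + g - 1

  set.seed(as.integer(seed))
  for (s in seq_len(nstep)) {
    if (!opened && !is.na(gate_step) && s > gate_step) {
      opened <- TRUE
      gate <- TRUE
      gv <- .gain_vectors(g_open, N - ns)
      if (length(idx_late)) {
        q[idx_late] <- gv$q; th[idx_late] <- gv$th
        sl[idx_late] <- gv$sl; M[idx_late] <- gv$M
      }
      if (config$feedback_init == "wave" && cf > 0 && fb > ns)
        x[fb] <- g * x[ns] / (1 + max(a_eff, 0))
    }
    if (s == cmp_step + 1L && include_comparison) {
      g_cmp <- gain$comparison %||%
        .comparison_gain(load_level(map, schedule$f2), g)
      gv <- .gain_vectors(g_cmp, ns)
      q[idx_main] <- gv$q; th[idx_main] <- gv$th
      sl[idx_main] <- gv$sl; M[idx_main] <- gv$M
      gate <- FALSE  # the executive episode ends with the delay period
      opened <- TRUE # and the gate must not re-open during comparison
    }
    u <- g * c(0, x[-N])
    if (gate && cf > 0) u[idx_main] <- u[idx_main] + cf * x[fb]
    drive <- sl * (u - th)
    drive[u < th | q] <- 0
    drive <- pmin(drive, M)
    x <- x + dt * (drive - x)
    if (sig > 0) x <- x + sq * stats::rnorm(N)
    if (s == keep[ki]) {
      if (!all(is.finite(x)))
        stop(sprintf("simulate_chain: non-finite state at step %d (t = %g)",
                     s, s * dt), call. = FALSE)
      out[, ki] <- x
      ki <- ki + 1L
    }
  }
  structure(list(times = keep * dt, activity = out, seed = as.integer(seed),
                 config = config, schedule = schedule, map = map, x0 = x0),
            class = "wavemem_sim")
}

#' @export
print.wavemem_sim <- function(x, ...) {
  cat(sprintf(
    "<simulation: %d cells x %d time points on [0, %g], seed %d%s>\n",
    nrow(x$activity), ncol(x$activity), max(x$times), x$seed,
    if (!is.null(x$late)) " (+ late line)" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
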