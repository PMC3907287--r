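#' Decay/amplification rate parameters
#'
#' Bundle of the analytic quantities describing a decay-amplify network:
#' decay rate `d = 1 - g` during the first part of the delay, amplification
#' rate `a` after the executive input (approximately `g + c - 1`),
#' resolution `eps` (relative activity tolerance at the end of the delay),
#' delay length `T`, and loaded level `x0`. Supply either (`g`, `c`) or
#' (`d`, `a`) directly.
#'
#' @param d decay rate per time constant (`>= 0` in the decay regime).
#' @param a amplification rate; amplification exists iff `a > 0`
#'   (equivalently `g + c > 1`).
#' @param eps resolution: the network must hold the end-of-delay activity
#'   within a relative band `x0 * [1 - eps, 1 + eps]`; `0 < eps < 1`.
#' @param T delay length (time constants).
#' @param x0 loaded activity level.
#' @param g,c alternative parameterisation through coupling and feedback.
#' @return an object of class `wavemem_rates`.
#' @export
rate_params <- function(d = NULL, a = NULL, eps = 0.1, T = 6, x0 = 0.8,
                        g = NULL, c = NULL) {
  if (is.null(d)) {
    if (is.null(g)) stop("rate_params: give d or g", call. = FALSE)
    d <- 1 - g
  }
  if (is.null(a)) {
    if (is.null(c) || is.null(g)) stop("rate_params: give a or (g, c)",
                                       call. = FALSE)
    a <- amplification_rate(g, c)
  }
  if (!(eps > 0 && eps < 1)) stop("rate_params: need 0 < eps < 1",
                                  call. = FALSE)
  if (!(T > 0)) stop("rate_params: need T > 0", call. = FALSE)
  structure(list(d = d, a = a, eps = eps, T = T, x0 = x0),
            class = "wavemem_rates")
}

#' @export
print.wavemem_rates <- function(x, ...) {
  cat(sprintf("<rates: d = %g, a = %g, eps = %g, T = %g, x0 = %g>\n",
              x$d, x$a, x$eps, x$T, x$x0))
  invisible(x)
}

#' Asymptotic amplification rate of the gated chain
#'
#' Once the gate is open, a deep persistent cell y and the feedback cell z
#' form the linear pair `y' = (g - 1) y + c z`, `z' = -z + g y`. The
#' activity grows at the dominant eigenvalue of that pair,
#' `lambda = (-(2 - g) + sqrt((2 - g)^2 - 4 (1 - g - c g))) / 2`,
#' which reduces to the first-order expression `g + c - 1` for small
#' `1 - g` and `c`. `feedback_strength()` is the exact inverse: the `c`
#' that realises amplification rate `a` at coupling `g`, namely
#' `c = (a + d)(1 + a) / (1 - d)` with `d = 1 - g` (first order:
#' `c = a + d`).
#'
#' @param g feed-forward coupling.
#' @param c feedback strength.
#' @return the asymptotic exponential rate (negative means net decay).
#' @export
amplification_rate <- function(g, c) {
  (-(2 - g) + sqrt((2 - g)^2 - 4 * (1 - g - c * g))) / 2
}

#' @rdname amplification_rate
#' @param a requested amplification rate (`a > -(1 - g)` for a real
#'   solution).
#' @export
feedback_strength <- function(g, a) {
  d <- 1 - g
  (a + d) * (1 + a) / (1 - d)
}

#' Persistent-cell envelope of the plain chain
#'
#' Large-time approximation of the chain solution for a cell deep inside
#' the stimulated block, after stimulus removal and before any gating:
#' pure exponential relaxation `x0 * exp((g - 1) t)`.
#'
#' @param t time(s) since stimulus offset (`>= 0`).
#' @param g feed-forward coupling.
#' @param x0 loaded level.
#' @return activity envelope at `t`.
#' @export
persistent_envelope <- function(t, g, x0 = 1) {
  if (any(t < 0)) stop("persistent_envelope: t must be >= 0", call. = FALSE)
  x0 * exp((g - 1) * t)
}

#' Piecewise-exponential decay-amplify envelope
#'
#' Mean trajectory of a persistent cell under the full mechanism: decay at
#' rate `d` until the executive input at `t_s`, then amplification at rate
#' `a`:
#' `x0 exp(-d t)` for `t <= t_s` and `x0 exp(-d t_s) exp(a (t - t_s))`
#' after; continuous at `t_s`.
#'
#' @param t evaluation time(s).
#' @param t_s executive-input time(s), `0 <= t_s <= T` (recycled against
#'   `t`).
#' @param params a [rate_params()].
#' @return envelope value(s).
#' @export
decay_amplify_envelope <- function(t, t_s, params) {
  stopifnot(inherits(params, "wavemem_rates"))
  if (any(t_s < 0 | t_s > params$T))
    stop("decay_amplify_envelope: t_s outside [0, T]", call. = FALSE)
  ifelse(t <= t_s,
         params$x0 * exp(-params$d * t),
         params$x0 * exp(-params$d * t_s) * exp(params$a * (t - t_s)))
}

#' Minimal coupling for a bare line attractor
#'
#' The smallest feed-forward coupling `g` for which the relative
#' end-of-delay drift of the envelope stays within the resolution:
#' `|exp((g - 1) T) - 1| <= eps`, i.e. `g = 1 + log(1 - eps) / T`.
#' A network at least this well tuned needs no amplification at all.
#'
#' @param eps resolution, `0 < eps < 1`.
#' @param T delay length.
#' @return minimal coupling (approaches 1 as `eps -> 0` or `T -> Inf`).
#' @export
line_attractor_min_coupling <- function(eps, T) {
  if (!(eps > 0 && eps < 1) || !(T > 0))
    stop("line_attractor_min_coupling: need 0 < eps < 1 and T > 0",
         call. = FALSE)
  1 + log1p(-eps) / T
}

#' Admissible timing interval for the executive input
#'
#' Solves `|envelope(T; t_s) / x0 - 1| <= eps` for the executive-input time:
#' `lo = (a T - log(1 + eps)) / (a + d)`,
#' `hi = (a T - log(1 - eps)) / (a + d)`,
#' then clips to the delay period `[0, T]`. The unclipped bounds and length
#' `log((1 + eps) / (1 - eps)) / (a + d)` are retained, since the clipped
#' window is what the task allows while the algebraic length is what the
#' tuning theory predicts (it scales with `1 / (a + d)`: doubling `a + d`
#' halves it).
#'
#' @param params a [rate_params()] with `a + d > 0`.
#' @return an object of class `wavemem_interval`: list with `lo`, `hi`,
#'   `length`, `center` (clipped values) and `lo_raw`, `hi_raw`,
#'   `length_raw`, `center_raw`.
#' @export
timing_interval <- function(params) {
  stopifnot(inherits(params, "wavemem_rates"))
  d <- params$d; a <- params$a; eps <- params$eps; T <- params$T
  if (a + d <= 0)
    stop("timing_interval: degenerate regime, need a + d > 0", call. = FALSE)
  lo_raw <- (a * T - log1p(eps)) / (a + d)
  hi_raw <- (a * T - log1p(-eps)) / (a + d)
  lo <- min(max(lo_raw, 0), T)
  hi <- min(max(hi_raw, 0), T)
  structure(list(lo = lo, hi = hi, length = hi - lo,
                 center = (lo + hi) / 2,
                 lo_raw = lo_raw, hi_raw = hi_raw,
                 length_raw = hi_raw - lo_raw,
                 center_raw = (lo_raw + hi_raw) / 2,
                 params = params),
            class = "wavemem_interval")
}

#' @export
print.wavemem_interval <- function(x, ...) {
  cat(sprintf(
    "<timing interval: [%.4g, %.4g] (length %.4g, center %.4g); unclipped [%.4g, %.4g]>\n",
    x$lo, x$hi, x$length, x$center, x$lo_raw, x$hi_raw))
  invisible(x)
}

#' Small-resolution approximation of the timing-interval length
#'
#' Leading-order form `2 eps / (a + d)`: the admissible window for the
#' executive input depends on decay and amplification only through their
#' sum, and shrinks inversely with it.
#'
#' @param params a [rate_params()] with `a + d > 0`.
#' @return approximate interval length.
#' @export
interval_length_approx <- function(params) {
  stopifnot(inherits(params, "wavemem_rates"))
  if (params$a + params$d <= 0)
    stop("interval_length_approx: need a + d > 0", call. = FALSE)
  2 * params$eps / (params$a + params$d)
}

#' Exact linear-chain solution via the matrix exponential
#'
#' Propagates an initial activity profile through the noiseless maintenance
#' dynamics `x' = (-I + g S) x` (S the sub-diagonal shift), the linear
#' regime the chain occupies after stimulus removal with no gating. Serves
#' as the independent oracle for the Euler integrator and is asymptotically
#' consistent with [persistent_envelope()] for deep cells.
#'
#' @param x_init initial profile (length N).
#' @param g coupling.
#' @param t time point(s) `>= 0`.
#' @return matrix of profiles, `length(x_init)` x `length(t)`.
#' @export
chain_solution <- function(x_init, g, t) {
  if (any(t < 0)) stop("chain_solution: t must be >= 0", call. = FALSE)
  N <- length(x_init)
  A <- Matrix::Matrix(build_chain_weights(N, g) - diag(N), sparse = TRUE)
  out <- vapply(t, function(tt) {
    if (tt == 0) x_init
    else as.numeric(Matrix::expm(A * tt) %*% x_init)
  }, numeric(N))
  matrix(out, nrow = N)
}

#' Timing-interval table over a parameter grid
#'
#' Tabulates [timing_interval()] over the Cartesian grid of decay rates,
#' amplification rates, resolutions and delay lengths (the CLI `theory`
#' verb emits this as CSV).
#'
#' @param d,a,eps,T numeric vectors of rates, resolutions and delay lengths.
#' @param x0 loaded level (scalar; does not affect the interval).
#' @return data.frame with one row per grid point: clipped and unclipped
#'   bounds, lengths, centers, and the small-eps approximation.
#' @export
timing_table <- function(d = c(0.02, 0.05, 0.1), a = d, eps = 0.1, T = 6,
                         x0 = 0.8) {
  grid <- expand.grid(d = d, a = a, eps = eps, T = T,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- rate_params(d = grid$d[i], a = grid$a[i], eps = grid$eps[i],
                     T = grid$T[i], x0 = x0)
    iv <- timing_interval(p)
    data.frame(d = p$d, a = p$a, eps = p$eps, T = p$T,
               lo = iv$lo, hi = iv$hi, length = iv$length,
               center = iv$center, lo_raw = iv$lo_raw, hi_raw = iv$hi_raw,
               length_raw = iv$length_raw,
               length_approx = interval_length_approx(p))
  })
  do.call(rbind, rows)
}
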