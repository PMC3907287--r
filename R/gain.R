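#' Gain-function configurations
#'
#' The response function F converts summed presynaptic activity into
#' postsynaptic drive. External task events act on the network purely by
#' switching F between four configurations:
#'
#' * `"loading"`: a saturating gain whose stable fixed point draws the
#'   activity of stimulated cells to a stimulus-specific level.
#' * `"maintenance"`: the memory configuration. With `threshold = 0` and
#'   `slope = 1` it is the identity on non-negative input, so a unit-coupled
#'   chain behaves as a line attractor.
#' * `"comparison"`: a steep gain whose unstable fixed point acts as a
#'   separatrix at the level encoding the second stimulus; activity above it
#'   grows, below it collapses.
#' * `"quiescent"`: F is identically zero; the cell ignores all input. Late
#'   cells are held in this mode until the executive input arrives.
#'
#' F is rectified piecewise-linear: zero below `threshold`, rising with
#' `slope` above it, optionally clipped at `saturation`. It is never
#' negative.
#'
#' @param mode one of `"loading"`, `"maintenance"`, `"comparison"`,
#'   `"quiescent"`.
#' @param threshold activity threshold \eqn{\theta \ge 0} below which the
#'   drive is zero (dimensionless rate units).
#' @param slope gain \eqn{s > 0} above threshold.
#' @param saturation plateau level \eqn{M > 0}, or `Inf` / `"none"` for an
#'   unsaturated gain.
#' @return an object of class `wavemem_gain`.
#' @seealso [evaluate_gain()], [classify_fixed_points()]
#' @examples
#' F_maint <- gain_spec("maintenance")
#' evaluate_gain(F_maint, c(-0.2, 0, 0.5))
#' @export
gain_spec <- function(mode = c("maintenance", "loading", "comparison",
                               "quiescent"),
                      threshold = 0, slope = 1, saturation = Inf) {
  mode <- match.arg(mode)
  if (identical(saturation, "none")) saturation <- Inf
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0 ||
      !is.finite(threshold))
    stop("gain_spec: 'threshold' must be a finite number >= 0", call. = FALSE)
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) ||
      slope <= 0)
    stop("gain_spec: 'slope' must be a finite number > 0", call. = FALSE)
  if (!is.numeric(saturation) || length(saturation) != 1L || saturation <= 0)
    stop("gain_spec: 'saturation' must be > 0 or Inf/\"none\"", call. = FALSE)
  structure(list(mode = mode, threshold = threshold, slope = slope,
                 saturation = saturation),
            class = "wavemem_gain")
}

#' @export
print.wavemem_gain <- function(x, ...) {
  cat(sprintf("<gain F: %s | theta = %g, slope = %g, saturation = %s>\n",
              x$mode, x$threshold, x$slope,
              if (is.finite(x$saturation)) format(x$saturation) else "none"))
  invisible(x)
}

#' Evaluate the response function F
#'
#' @param spec a [gain_spec()].
#' @param u summed presynaptic input (numeric vector; may be negative, since
#'   noise enters the state outside of F).
#' @return postsynaptic drive, same length as `u`; always `>= 0`, and exactly
#'   0 below threshold. Quiescent mode returns 0 for every input.
#' @export
evaluate_gain <- function(spec, u) {
  stopifnot(inherits(spec, "wavemem_gain"))
  if (any(!is.finite(u)))
    stop("evaluate_gain: 'u' must be finite", call. = FALSE)
  if (spec$mode == "quiescent") return(numeric(length(u)) )
  y <- spec$slope * (u - spec$threshold)
  y[u < spec$threshold] <- 0
  pmin(y, spec$saturation)
}

#' Map a stimulus value to a loaded activity level
#'
#' Positively monotonic encoding: the loading configuration of F draws the
#' activity of stimulated cells to a level that increases with the stimulus
#' variable (e.g. vibration frequency). `stimulus_map()` fixes that map;
#' `load_level()` evaluates it. The default map is linear from
#' f in \[10, 34\] (frequency-like units) onto activity in \[0.4, 1.2\].
#'
#' @param f_min,f_max stimulus-variable bounds.
#' @param x_lo,x_hi loaded activity levels at `f_min` and `f_max`;
#'   `x_hi > x_lo` (increasing encoders only).
#' @return an object of class `wavemem_map`.
#' @examples
#' m <- stimulus_map()
#' load_level(m, c(10, 22, 34))
#' @export
stimulus_map <- function(f_min = 10, f_max = 34, x_lo = 0.4, x_hi = 1.2) {
  if (!(f_max > f_min)) stop("stimulus_map: f_max must exceed f_min",
                             call. = FALSE)
  if (!(x_hi > x_lo) || x_lo < 0)
    stop("stimulus_map: need 0 <= x_lo < x_hi", call. = FALSE)
  structure(list(f_min = f_min, f_max = f_max, x_lo = x_lo, x_hi = x_hi),
            class = "wavemem_map")
}

#' @rdname stimulus_map
#' @param map a `wavemem_map`.
#' @param f stimulus value(s) in `[f_min, f_max]`.
#' @export
load_level <- function(map, f) {
  stopifnot(inherits(map, "wavemem_map"))
  if (any(f < map$f_min | f > map$f_max))
    stop(sprintf("load_level: f outside [%g, %g]", map$f_min, map$f_max),
         call. = FALSE)
  map$x_lo + (f - map$f_min) / (map$f_max - map$f_min) * (map$x_hi - map$x_lo)
}

#' Fixed points of the single-cell self-consistency map
#'
#' Solves `x = F(g x)` on `x >= 0` for a cell receiving its own activity
#' through coupling `g`, and classifies each solution by the local slope of
#' `F(g x)`: slope < 1 stable, > 1 unstable, = 1 a neutral continuum (line
#' attractor). This reproduces the phase portraits of the four task
#' configurations: loading has a stable fixed point at the saturation level,
#' maintenance with unit loop gain is a line attractor, comparison has an
#' unstable separatrix.
#'
#' @param spec a [gain_spec()].
#' @param g loop coupling strength (`>= 0`).
#' @return a data.frame with columns `level` and `stability`
#'   (`"stable"`, `"unstable"`, `"neutral-continuum"`). For a continuum the
#'   row carries the lower end in `level` and the upper end in the
#'   `"continuum_hi"` attribute. May have zero rows only in degenerate
#'   cases (never here, since x = 0 is always fixed).
#' @export
classify_fixed_points <- function(spec, g) {
  stopifnot(inherits(spec, "wavemem_gain"), is.numeric(g), g >= 0)
  fp <- data.frame(level = numeric(0), stability = character(0),
                   stringsAsFactors = FALSE)
  add <- function(level, stability)
    rbind(fp, data.frame(level = level, stability = stability,
                         stringsAsFactors = FALSE))
  if (spec$mode == "quiescent" || g == 0)
    return(add(0, "stable"))
  s <- spec$slope; th <- spec$threshold; M <- spec$saturation
  sg <- s * g
  if (th == 0 && sg == 1) {
    # every x with F unsaturated is fixed: the line attractor
    hi <- if (is.finite(M)) M else Inf
    fp <- add(0, "neutral-continuum")
    attr(fp, "continuum_hi") <- hi
    return(fp)
  }
  # x = 0: F(0) = 0 always (theta >= 0); local slope is 0 when th > 0
  slope0 <- if (th > 0) 0 else sg
  fp <- add(0, if (slope0 < 1) "stable" else "unstable")
  # interior linear-branch solution x = s (g x - th)
  if (sg > 1 && th > 0) {
    xs <- s * th / (sg - 1)
    if (g * xs >= th && s * (g * xs - th) <= M)
      fp <- add(xs, "unstable")
  }
  # saturated solution x = M (requires F(gM) to have reached the plateau)
  if (is.finite(M) && s * (g * M - th) >= M)
    fp <- add(M, "stable")
  fp[order(fp$level), , drop = FALSE]
}
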