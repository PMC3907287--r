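#' Task schedule
#'
#' Timeline of the delayed-discrimination task in model time units (the
#' membrane time constant is the unit, tau = 1). Time 0 is stimulus offset,
#' i.e. the start of the delay period. The executive input arrives at
#' `t_exec` (gating the late cells and switching on their feedback), the
#' delay ends at `T`, and the comparison stimulus `f2` then acts for
#' `t_cmp_len` time units.
#'
#' @param T delay-period length.
#' @param t_exec executive-input time `t_s`, `0 <= t_exec <= T`. Use
#'   `t_exec = Inf` (or `t_exec = T` with zero feedback) for a plain run in
#'   which the gate never opens.
#' @param t_cmp_len comparison-window length (`> 0`).
#' @param f1,f2 first and second stimulus values, interpreted through a
#'   [stimulus_map()].
#' @return an object of class `wavemem_schedule`.
#' @export
task_schedule <- function(T = 150, t_exec = T / 2, t_cmp_len = 1,
                          f1 = 22, f2 = f1) {
  if (!(T > 0)) stop("task_schedule: T must be > 0", call. = FALSE)
  if (!(t_exec >= 0) || (is.finite(t_exec) && t_exec > T))
    stop("task_schedule: need 0 <= t_exec <= T (or Inf)", call. = FALSE)
  if (!(t_cmp_len > 0))
    stop("task_schedule: t_cmp_len must be > 0", call. = FALSE)
  structure(list(T = T, t_exec = t_exec, t_cmp_len = t_cmp_len,
                 f1 = f1, f2 = f2),
            class = "wavemem_schedule")
}

#' @export
print.wavemem_schedule <- function(x, ...) {
  cat(sprintf(
    "<schedule: delay T = %g, executive input t_s = %g, comparison %g | f1 = %g, f2 = %g>\n",
    x$T, x$t_exec, x$t_cmp_len, x$f1, x$f2))
  invisible(x)
}

#' Task phase and late-cell gate state at a time point
#'
#' @param t time(s), `>= 0`.
#' @param schedule a [task_schedule()].
#' @return data.frame with columns `t`, `phase` (`"maintenance"` or
#'   `"comparison"`) and `gate_open` (logical). The gate is open for
#'   `t >= t_exec` (closed-interval convention); the comparison phase is
#'   `t > T`.
#' @export
phase_at <- function(t, schedule) {
  stopifnot(inherits(schedule, "wavemem_schedule"))
  if (any(t < 0)) stop("phase_at: t must be >= 0", call. = FALSE)
  data.frame(t = t,
             phase = ifelse(t > schedule$T, "comparison", "maintenance"),
             gate_open = t >= schedule$t_exec,
             stringsAsFactors = FALSE)
}
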