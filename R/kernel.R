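#' Symmetric-kernel field model configuration
#'
#' Recurrent variant of the mechanism with no directional bias: the
#' early/persistent population is a line of `N_x` cells coupled through a
#' symmetric, non-negative Gaussian-shaped kernel of spatial scale
#' `kernel_sd` (cell-index units), truncated at `trunc_sd` standard
#' deviations and normalised to unit mass on the unbounded domain. No
#' boundary renormalisation is applied, so cells near the edges lose kernel
#' mass, decay first, and launch trailing wavefronts that travel inward
#' from both boundaries; interior cells sit exactly on the line-attractor
#' balance when `gbar = 1` (the default, since the discrete kernel weights
#' sum to one).
#'
#' The late cells form a second line of `N_x` cells receiving divergent,
#' uniform-weight drive from the whole early/persistent population (gated
#' to zero before `t_exec`) and feeding back one-to-one with strength `c`.
#'
#' @param N_x number of early/persistent grid cells.
#' @param kernel_sd kernel spatial scale in cell-index units.
#' @param trunc_sd truncation radius in standard deviations.
#' @param gbar coupling scale; `NULL` uses 1, which balances interior cells
#'   exactly on the discrete grid.
#' @param c one-to-one feedback strength from the late line.
#' @param sigma,dt as in [chain_config()].
#' @return an object of class `wavemem_kernel`.
#' @export
kernel_config <- function(N_x = 300, kernel_sd = 5, trunc_sd = 4,
                          gbar = NULL, c = 0.01, sigma = 0, dt = 0.01) {
  if (!(N_x >= 10)) stop("kernel_config: N_x must be >= 10", call. = FALSE)
  if (!(kernel_sd > 0) || !(trunc_sd > 0))
    stop("kernel_config: kernel_sd and trunc_sd must be > 0", call. = FALSE)
  if (is.null(gbar)) gbar <- 1
  if (gbar < 0 || c < 0 || sigma < 0 || dt <= 0)
    stop("kernel_config: need gbar >= 0, c >= 0, sigma >= 0, dt > 0",
         call. = FALSE)
  structure(list(N_x = as.integer(N_x), kernel_sd = kernel_sd,
                 trunc_sd = trunc_sd, gbar = gbar, c = c, sigma = sigma,
                 dt = dt),
            class = "wavemem_kernel")
}

#' @export
print.wavemem_kernel <- function(x, ...) {
  cat(sprintf(
    "<kernel field: %d cells, Gaussian sd = %g (trunc %g sd), gbar = %g, c = %g, sigma = %g>\n",
    x$N_x, x$kernel_sd, x$trunc_sd, x$gbar, x$c, x$sigma))
  invisible(x)
}

# discrete symmetric kernel weights, unit mass over the truncated support
.kernel_weights <- function(kernel_sd, trunc_sd) {
  r <- as.integer(ceiling(trunc_sd * kernel_sd))
  m <- (-r):r
  w <- exp(-m^2 / (2 * kernel_sd^2))
  w / sum(w)
}

# connectivity matrix: rows are NOT renormalised at the boundaries
.kernel_matrix <- function(N_x, kernel_sd, trunc_sd) {
  w <- .kernel_weights(kernel_sd, trunc_sd)
  r <- (length(w) - 1L) / 2L
  K <- matrix(0, N_x, N_x)
  for (i in seq_len(N_x)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= N_x
    K[i, j[ok]] <- w[ok]
  }
  K
}

#' Simulate the symmetric-kernel field model
#'
#' Euler-Maruyama integration of the two coupled lines
#' `du_i = (-u_i + F(gbar (K u)_i + c v_i [gate])) dt + sigma dB_i` and
#' `dv_i = (-v_i + F_late(mean(u))) dt + sigma dB_i`,
#' where `F_late` is quiescent before `t_exec` and maintenance afterwards.
#' The early/persistent line starts at the loaded level on every cell; the
#' late line starts at rest.
#'
#' @param config a [kernel_config()].
#' @param schedule a [task_schedule()].
#' @param seed integer seed.
#' @param map a [stimulus_map()].
#' @param x0 optional explicit loaded level.
#' @param record_every thinning factor for the stored trajectory.
#' @return a `wavemem_sim` whose `activity` holds the early/persistent line
#'   u and whose `late` matrix holds the late line v.
#' @export
simulate_kernel <- function(config, schedule, seed = 1L,
                            map = stimulus_map(), x0 = NULL,
                            record_every = 1L) {
  stopifnot(inherits(config, "wavemem_kernel"),
            inherits(schedule, "wavemem_schedule"))
  if (is.null(x0)) x0 <- load_level(map, schedule$f1)
  N <- config$N_x; dt <- config$dt; sig <- config$sigma
  K <- config$gbar * .kernel_matrix(N, config$kernel_sd, config$trunc_sd)
  nstep <- as.integer(round(schedule$T / dt))
  gate_step <- if (is.finite(schedule$t_exec))
    as.integer(ceiling(schedule$t_exec / dt - 1e-9)) else NA_integer_
  u <- rep(x0, N)
  v <- numeric(N)
  keep <- seq.int(0L, nstep, by = as.integer(record_every))
  if (keep[length(keep)] != nstep) keep <- c(keep, nstep)
  out_u <- matrix(NA_real_, N, length(keep)); out_u[, 1L] <- u
  out_v <- matrix(NA_real_, N, length(keep)); out_v[, 1L] <- v
  ki <- 2L
  sq <- sig * sqrt(dt)
  gate <- FALSE
  set.seed(as.integer(seed))
  for (s in seq_len(nstep)) {
    if (!gate && !is.na(gate_step) && s > gate_step) gate <- TRUE
    inp <- as.numeric(K %*% u)
    if (gate && config$c > 0) inp <- inp + config$c * v
    du <- pmax(inp, 0) - u
    dv <- (if (gate) pmax(mean(u), 0) else 0) - v
    u <- u + dt * du
    v <- v + dt * dv
    if (sig > 0) {
      u <- u + sq * stats::rnorm(N)
      v <- v + sq * stats::rnorm(N)
    }
    if (s == keep[ki]) {
      if (!all(is.finite(u)) || !all(is.finite(v)))
        stop(sprintf("simulate_kernel: non-finite state at step %d (t = %g)",
                     s, s * dt), call. = FALSE)
      out_u[, ki] <- u; out_v[, ki] <- v
      ki <- ki + 1L
    }
  }
  structure(list(times = keep * dt, activity = out_u, late = out_v,
                 seed = as.integer(seed), config = config,
                 schedule = schedule, map = map, x0 = x0),
            class = "wavemem_sim")
}
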