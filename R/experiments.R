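#' Default experiment worlds
#'
#' Two documented parameter worlds are used by the scripted experiments.
#'
#' `sweep_world()` is the quantitative timing world: a short delay (`T = 6`
#' time constants) with matched decay/amplification rates
#' `d = a` in {0.02, 0.05, 0.1} and resolution `eps = 0.1`, for which all
#' three analytic timing intervals lie strictly inside the delay period.
#' Readout uses the last 10 persistent cells.
#'
#' `raster_world()` is the phenomenology world: a long delay
#' (`T = 150` time constants, i.e. a 3 s delay at tau = 20 ms) during which
#' the travelling fronts traverse the 150-cell chain, with gentle rates
#' `d = a = 0.005` and noise `sigma = 0.005`. This is the world in which
#' early/persistent/late classification, the U-shaped encoding count, and
#' front tracking are measured.
#'
#' @param d decay rate (`= 1 - g`); amplification is matched (`a = d`)
#'   through [feedback_strength()].
#' @param sigma noise strength.
#' @param T delay length; `t_exec` defaults to the midpoint.
#' @param t_exec executive-input time.
#' @param f1 first stimulus value.
#' @return list with components `config` ([chain_config()]) and `schedule`
#'   ([task_schedule()]).
#' @export
sweep_world <- function(d = 0.05, sigma = 0.01, T = 6, t_exec = T / 2,
                        f1 = 22) {
  g <- 1 - d
  list(config = chain_config(g = g,
                             c = if (d > 0) feedback_strength(g, d) else 0,
                             sigma = sigma),
       schedule = task_schedule(T = T, t_exec = t_exec, f1 = f1))
}

#' @rdname sweep_world
#' @export
raster_world <- function(d = 0.005, sigma = 0.005, T = 150, t_exec = T / 2,
                         f1 = 22) {
  sweep_world(d = d, sigma = sigma, T = T, t_exec = t_exec, f1 = f1)
}

#' Sweep specification
#'
#' Grid of executive-input times and noise strengths for a Monte-Carlo
#' success-rate sweep, with the fixed chain configuration and schedule
#' template. Every (grid point, repetition) pair receives a distinct seed
#' derived from `base_seed` via [derive_seed()].
#'
#' @param t_s_grid executive-input times (nonempty, within `[0, T]`).
#' @param sigma_grid noise strengths (nonempty).
#' @param reps trials per grid point (`>= 1`; the reference protocol uses
#'   200).
#' @param base_seed integer base seed.
#' @param config a [chain_config()] (its `sigma` is overridden per grid
#'   point).
#' @param schedule a [task_schedule()] (its `t_exec` is overridden).
#' @param eps resolution defining the success band.
#' @return an object of class `wavemem_sweep`.
#' @export
sweep_spec <- function(t_s_grid, sigma_grid = c(0, 0.005, 0.01, 0.02),
                       reps = 200, base_seed = 1L,
                       config = sweep_world()$config,
                       schedule = sweep_world()$schedule, eps = 0.1) {
  if (!length(t_s_grid) || !length(sigma_grid))
    stop("sweep_spec: grids must be nonempty", call. = FALSE)
  if (any(t_s_grid < 0 | t_s_grid > schedule$T))
    stop("sweep_spec: t_s_grid outside [0, T]", call. = FALSE)
  if (reps < 1) stop("sweep_spec: reps >= 1 required", call. = FALSE)
  structure(list(t_s_grid = t_s_grid, sigma_grid = sigma_grid,
                 reps = as.integer(reps), base_seed = as.integer(base_seed),
                 config = config, schedule = schedule, eps = eps),
            class = "wavemem_sweep")
}

.report <- function(table, meta) {
  structure(list(table = table, meta = meta), class = "wavemem_report")
}

#' @export
print.wavemem_report <- function(x, ...) {
  cat(sprintf("<experiment report: %s | %d rows>\n",
              x$meta$experiment, nrow(x$table)))
  print(utils::head(x$table, 10))
  if (nrow(x$table) > 10) cat("...\n")
  invisible(x)
}

#' Monte-Carlo success-rate sweep over executive-input timing
#'
#' For every (t_s, sigma) grid point, runs `reps` seeded trials of the
#' chain, scores each with [trial_success()], and tabulates the success
#' rate with its binomial standard error. The analytic timing-interval
#' boundaries for the configuration are attached to the metadata for
#' overlay.
#'
#' @param spec a [sweep_spec()].
#' @return a `wavemem_report`; `table` has columns `t_s`, `sigma`, `reps`,
#'   `successes`, `rate`, `se`.
#' @export
run_success_sweep <- function(spec) {
  stopifnot(inherits(spec, "wavemem_sweep"))
  t_start <- Sys.time()
  cfg <- spec$config
  rec <- max(1L, as.integer(round(spec$schedule$T / cfg$dt)))
  grid <- expand.grid(t_s = spec$t_s_grid, sigma = spec$sigma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  n_succ <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg_i <- cfg; cfg_i$sigma <- grid$sigma[i]
    sch_i <- spec$schedule; sch_i$t_exec <- grid$t_s[i]
    point_base <- derive_seed(spec$base_seed, i)
    succ <- vapply(seq_len(spec$reps), function(r) {
      sim <- simulate_chain(cfg_i, sch_i, seed = derive_seed(point_base, r),
                            record_every = rec)
      as.logical(trial_success(sim, eps = spec$eps))
    }, logical(1))
    n_succ[i] <- sum(succ)
  }
  rate <- n_succ / spec$reps
  tab <- data.frame(t_s = grid$t_s, sigma = grid$sigma, reps = spec$reps,
                    successes = n_succ, rate = rate,
                    se = sqrt(pmax(rate * (1 - rate), 0) / spec$reps))
  a <- amplification_rate(cfg$g, cfg$c)
  iv <- timing_interval(rate_params(d = 1 - cfg$g, a = a, eps = spec$eps,
                                    T = spec$schedule$T,
                                    x0 = load_level(stimulus_map(),
                                                    spec$schedule$f1)))
  .report(tab, list(experiment = "success_sweep",
                    base_seed = spec$base_seed, eps = spec$eps,
                    d = 1 - cfg$g, a = a,
                    interval = iv[c("lo", "hi", "length", "center")],
                    config = unclass(cfg),
                    schedule = unclass(spec$schedule),
                    package_version = as.character(
                      utils::packageVersion("wavemem")),
                    wall_time_s = as.numeric(difftime(Sys.time(), t_start,
                                                      units = "secs"))))
}

#' Interpolated 0.5-crossings of a success-rate curve
#'
#' @param report a `wavemem_report` from [run_success_sweep()].
#' @param sigma which noise level to extract.
#' @return list with `up` (first rise through 0.5) and `down` (last fall
#'   through 0.5), linearly interpolated; `NA` when the curve does not
#'   cross.
#' @export
success_curve_crossings <- function(report, sigma) {
  tab <- report$table[report$table$sigma == sigma, ]
  tab <- tab[order(tab$t_s), ]
  r <- tab$rate; t <- tab$t_s
  interp <- function(i) t[i] + (0.5 - r[i]) / (r[i + 1] - r[i]) *
    (t[i + 1] - t[i])
  up <- NA_real_; down <- NA_real_
  for (i in seq_len(length(r) - 1)) {
    if (is.na(up) && r[i] < 0.5 && r[i + 1] >= 0.5) up <- interp(i)
    if (r[i] >= 0.5 && r[i + 1] < 0.5) down <- interp(i)
  }
  list(up = up, down = down)
}

#' Noise integration: decay-amplify versus line attractor
#'
#' Records the end-of-delay activity of a single cell (the last persistent
#' cell) across `reps` trials for a perfect line attractor (`g = 1`,
#' `c = 0`, no gating) and for decay-amplify configurations whose matched
#' rates make the noiseless endpoint equal to the line attractor's (the
#' executive input arrives at the analytic interval center). Reports means,
#' variances and variance ratios against the line attractor at each noise
#' strength.
#'
#' @param d_grid matched decay/amplification rates of the decay-amplify
#'   configurations.
#' @param sigma_grid noise strengths.
#' @param reps trials per configuration and noise strength.
#' @param base_seed integer seed.
#' @param T delay length.
#' @param f1 stimulus value.
#' @param eps resolution (sets the interval center used for `t_exec`).
#' @return a `wavemem_report`; `table` columns `model`, `d`, `sigma`,
#'   `reps`, `mean`, `var`, `var_ratio`.
#' @export
run_noise_comparison <- function(d_grid = c(0.05, 0.1),
                                 sigma_grid = c(0, 0.005, 0.01, 0.02),
                                 reps = 200, base_seed = 1L, T = 6, f1 = 22,
                                 eps = 0.1) {
  t_start <- Sys.time()
  rows <- list()
  for (sg in sigma_grid) {
    # all models at this noise level share the same per-trial seeds (common
    # random numbers), so the sampling fluctuation of the variance estimate
    # largely cancels in the variance ratios
    seed_sg <- derive_seed(base_seed, round(sg * 1e5))
    # line attractor: exact tuning, gate never opens
    w <- sweep_world(d = 0, sigma = sg, T = T, f1 = f1)
    w$schedule$t_exec <- Inf
    ends_la <- .endpoint_samples(w$config, w$schedule, reps, seed_sg)
    rows[[length(rows) + 1]] <-
      data.frame(model = "line_attractor", d = 0, sigma = sg, reps = reps,
                 mean = mean(ends_la), var = stats::var(ends_la),
                 var_ratio = 1)
    for (dd in d_grid) {
      iv <- timing_interval(rate_params(d = dd, a = dd, eps = eps, T = T))
      w2 <- sweep_world(d = dd, sigma = sg, T = T, t_exec = iv$center,
                        f1 = f1)
      ends <- .endpoint_samples(w2$config, w2$schedule, reps, seed_sg)
      rows[[length(rows) + 1]] <-
        data.frame(model = "decay_amplify", d = dd, sigma = sg, reps = reps,
                   mean = mean(ends), var = stats::var(ends),
                   var_ratio = if (sg > 0) stats::var(ends) /
                     stats::var(ends_la) else NA_real_)
    }
  }
  tab <- do.call(rbind, rows)
  .report(tab, list(experiment = "noise_comparison", base_seed = base_seed,
                    readout = "last persistent cell", T = T, f1 = f1,
                    eps = eps,
                    package_version = as.character(
                      utils::packageVersion("wavemem")),
                    wall_time_s = as.numeric(difftime(Sys.time(), t_start,
                                                      units = "secs"))))
}

.endpoint_samples <- function(config, schedule, reps, base_seed) {
  rec <- max(1L, as.integer(round(schedule$T / config$dt)))
  vapply(seq_len(reps), function(r) {
    sim <- simulate_chain(config, schedule, seed = derive_seed(base_seed, r),
                          record_every = rec)
    attr(trial_success(sim, eps = Inf, readout = "cell"), "readout_value")
  }, numeric(1))
}

#' Delay-length stretch experiment
#'
#' Retunes the network to a doubled delay period by moving a single
#' parameter: the executive-input time. Three noiseless runs are compared:
#' the original delay `T` with the input at its midpoint, the doubled delay
#' `2T` with the input at the new midpoint `T`, and the mistimed control
#' (doubled delay, input left at `T/2`). For a fixed late cell (the first
#' late cell) the first half-maximum crossing ("onset") is recorded; the
#' onset ratio between the retuned and original runs is approximately 2,
#' while the mistimed control overshoots the success band.
#'
#' The default delay here is shorter than the raster world's because with
#' `sigma = 0` there is no noise floor to prop the trailing front, which
#' would otherwise erode the whole persistent block during the doubled
#' delay.
#'
#' @param T original delay length.
#' @param d matched decay/amplification rate.
#' @param f1 stimulus value.
#' @param eps resolution for the success band.
#' @param base_seed integer seed (the runs are noiseless; retained for the
#'   report contract).
#' @return a `wavemem_report`; `table` columns `run`, `T`, `t_exec`,
#'   `onset`, `success`; metadata carries `onset_ratio`.
#' @export
run_stretch_experiment <- function(T = 30, d = 0.005, f1 = 22, eps = 0.1,
                                   base_seed = 1L) {
  t_start <- Sys.time()
  runs <- data.frame(run = c("original", "retuned", "mistimed"),
                     T = c(T, 2 * T, 2 * T),
                     t_exec = c(T / 2, T, T / 2))
  onset <- numeric(3); success <- logical(3)
  for (i in 1:3) {
    w <- sweep_world(d = d, sigma = 0, T = runs$T[i],
                     t_exec = runs$t_exec[i], f1 = f1)
    sim <- simulate_chain(w$config, w$schedule,
                          seed = derive_seed(base_seed, i),
                          record_every = 10L)
    tr <- sim$activity[w$config$n_stim + 1L, ]
    k <- which(tr >= 0.5 * sim$x0)[1]
    onset[i] <- if (is.na(k)) NA_real_ else sim$times[k]
    success[i] <- as.logical(trial_success(sim, eps = eps))
  }
  runs$onset <- onset; runs$success <- success
  .report(runs, list(experiment = "stretch", base_seed = base_seed,
                     d = d, eps = eps,
                     onset_ratio = onset[2] / onset[1],
                     tracked_cell = "first late cell",
                     package_version = as.character(
                       utils::packageVersion("wavemem")),
                     wall_time_s = as.numeric(difftime(Sys.time(), t_start,
                                                       units = "secs"))))
}

#' Catalogue of single-cell activity patterns
#'
#' Reproduces the four qualitative delay-period patterns of a persistent
#' cell under the linear-filter dynamics, as the sign of the activity slope
#' before and after the executive input:
#' decline throughout (`g < 1`, weak feedback), decline then rise
#' (`g < 1`, feedback strong enough to amplify), rise then fall (`g > 1`,
#' the cell is overtaken by the trailing front), and rise throughout
#' (`g > 1`, not overtaken within the delay).
#'
#' @param base_seed integer seed (runs are noiseless by default).
#' @param sigma noise strength.
#' @return a `wavemem_report`; `table` columns `scenario`, `g`, `c`,
#'   `cell`, `slope_before`, `slope_after`, `pattern`.
#' @export
run_pattern_catalogue <- function(base_seed = 1L, sigma = 0) {
  t_start <- Sys.time()
  T <- 40; t_exec <- 20
  scen <- list(
    list(name = "decay_weak_feedback",   g = 0.98, c = 0.005, cell = 90L),
    list(name = "decay_strong_feedback", g = 0.98,
         c = feedback_strength(0.98, 0.02), cell = 90L),
    list(name = "growth_caught",         g = 1.02, c = 0,     cell = 25L),
    list(name = "growth_not_caught",     g = 1.02, c = 0,     cell = 90L))
  rows <- lapply(seq_along(scen), function(i) {
    s <- scen[[i]]
    cfg <- chain_config(g = s$g, c = s$c, sigma = sigma)
    sch <- task_schedule(T = T, t_exec = t_exec)
    sim <- simulate_chain(cfg, sch, seed = derive_seed(base_seed, i),
                          record_every = 10L)
    tr <- sim$activity[s$cell, ]
    sl <- function(w) {
      ti <- sim$times >= w[1] & sim$times <= w[2]
      unname(stats::coef(stats::lm(tr[ti] ~ sim$times[ti]))[2])
    }
    b <- sl(c(0, t_exec)); a <- sl(c(t_exec, T))
    data.frame(scenario = s$name, g = s$g, c = s$c, cell = s$cell,
               slope_before = b, slope_after = a,
               pattern = paste0(ifelse(b > 0, "+", "-"),
                                ifelse(a > 0, "+", "-")))
  })
  tab <- do.call(rbind, rows)
  .report(tab, list(experiment = "pattern_catalogue", base_seed = base_seed,
                    T = T, t_exec = t_exec, sigma = sigma,
                    package_version = as.character(
                      utils::packageVersion("wavemem")),
                    wall_time_s = as.numeric(difftime(Sys.time(), t_start,
                                                      units = "secs"))))
}
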