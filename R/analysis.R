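#' Monotonic-encoding criterion
#'
#' Operational definition of "the cell encodes the stimulus at time t":
#' across an ensemble of trials spanning a grid of first-stimulus values,
#' the trial-mean activities must be strictly increasing in the stimulus
#' AND the spread of the means must exceed `k_sd` times the pooled
#' within-stimulus standard deviation. The first clause captures monotone
#' tuning; the second rejects tuning that is buried in trial-to-trial
#' noise. Under label permutation the false-positive rate is at most
#' `1 / factorial(length(f1_grid))` (strict ordering of exchangeable means).
#'
#' @param f1_grid stimulus values (at least 5, spanning the map).
#' @param reps noisy trials per stimulus value (`>= 1`).
#' @param k_sd separation multiplier (`> 0`).
#' @return an object of class `wavemem_criterion`.
#' @export
encoding_criterion <- function(f1_grid = c(10, 16, 22, 28, 34), reps = 20,
                               k_sd = 2) {
  if (length(f1_grid) < 2 || is.unsorted(f1_grid, strictly = TRUE))
    stop("encoding_criterion: f1_grid must be strictly increasing",
         call. = FALSE)
  if (reps < 1) stop("encoding_criterion: reps >= 1 required", call. = FALSE)
  if (!(k_sd > 0)) stop("encoding_criterion: k_sd > 0 required",
                        call. = FALSE)
  structure(list(f1_grid = f1_grid, reps = as.integer(reps), k_sd = k_sd),
            class = "wavemem_criterion")
}

#' Simulate a tuning ensemble over a stimulus grid
#'
#' Runs `reps` seeded trials of [simulate_chain()] for every stimulus value
#' in the criterion's grid, with otherwise identical configuration. Trial
#' seeds derive from `base_seed` via [derive_seed()].
#'
#' @param config a [chain_config()].
#' @param schedule a [task_schedule()]; its `f1` is replaced by each grid
#'   value in turn.
#' @param criterion an [encoding_criterion()].
#' @param base_seed integer base seed.
#' @param map a [stimulus_map()].
#' @param record_every thinning factor passed to the simulator (default
#'   records once per time constant at `dt = 0.01`).
#' @param init passed to [simulate_chain()].
#' @return an object of class `wavemem_ensemble`: array
#'   `f1 x rep x cell x time` plus the recorded time grid and metadata.
#' @export
simulate_ensemble <- function(config, schedule, criterion, base_seed = 1L,
                              map = stimulus_map(), record_every = 100L,
                              init = "block") {
  stopifnot(inherits(criterion, "wavemem_criterion"))
  nf <- length(criterion$f1_grid); reps <- criterion$reps
  first <- NULL
  arr <- NULL
  for (i in seq_len(nf)) {
    sch <- schedule
    sch$f1 <- criterion$f1_grid[i]
    for (r in seq_len(reps)) {
      sim <- simulate_chain(config, sch,
                            seed = derive_seed(base_seed, (i - 1L) * reps + r),
                            map = map, record_every = record_every,
                            init = init)
      if (is.null(arr)) {
        first <- sim
        arr <- array(NA_real_, c(nf, reps, nrow(sim$activity),
                                 length(sim$times)))
      }
      arr[i, r, , ] <- sim$activity
    }
  }
  structure(list(activity = arr, times = first$times,
                 criterion = criterion, config = config, schedule = schedule,
                 map = map, base_seed = as.integer(base_seed)),
            class = "wavemem_ensemble")
}

#' @export
print.wavemem_ensemble <- function(x, ...) {
  d <- dim(x$activity)
  cat(sprintf(
    "<ensemble: %d stimuli x %d reps x %d cells x %d time points>\n",
    d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Encoding status of every cell at every recorded time
#'
#' Applies the [encoding_criterion()] to a [simulate_ensemble()] result.
#'
#' @param ensemble a `wavemem_ensemble`.
#' @return logical matrix, cells x time points; attribute `"times"` carries
#'   the time grid.
#' @export
encoding_matrix <- function(ensemble) {
  stopifnot(inherits(ensemble, "wavemem_ensemble"))
  enc <- .encode(ensemble$activity, ensemble$criterion$k_sd)
  attr(enc, "times") <- ensemble$times
  enc
}

# core criterion on a raw (f1, rep, cell, time) array; also used by the
# permutation oracle in the tests
.encode <- function(arr, k_sd) {
  d <- dim(arr)
  if (d[2] > 1) {
    m <- apply(arr, c(1, 3, 4), mean)
    v <- apply(arr, c(1, 3, 4), stats::var)
    pooled <- sqrt(apply(v, c(2, 3), mean))
  } else {
    m <- array(arr[, 1, , ], d[c(1, 3, 4)])
    pooled <- matrix(0, d[3], d[4])
  }
  mono <- apply(m, c(2, 3), function(z) all(diff(z) > 0))
  rng <- apply(m, c(2, 3), function(z) max(z) - min(z))
  mono & (rng > k_sd * pooled)
}

#' Is a cell encoding the stimulus at a time point?
#'
#' @param ensemble a `wavemem_ensemble`.
#' @param cell cell index.
#' @param t time (matched to the nearest recorded point).
#' @param enc optional precomputed [encoding_matrix()] to avoid
#'   recomputation.
#' @return logical.
#' @export
is_encoding <- function(ensemble, cell, t, enc = NULL) {
  if (is.null(enc)) enc <- encoding_matrix(ensemble)
  ti <- which.min(abs(attr(enc, "times") - t))
  enc[cell, ti]
}

#' Classify cells as early, persistent, late or unresponsive
#'
#' A cell "encodes in a window" when it satisfies the encoding criterion at
#' more than half of the window's recorded time points (majority rule; this
#' is robust to single-point noise at the window edges). Early cells encode
#' in the early window but not the late one; late cells the converse;
#' persistent cells both; unresponsive cells neither.
#'
#' @param ensemble a `wavemem_ensemble`.
#' @param early_window,late_window window lengths as fractions of the delay
#'   period (defaults: first and last 10%).
#' @param enc optional precomputed [encoding_matrix()].
#' @return an object of class `wavemem_classification`: list with `labels`
#'   (factor per cell), `count` (encoding-count time series), `times`, and
#'   the window definitions.
#' @export
classify_cells <- function(ensemble, early_window = 0.1, late_window = 0.1,
                           enc = NULL) {
  stopifnot(inherits(ensemble, "wavemem_ensemble"))
  if (!(early_window > 0 && early_window < 1) ||
      !(late_window > 0 && late_window < 1) ||
      early_window + late_window > 1)
    stop("classify_cells: windows must be positive fractions with sum <= 1",
         call. = FALSE)
  if (is.null(enc)) enc <- encoding_matrix(ensemble)
  times <- attr(enc, "times")
  T <- ensemble$schedule$T
  ew <- times <= early_window * T
  lw <- times >= (1 - late_window) * T & times <= T
  in_w <- function(cell, w) mean(enc[cell, w]) > 0.5
  lab <- vapply(seq_len(nrow(enc)), function(cc) {
    e <- in_w(cc, ew); l <- in_w(cc, lw)
    if (e && l) "persistent" else if (e) "early"
    else if (l) "late" else "unresponsive"
  }, character(1))
  structure(list(labels = factor(lab, levels = c("early", "persistent",
                                                 "late", "unresponsive")),
                 count = colSums(enc), times = times,
                 early_window = early_window, late_window = late_window),
            class = "wavemem_classification")
}

#' @export
print.wavemem_classification <- function(x, ...) {
  print(table(x$labels))
  invisible(x)
}

#' Encoding-count curve and its U-shape statistics
#'
#' Number of encoding cells per recorded time point. For a decay-amplify
#' run the curve falls while the trailing front erodes the early cells,
#' reaches its minimum when the executive input lets the late cells join,
#' and rises afterwards. `u_shape_stats()` reports the drop from the start
#' to the minimum, the recovery from the minimum to the end, and the
#' location of the minimum (earliest index at ties).
#'
#' @param ensemble a `wavemem_ensemble`.
#' @param enc optional precomputed [encoding_matrix()].
#' @return data.frame with columns `t` and `count`.
#' @export
encoding_count_curve <- function(ensemble, enc = NULL) {
  if (is.null(enc)) enc <- encoding_matrix(ensemble)
  data.frame(t = attr(enc, "times"), count = colSums(enc))
}

#' @rdname encoding_count_curve
#' @param curve a data.frame from `encoding_count_curve()`.
#' @export
u_shape_stats <- function(curve) {
  i_min <- which.min(curve$count)   # earliest minimiser by convention
  list(t_min = curve$t[i_min], count_min = curve$count[i_min],
       drop = curve$count[1] - curve$count[i_min],
       recovery = curve$count[nrow(curve)] - curve$count[i_min])
}

#' Track a wavefront through the network
#'
#' Per-cell level-crossing times of the reference activity
#' `level * load_level(f1)`: the first up-crossing for the leading front,
#' the last down-crossing for the trailing front, linearly interpolated
#' between recorded steps (earliest step at ties). The front speed is the
#' least-squares slope of cell index versus crossing time (cells per time
#' unit) over the requested cell range; cells that never cross are recorded
#' as `NA` and excluded from the fit.
#'
#' @param result a `wavemem_sim`.
#' @param level crossing level as a fraction of the loaded activity,
#'   in (0, 1); default half-maximum.
#' @param side `"leading"` or `"trailing"`.
#' @param cells cell-index range used for the speed fit (default: all).
#' @return an object of class `wavemem_front`: data.frame with `cell` and
#'   `t_cross`, plus attributes `speed` and `fit_cells`.
#' @export
track_front <- function(result, level = 0.5,
                        side = c("leading", "trailing"), cells = NULL) {
  stopifnot(inherits(result, "wavemem_sim"))
  side <- match.arg(side)
  if (!(level > 0 && level < 1))
    stop("track_front: level must be in (0, 1)", call. = FALSE)
  ref <- level * result$x0
  act <- result$activity
  times <- result$times
  N <- nrow(act)
  cross <- rep(NA_real_, N)
  for (i in seq_len(N)) {
    above <- act[i, ] >= ref
    if (side == "leading") {
      k <- which(above)[1]
      if (!is.na(k)) {
        if (k == 1L) cross[i] <- times[1]
        else {
          f <- (ref - act[i, k - 1]) / (act[i, k] - act[i, k - 1])
          cross[i] <- times[k - 1] + f * (times[k] - times[k - 1])
        }
      }
    } else {
      k <- which(above)
      if (length(k) && k[length(k)] < length(times)) {
        k <- k[length(k)]
        f <- (act[i, k] - ref) / (act[i, k] - act[i, k + 1])
        cross[i] <- times[k] + f * (times[k + 1] - times[k])
      }
    }
  }
  df <- data.frame(cell = seq_len(N), t_cross = cross)
  if (is.null(cells)) cells <- seq_len(N)
  fit_df <- df[df$cell %in% cells & !is.na(df$t_cross), ]
  speed <- if (nrow(fit_df) >= 2)
    unname(stats::coef(stats::lm(cell ~ t_cross, data = fit_df))[2])
  else NA_real_
  structure(df, class = c("wavemem_front", "data.frame"),
            speed = speed, fit_cells = cells, side = side, level = level)
}

#' Front position over time
#'
#' Position of an activity front at each recorded time: for the trailing
#' front, the lowest cell index whose activity exceeds the reference level
#' (the rear edge of the pulse); for the leading front, the highest. Useful
#' for measuring whether a front keeps moving or freezes.
#'
#' @inheritParams track_front
#' @param t_window optional time window `c(from, to)` restricting the fit.
#' @return data.frame `t`, `position`, with attribute `speed` (cells per
#'   time unit, least squares; sign: positive = moving to higher indices).
#' @export
front_position <- function(result, level = 0.5,
                           side = c("trailing", "leading"),
                           t_window = NULL) {
  stopifnot(inherits(result, "wavemem_sim"))
  side <- match.arg(side)
  ref <- level * result$x0
  act <- result$activity
  pos <- vapply(seq_along(result$times), function(j) {
    alive <- which(act[, j] >= ref)
    if (!length(alive)) return(NA_real_)
    if (side == "trailing") min(alive) else max(alive)
  }, numeric(1))
  df <- data.frame(t = result$times, position = pos)
  fit_df <- df
  if (!is.null(t_window))
    fit_df <- df[df$t >= t_window[1] & df$t <= t_window[2], ]
  fit_df <- fit_df[!is.na(fit_df$position), ]
  speed <- if (nrow(fit_df) >= 2)
    unname(stats::coef(stats::lm(position ~ t, data = fit_df))[2])
  else NA_real_
  structure(df, class = c("data.frame"), speed = speed)
}

#' Comparison-phase decision
#'
#' During the comparison window the gain of the stimulated block has an
#' unstable fixed point (separatrix) at the activity level encoding the
#' second stimulus `f2`. If the end-of-delay activity sits above the
#' separatrix it grows, signalling `f1_higher`; below, it collapses,
#' signalling `f1_lower`. The decision reads the change of the readout-set
#' mean across the comparison window; changes below `1e-6` are
#' `"undecided"`.
#'
#' @param result a `wavemem_sim` simulated with `include_comparison = TRUE`.
#' @param readout `"last10"` (mean of the last 10 persistent cells) or
#'   `"cell"` (single cell, by default the last persistent cell).
#' @param cell readout cell index when `readout = "cell"`.
#' @return an object of class `wavemem_outcome`: list with `decision`,
#'   `readout_value` (end-of-delay readout mean) and `change`.
#' @export
readout_decision <- function(result, readout = c("last10", "cell"),
                             cell = NULL) {
  stopifnot(inherits(result, "wavemem_sim"))
  readout <- match.arg(readout)
  sch <- result$schedule
  if (max(result$times) < sch$T + sch$t_cmp_len - 1e-9)
    stop("readout_decision: result lacks the comparison window",
         call. = FALSE)
  cells <- .readout_cells(result$config, readout, cell)
  i_T <- which.min(abs(result$times - sch$T))
  i_end <- length(result$times)
  v_T <- mean(result$activity[cells, i_T])
  v_end <- mean(result$activity[cells, i_end])
  change <- v_end - v_T
  decision <- if (abs(change) < 1e-6) "undecided"
  else if (change > 0) "f1_higher" else "f1_lower"
  structure(list(decision = decision, readout_value = v_T, change = change),
            class = "wavemem_outcome")
}

.readout_cells <- function(config, readout = c("last10", "cell"),
                           cell = NULL) {
  readout <- match.arg(readout)
  if (readout == "last10")
    seq.int(max(1L, config$n_stim - 9L), config$n_stim)
  else if (is.null(cell)) config$n_stim else as.integer(cell)
}

#' Trial success
#'
#' A trial succeeds when the readout-set mean activity at the end of the
#' delay period lies inside the resolution band
#' `load_level(f1) * [1 - eps, 1 + eps]`. The default readout set is the
#' last 10 persistent cells of the chain.
#'
#' @param result a `wavemem_sim`.
#' @param eps resolution (band half-width, relative). `Inf` makes every
#'   trial succeed.
#' @param readout,cell as in [readout_decision()].
#' @return logical; attribute `"readout_value"` carries the measured mean.
#' @export
trial_success <- function(result, eps = 0.1, readout = c("last10", "cell"),
                          cell = NULL) {
  stopifnot(inherits(result, "wavemem_sim"))
  readout <- match.arg(readout)
  cells <- .readout_cells(result$config, readout, cell)
  i_T <- which.min(abs(result$times - result$schedule$T))
  v <- mean(result$activity[cells, i_T])
  x_tar <- result$x0
  ok <- if (is.infinite(eps)) TRUE
  else v >= x_tar * (1 - eps) && v <= x_tar * (1 + eps)
  structure(ok, readout_value = v)
}
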