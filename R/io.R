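#' Load and validate a run configuration file
#'
#' Configurations are JSON objects with up to five documented sections;
#' every key is optional and defaults to the package defaults, but unknown
#' sections or keys are rejected by name.
#'
#' * `chain`: `N`, `n_stim`, `g`, `c`, `sigma`, `dt`, `feedback_source`,
#'   `feedback_init` (see [chain_config()]).
#' * `kernel`: `N_x`, `kernel_sd`, `trunc_sd`, `gbar`, `c`, `sigma`, `dt`
#'   (see [kernel_config()]).
#' * `schedule`: `T`, `t_exec`, `t_cmp_len`, `f1`, `f2`
#'   (see [task_schedule()]).
#' * `map`: `f_min`, `f_max`, `x_lo`, `x_hi` (see [stimulus_map()]).
#' * `criterion`: `f1_grid`, `reps`, `k_sd` (see [encoding_criterion()]).
#' * `sweep`: `t_s_grid`, `sigma_grid`, `reps`, `base_seed`, `eps`
#'   (see [sweep_spec()]).
#'
#' @param path path to a JSON file, or `NULL` for all defaults.
#' @return list with validated components `chain`, `kernel`, `schedule`,
#'   `map`, `criterion`, `sweep`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list()
  else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- list(
    chain = c("N", "n_stim", "g", "c", "sigma", "dt", "tau",
              "feedback_source", "feedback_init"),
    kernel = c("N_x", "kernel_sd", "trunc_sd", "gbar", "c", "sigma", "dt"),
    schedule = c("T", "t_exec", "t_cmp_len", "f1", "f2"),
    map = c("f_min", "f_max", "x_lo", "x_hi"),
    criterion = c("f1_grid", "reps", "k_sd"),
    sweep = c("t_s_grid", "sigma_grid", "reps", "base_seed", "eps"))
  bad <- setdiff(names(raw), names(known))
  if (length(bad))
    stop(sprintf("load_config: unknown section(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), known[[sec]])
    if (length(bad))
      stop(sprintf("load_config: unknown key(s) in '%s': %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  sched <- do.call(task_schedule, raw$schedule %||% list())
  list(chain = do.call(chain_config, raw$chain %||% list()),
       kernel = do.call(kernel_config, raw$kernel %||% list()),
       schedule = sched,
       map = do.call(stimulus_map, raw$map %||% list()),
       criterion = do.call(encoding_criterion, raw$criterion %||% list()),
       sweep_args = raw$sweep %||% list())
}

#' Write a run configuration file
#'
#' Inverse of [load_config()]: serialises the validated components back to
#' JSON so that a written file loads to an identical configuration.
#'
#' @param config a list as returned by [load_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- list(chain = unclass(config$chain),
              kernel = unclass(config$kernel),
              schedule = unclass(config$schedule),
              map = unclass(config$map),
              criterion = unclass(config$criterion))
  if (length(config$sweep_args)) out$sweep <- config$sweep_args
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write an experiment report as CSV plus JSON metadata sidecar
#'
#' The tidy result table goes to `<path>` as CSV; the metadata (experiment
#' name, base seed, configuration snapshot, package version, wall time)
#' goes to `<path>` with extension replaced by `.meta.json`. Re-running an
#' experiment with the same specification reproduces the CSV byte for byte
#' (the sidecar differs only in wall time).
#'
#' @param report a `wavemem_report`.
#' @param path output CSV path.
#' @return invisible list with the two paths written.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "wavemem_report"))
  utils::write.csv(report$table, path, row.names = FALSE)
  meta_path <- sub("\\.[^.]*$", "", path)
  meta_path <- paste0(meta_path, ".meta.json")
  jsonlite::write_json(report$meta, meta_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(list(csv = path, meta = meta_path))
}

#' Write a trajectory in long format
#'
#' One row per (time, cell): columns `time`, `cell_index`, `population`
#' (`"main"` or `"late"`), `activity`. The configuration snapshot is written
#' as a JSON sidecar.
#'
#' @param result a `wavemem_sim`.
#' @param path output CSV path.
#' @return invisible list with the paths written.
#' @export
write_trajectory <- function(result, path) {
  stopifnot(inherits(result, "wavemem_sim"))
  long <- function(mat, pop)
    data.frame(time = rep(result$times, each = nrow(mat)),
               cell_index = rep(seq_len(nrow(mat)), length(result$times)),
               population = pop,
               activity = as.vector(mat))
  df <- long(result$activity, "main")
  if (!is.null(result$late)) df <- rbind(df, long(result$late, "late"))
  utils::write.csv(df, path, row.names = FALSE)
  meta_path <- paste0(sub("\\.[^.]*$", "", path), ".meta.json")
  jsonlite::write_json(list(seed = result$seed,
                            config = unclass(result$config),
                            schedule = unclass(result$schedule),
                            map = unclass(result$map), x0 = result$x0),
                       meta_path, auto_unbox = TRUE, digits = NA)
  invisible(list(csv = path, meta = meta_path))
}
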