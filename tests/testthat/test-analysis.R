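# a small, fast ensemble world shared by the encoding tests:
# 30-cell chain, 20 stimulated, delay 20, gate at 10
mini_world <- function(g = 1, c = 0, sigma = 0, T = 20, t_exec = 10) {
  list(config = tiny_chain(g = g, c = c, sigma = sigma),
       schedule = task_schedule(T = T, t_exec = t_exec))
}

test_that("noiseless line attractor: every stimulated cell encodes at every time", {
  w <- mini_world(t_exec = 0)   # gate open throughout: no quiescent block
  crit <- encoding_criterion(reps = 1)
  ens <- simulate_ensemble(w$config, w$schedule, crit, base_seed = 1,
                           record_every = 100L,
                           init = "uniform_all")
  enc <- encoding_matrix(ens)
  expect_true(all(enc))
  # and the encoding count is constant
  expect_equal(unique(encoding_count_curve(ens, enc = enc)$count),
               w$config$N)
})

test_that("late cells do not encode before the executive input", {
  w <- mini_world(sigma = 0.005)
  crit <- encoding_criterion(reps = 5)
  ens <- simulate_ensemble(w$config, w$schedule, crit, base_seed = 2,
                           record_every = 100L)
  enc <- encoding_matrix(ens)
  late <- (w$config$n_stim + 1):w$config$N
  pre <- attr(enc, "times") < w$schedule$t_exec
  expect_true(all(!enc[late, pre]))
  expect_false(is_encoding(ens, cell = 25, t = 5, enc = enc))
})

test_that("encoding is invariant to reps when sigma = 0", {
  w <- mini_world()
  e1 <- encoding_matrix(simulate_ensemble(w$config, w$schedule,
                                          encoding_criterion(reps = 1),
                                          base_seed = 3,
                                          record_every = 200L))
  e3 <- encoding_matrix(simulate_ensemble(w$config, w$schedule,
                                          encoding_criterion(reps = 3),
                                          base_seed = 4,
                                          record_every = 200L))
  expect_equal(e1, e3, ignore_attr = TRUE)
})

test_that("pure noise matches the permutation null of the criterion", {
  # x0 ~ 0 for every stimulus: trials are exchangeable across the f1
  # labels, so the encoding fraction must match the label-permutation null,
  # whose mean is bounded by P(5 exchangeable means strictly ordered) = 1/120
  w <- list(config = tiny_chain(sigma = 0.01),
            schedule = task_schedule(T = 10, t_exec = 5))
  crit <- encoding_criterion(reps = 5)
  map0 <- stimulus_map(x_lo = 0, x_hi = 1e-12)
  ens <- simulate_ensemble(w$config, w$schedule, crit, base_seed = 5,
                           map = map0, record_every = 200L)
  # drop t = 0: the deterministic initial condition has zero within-group
  # variance, so the (infinitesimally ordered) loaded levels trivially
  # "encode" there
  keep_t <- ens$times > 0
  observed <- mean(encoding_matrix(ens)[, keep_t])
  # permutation oracle: shuffle trials across f1 labels, re-apply criterion
  arr <- ens$activity[, , , keep_t, drop = FALSE]
  d <- dim(arr)
  flat <- array(aperm(arr, c(2, 1, 3, 4)), c(d[1] * d[2], d[3], d[4]))
  set.seed(99)
  null_frac <- vapply(1:200, function(i) {
    idx <- sample(d[1] * d[2])
    shuf <- array(flat[idx, , ], c(d[2], d[1], d[3], d[4]))
    mean(wavemem:::.encode(aperm(shuf, c(2, 1, 3, 4)), crit$k_sd))
  }, numeric(1))
  # observed fraction consistent with the null distribution
  expect_lte(observed, max(null_frac))
  # and the null false-positive rate is at most 1/120 (3 MC SEs of slack)
  se <- stats::sd(null_frac) / sqrt(length(null_frac))
  expect_lt(mean(null_frac), 1 / 120 + 3 * max(se, 1e-4))
})

test_that("leading and trailing fronts share speed in the plain pulse", {
  # no gating, no feedback, g = 1: a pulse travelling ~1 cell per time unit
  cfg <- chain_config(N = 80, n_stim = 30, g = 1, c = 0, sigma = 0)
  sch <- task_schedule(T = 40, t_exec = 0)
  sim <- simulate_chain(cfg, sch, record_every = 10L)
  lead <- track_front(sim, side = "leading", cells = 35:65)
  trail <- track_front(sim, side = "trailing", cells = 5:30)
  expect_equal(attr(lead, "speed"), attr(trail, "speed"), tolerance = 0.1)
  expect_equal(attr(lead, "speed"), 1, tolerance = 0.2)
})

test_that("feedback freezes the trailing front after the executive input", {
  # with the gate at t = 40 the feedback prop (summed noise plus c*z,
  # accumulating one chain stage per time constant) catches the trailing
  # front within ~20 time units and pins it for the rest of the delay
  w <- raster_world(t_exec = 40)
  sim <- simulate_chain(w$config, w$schedule, seed = 8, record_every = 100L)
  fp <- front_position(sim, side = "trailing", t_window = c(70, 150))
  expect_lt(abs(attr(fp, "speed")), 0.2)
  # control: before the input the trailing front recedes at ~1 cell/tau
  fp0 <- front_position(sim, side = "trailing", t_window = c(5, 38))
  expect_gt(attr(fp0, "speed"), 0.6)
})

test_that("readout decision follows the separatrix; exact tie is undecided", {
  w <- world6(d = 0.05, sigma = 0, t_exec = timing_interval(
    rate_params(d = 0.05, a = 0.05, eps = 0.1, T = 6))$center)
  sch <- w$schedule
  sch$f2 <- 14   # f2 well below f1 = 22: end-of-delay activity above separatrix
  sim <- simulate_chain(w$config, sch, record_every = 10L,
                        include_comparison = TRUE)
  expect_equal(readout_decision(sim)$decision, "f1_higher")
  sch$f2 <- 30
  sim <- simulate_chain(w$config, sch, record_every = 10L,
                        include_comparison = TRUE)
  expect_equal(readout_decision(sim)$decision, "f1_lower")
  # activity pinned exactly on the separatrix: undecided
  cfg0 <- chain_config(N = 150, n_stim = 100, g = 1, c = 0, sigma = 0)
  sch0 <- task_schedule(T = 2, t_exec = Inf, f1 = 22, f2 = 22)
  sim0 <- simulate_chain(cfg0, sch0, record_every = 10L,
                         include_comparison = TRUE)
  expect_equal(readout_decision(sim0)$decision, "undecided")
  # missing comparison window is an input error
  sim1 <- simulate_chain(cfg0, sch0, record_every = 10L)
  expect_error(readout_decision(sim1), "comparison")
})

test_that("trial success bands behave as the envelope predicts", {
  iv <- timing_interval(rate_params(d = 0.05, a = 0.05, eps = 0.1, T = 6))
  w_in <- world6(d = 0.05, sigma = 0, t_exec = iv$center)
  expect_true(as.logical(trial_success(
    simulate_chain(w_in$config, w_in$schedule, record_every = 600L))))
  w_out <- world6(d = 0.05, sigma = 0, t_exec = min(6, iv$hi + 0.6))
  sim_out <- simulate_chain(w_out$config, w_out$schedule,
                            record_every = 600L)
  expect_false(as.logical(trial_success(sim_out)))
  expect_true(as.logical(trial_success(sim_out, eps = Inf)))
})

test_that("classification windows are validated", {
  w <- mini_world()
  ens <- simulate_ensemble(w$config, w$schedule, encoding_criterion(reps = 1),
                           base_seed = 1, record_every = 200L)
  expect_error(classify_cells(ens, early_window = 0), "windows")
  expect_error(classify_cells(ens, early_window = 0.7, late_window = 0.7),
               "windows")
})
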