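# shared fixtures: all built in code, sized for fast tests

# short-delay quantitative world (timing theory holds to high accuracy)
world6 <- function(d = 0.05, sigma = 0, t_exec = 3) {
  sweep_world(d = d, sigma = sigma, T = 6, t_exec = t_exec)
}

# miniature chain for ensemble-heavy tests
tiny_chain <- function(g = 1, c = 0, sigma = 0, N = 30, n_stim = 20) {
  chain_config(N = N, n_stim = n_stim, g = g, c = c, sigma = sigma)
}

# endpoint of the readout mean (last 10 persistent cells)
readout_end <- function(sim) {
  cells <- seq.int(sim$config$n_stim - 9L, sim$config$n_stim)
  mean(sim$activity[cells, ncol(sim$activity)])
}

# restrict a sweep report to part of its t_s grid
.subset_report <- function(report, t_s) {
  report$table <- report$table[report$table$t_s %in% t_s, ]
  report
}

# bisection root of f on [lo, hi] (f(lo), f(hi) of opposite sign)
bisect <- function(f, lo, hi, tol = 1e-12) {
  flo <- f(lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) break
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}
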