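# Small simulation helpers shared across test files.

# Repeated-measures data with individual effects and an optional condition
# shift on the first `n_shift` variables: the canonical crossed design for
# pDFA checks (n_ind individuals x 2 conditions x n_call calls x p vars).
make_crossed_data <- function(seed, n_ind = 8, n_call = 20, p = 4,
                              shift = 0, n_shift = 2, ind_sd = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_ind), function(i) {
    u <- rnorm(p, sd = ind_sd)
    do.call(rbind, lapply(c("A", "B"), function(cond) {
      x <- sweep(matrix(rnorm(n_call * p), n_call, p), 2, u, "+")
      if (cond == "B" && shift != 0) {
        x[, seq_len(n_shift)] <- x[, seq_len(n_shift)] + shift
      }
      d <- data.frame(caller = sprintf("ind%02d", i), condition = cond, x)
      names(d)[-(1:2)] <- paste0("V", seq_len(p))
      d
    }))
  }))
}

# Mixed-model data: ln-distance-like outcome with a per-individual random
# intercept and linear week effects per sex.
make_lme_data <- function(seed, n_ind = 4, weeks = c(0, 0.5, 1:16),
                          n_call = 10, slope_f = -0.05, slope_m = slope_f,
                          intercept = 0, ind_sd = 0.2, resid_sd = 0.3) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_ind), function(i) {
    sex <- if (i %% 2 == 0) "M" else "F"
    slope <- if (sex == "M") slope_m else slope_f
    u <- rnorm(1, sd = ind_sd)
    do.call(rbind, lapply(weeks, function(w) {
      data.frame(caller = sprintf("ind%02d", i), sex = sex,
                 call_type = "trill", week = w,
                 condition = ifelse(w == 0, "Before",
                                    ifelse(w == 0.5, "NewPhys", "NewSoc")),
                 ln_distance = intercept + u + slope * w +
                   rnorm(n_call, sd = resid_sd))
    }))
  }))
}

# A tiny quiet scenario for pipeline tests: fewer weeks, fewer calls.
small_scenario <- function(...) {
  sched <- data.frame(
    condition = c("Before", "NewPhys", "NewPhys", rep("NewSoc", 6)),
    week = c(0, 0.5, 0.5, c(1, 2, 3, 5, 6, 8)),
    trill = 6, phee = 6, food = 6
  )
  default_scenario(schedule = sched, ...)
}
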