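# Round-robin assignment of parameters to latent noise factors: parameter
# j belongs to factor ((j - 1) %/% block) + 1 with contiguous blocks.
noise_factor_assignment <- function(p, n_factors) {
  rep(seq_len(n_factors), each = ceiling(p / n_factors))[seq_len(p)]
}

#' Dialect offset aligned with the generator's noise-factor blocks
#'
#' Builds an offset vector of magnitude `magnitude` on the first
#' `n_per_factor` parameters of the first latent noise factor and
#' `-magnitude` on the first `n_per_factor` parameters of the second, so
#' the colony difference lies inside the correlated subspace a principal
#' component analysis retains (a dialect shift confined to directions the
#' PCA discards would be invisible downstream, which real dialect
#' differences are not).
#'
#' @param p parameter count (17 trill, 15 otherwise).
#' @param magnitude offset size in within-call SD units.
#' @param n_per_factor parameters shifted per factor.
#' @param n_factors latent factors assumed (must match the scenario's).
#' @return Numeric offset vector of length `p`.
#' @export
factor_aligned_offset <- function(p, magnitude, n_per_factor = 3,
                                  n_factors = 4) {
  fa <- noise_factor_assignment(p, n_factors)
  v <- numeric(p)
  v[which(fa == 1)[seq_len(n_per_factor)]] <- magnitude
  v[which(fa == 2)[seq_len(n_per_factor)]] <- -magnitude
  v
}

# Convergence shape: offsets decay exponentially with weeks of social
# exposure. Weeks 0 (natal colony) and 0.5 (quarantine: new environment but
# no novel vocal input) carry no exposure, so g() = 1 there; the decay
# starts with the first week in the new colony.
convergence_factor <- function(week, rate) {
  exposure <- ifelse(week >= 1, week, 0)
  exp(-rate * exposure)
}

#' Simulate a per-call acoustic feature table with known ground truth
#'
#' Draws one row per call under the scenario's generative model. For a call
#' of type `ct` by individual `i` of colony `c` in week `w`:
#' \deqn{x = \delta_{c,ct}\, g(w; r_{ct,sex}) + \pi_{ct}\,1[w \in W_p] +
#'       u_{i,ct} + \epsilon}
#' where \eqn{\delta} is the dialect offset of the translocated colony
#' (zero for the target colony), \eqn{g(w; r) = e^{-r\,w}} for exposure
#' weeks and 1 before any social exposure, \eqn{\pi} is the transient
#' perturbation active only in `perturbation_weeks`, \eqn{u_{i,ct} \sim
#' N(0, \sigma_{ind}^2 I)} is a per-individual offset drawn once, and
#' \eqn{\epsilon} is within-individual call noise with per-parameter SD
#' `call_sd` drawn from a latent factor model (`n_noise_factors` shared
#' factors carrying `noise_factor_share` of the variance) so parameters
#' are correlated the way real acoustic measures are.
#' Parameter columns are named `para_01`, `para_02`, ...; call types
#' with 15 parameters leave `para_16`/`para_17` as `NA`.
#'
#' @param cfg a [scenario_config()].
#' @param seed integer seed; defaults to the scenario's own seed. Identical
#'   `(cfg, seed)` pairs yield byte-identical tables.
#' @return A list with `features` (data frame: `caller`, `colony`, `sex`,
#'   `call_type`, `condition`, `week`, then parameter columns) and `truth`
#'   (a `simulation_truth`: per-individual offsets, the translocated
#'   group's expected offset trajectory per call type, the rates and seed).
#' @export
simulate_features <- function(cfg, seed = cfg$seed) {
  validate_scenario(cfg)
  sched <- cfg$schedule
  for (ct in cfg$call_types) {
    if (any(sched[[ct]] <= 0)) {
      stop("schedule call targets must be positive", call. = FALSE)
    }
  }
  max_p <- max(cfg$n_params_per_type)
  translocated <- cfg$colonies[1]
  has_target <- length(cfg$colonies) > 1

  with_seed(seed, {
    # per-individual random offsets, one vector per (caller, call type)
    ind_offsets <- list()
    for (caller in cfg$callers) {
      ind_offsets[[caller]] <- lapply(
        stats::setNames(nm = cfg$call_types),
        function(ct) stats::rnorm(cfg$n_params_per_type[[ct]],
                                  sd = cfg$individual_sd))
    }

    rows <- list()
    k <- 1L
    for (caller in cfg$callers) {
      colony <- cfg$colony_of[[caller]]
      sex <- cfg$sexes[[caller]]
      for (b in seq_len(nrow(sched))) {
        week <- sched$week[b]
        cond <- sched$condition[b]
        for (ct in cfg$call_types) {
          n_calls <- sched[[ct]][b]
          p <- cfg$n_params_per_type[[ct]]
          mu <- ind_offsets[[caller]][[ct]]
          if (colony == translocated && has_target) {
            rate <- cfg$convergence_rate[[ct]][[sex]]
            mu <- mu + cfg$dialect_offset[[ct]] * convergence_factor(week, rate)
          }
          if (week %in% cfg$perturbation_weeks) {
            mu <- mu + cfg$perturbation[[ct]]
          }
          # within-call noise: shared latent factors + unique residual,
          # total per-parameter SD = call_sd
          fa <- noise_factor_assignment(p, cfg$n_noise_factors)
          load_sd <- cfg$call_sd * sqrt(cfg$noise_factor_share)
          uniq_sd <- cfg$call_sd * sqrt(1 - cfg$noise_factor_share)
          f <- matrix(stats::rnorm(n_calls * cfg$n_noise_factors),
                      n_calls, cfg$n_noise_factors)
          x <- f[, fa, drop = FALSE] * load_sd +
            matrix(stats::rnorm(n_calls * p, sd = uniq_sd), n_calls, p)
          x <- sweep(x, 2, mu, "+")
          if (p < max_p) {
            x <- cbind(x, matrix(NA_real_, n_calls, max_p - p))
          }
          colnames(x) <- sprintf("para_%02d", seq_len(max_p))
          rows[[k]] <- data.frame(
            caller = caller, colony = colony, sex = sex, call_type = ct,
            condition = cond, week = week, x,
            stringsAsFactors = FALSE, row.names = NULL
          )
          k <- k + 1L
        }
      }
    }
    features <- do.call(rbind, rows)
    rownames(features) <- NULL

    trajectories <- lapply(stats::setNames(nm = cfg$call_types), function(ct) {
      weeks <- sort(unique(sched$week))
      do.call(rbind, lapply(c("F", "M"), function(sx) {
        g <- convergence_factor(weeks, cfg$convergence_rate[[ct]][[sx]])
        data.frame(sex = sx, week = weeks, g = g,
                   offset_norm = sqrt(sum(cfg$dialect_offset[[ct]]^2)) * g)
      }))
    })

    truth <- structure(list(
      individual_offsets = ind_offsets,
      trajectories = trajectories,
      convergence_rate = cfg$convergence_rate,
      dialect_offset = cfg$dialect_offset,
      seed = as.integer(seed)
    ), class = "simulation_truth")

    list(features = features, truth = truth)
  })
}

#' Write or read a feature table as CSV
#'
#' One row per call: metadata columns (`caller`, `colony`, `sex`,
#' `call_type`, `condition`, `week`) followed by the parameter columns.
#'
#' @param features feature data frame.
#' @param path file path.
#' @return `read_feature_csv()` returns the data frame.
#' @export
write_feature_csv <- function(features, path) {
  stopifnot_cols(features, c("caller", "call_type", "week"), "feature table")
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
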