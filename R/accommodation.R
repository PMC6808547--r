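#' Mixed-effects model of vocal accommodation over exposure time
#'
#' Fits, by maximum likelihood, the linear mixed model
#' `ln_distance ~ sex + week + sex:week + (1 | caller)`
#' with females as the reference sex. When the sex-by-week interaction is
#' not significant (t-based p >= `alpha`, Satterthwaite degrees of
#' freedom), the model is refitted without it and the reduced model is
#' reported (`interaction_kept = FALSE`), matching the convention of
#' interpreting only the highest-order term in which a predictor occurs.
#' The fit carries a likelihood-ratio test against the null model of
#' intercept plus random effects only, and marginal / conditional
#' R-squared.
#'
#' @param records a `distance_records` data frame (one call type).
#' @param drop_ns_interaction drop a non-significant interaction?
#' @param alpha significance level for the interaction decision.
#' @return An `accommodation_lme` with `coefficients` (B, SE, df, t, P),
#'   variance components, `R2_marginal`, `R2_conditional`, `lrt`
#'   (chi-square, df, p), `n_obs`, `n_individuals`, `interaction_kept`,
#'   and the underlying `lmerTest` fit.
#' @export
fit_accommodation <- function(records, drop_ns_interaction = TRUE,
                              alpha = 0.05) {
  stopifnot_cols(records, c("ln_distance", "sex", "week", "caller"),
                 "records")
  if (length(unique(records$caller)) < 2L) {
    stop("need >= 2 individuals", call. = FALSE)
  }
  if (length(unique(records$week)) < 2L) {
    stop("need >= 2 distinct weeks", call. = FALSE)
  }
  dat <- records
  dat$sex <- stats::relevel(factor(dat$sex), ref = "F")
  dat$caller <- factor(dat$caller)

  two_sexes <- nlevels(dat$sex) > 1L
  full_formula <- if (two_sexes) {
    ln_distance ~ sex + week + sex:week + (1 | caller)
  } else {
    ln_distance ~ week + (1 | caller)
  }
  fit <- suppressMessages(
    lmerTest::lmer(full_formula, data = dat, REML = FALSE))
  coefs <- summary(fit)$coefficients
  interaction_kept <- FALSE
  if (two_sexes) {
    int_row <- grep(":", rownames(coefs))
    int_p <- coefs[int_row, "Pr(>|t|)"]
    if (drop_ns_interaction && int_p >= alpha) {
      fit <- suppressMessages(
        lmerTest::lmer(ln_distance ~ sex + week + (1 | caller),
                       data = dat, REML = FALSE))
      coefs <- summary(fit)$coefficients
    } else {
      interaction_kept <- TRUE
    }
  }

  vc <- as.data.frame(lme4::VarCorr(fit))
  var_random <- vc$vcov[vc$grp == "caller"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  singular <- lme4::isSingular(fit)
  if (singular) {
    message("random-intercept variance at the zero boundary (singular fit)")
  }
  r2 <- nakagawa_r2_components(fit)
  coef_table <- data.frame(term = rownames(coefs),
                           B = coefs[, "Estimate"],
                           SE = coefs[, "Std. Error"],
                           df = coefs[, "df"],
                           t = coefs[, "t value"],
                           P = coefs[, "Pr(>|t|)"],
                           row.names = NULL)

  out <- structure(list(
    call_type = if (!is.null(records$call_type)) records$call_type[1]
                else NA_character_,
    fit = fit,
    coefficients = coef_table,
    var_random = var_random,
    var_resid = var_resid,
    singular = singular,
    logLik = as.numeric(stats::logLik(fit)),
    R2_marginal = r2[["R2_marginal"]],
    R2_conditional = r2[["R2_conditional"]],
    n_obs = nrow(dat),
    n_individuals = nlevels(dat$caller),
    interaction_kept = interaction_kept
  ), class = "accommodation_lme")
  out$lrt <- lrt_vs_null(out, dat)
  out
}

#' Likelihood-ratio test against the intercept + random-effects null
#'
#' Refits the null model `ln_distance ~ 1 + (1 | caller)` by maximum
#' likelihood on the same rows and returns the chi-square statistic
#' `2 (LL_full - LL_null)`, its degrees of freedom (difference in fixed
#' -effect counts) and p-value.
#'
#' @param model an `accommodation_lme` (or an ML `lmerMod`).
#' @param records the data the model was fitted on.
#' @return List with `chisq`, `df`, `p`.
#' @export
lrt_vs_null <- function(model, records) {
  fit <- if (inherits(model, "accommodation_lme")) model$fit else model
  if (nrow(stats::model.frame(fit)) != nrow(records)) {
    stop("records do not match the fitted model's rows", call. = FALSE)
  }
  null_fit <- suppressMessages(
    lme4::lmer(ln_distance ~ 1 + (1 | caller), data = records, REML = FALSE))
  chisq <- max(0, 2 * (as.numeric(stats::logLik(fit)) -
                         as.numeric(stats::logLik(null_fit))))
  df <- length(lme4::fixef(fit)) - 1L
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

nakagawa_r2_components <- function(fit) {
  # variance of the fixed-effect linear predictor over the data
  var_fixed <- stats::var(as.vector(
    stats::model.matrix(fit) %*% lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_random <- sum(vc$vcov[vc$grp != "Residual"])
  var_resid <- vc$vcov[vc$grp == "Residual"]
  total <- var_fixed + var_random + var_resid
  if (total <= 0) stop("zero total variance; R2 undefined", call. = FALSE)
  c(R2_marginal = var_fixed / total,
    R2_conditional = (var_fixed + var_random) / total)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-decomposition R-squared for a Gaussian mixed model: marginal
#' R2 is the fixed-effect variance over the sum of fixed, random and
#' residual variances; conditional R2 adds the random-effect variance to
#' the numerator. The fixed-effect variance is the variance of the fixed
#' -effect linear predictor over the data.
#'
#' @param model an `accommodation_lme` or `lmerMod`.
#' @return Named vector `R2_marginal`, `R2_conditional`.
#' @export
nakagawa_r2 <- function(model) {
  fit <- if (inherits(model, "accommodation_lme")) model$fit else model
  nakagawa_r2_components(fit)
}

#' Pre- vs post-translocation comparison of vocal distance
#'
#' Ordinary linear model `ln_distance ~ condition * sex` contrasting the
#' recordings immediately before the translocation into the new colony
#' (quarantine, condition "NewPhys") with recordings made 5+ weeks after,
#' when transient environmental effects have decayed. When the
#' condition-by-sex interaction is not significant the additive model is
#' reported. The headline `condition_effect` is the post-minus-pre
#' contrast averaged over the sexes (negative = calls moved closer to the
#' population).
#'
#' @param records `distance_records` for one call type.
#' @param pre_condition condition label of the pre window.
#' @param post_condition,post_min_week condition label and minimum week of
#'   the post window.
#' @param alpha significance level for the interaction decision.
#' @return A `prepost_lm` list: `coefficients`, `condition_effect`,
#'   `condition_p`, `interaction_kept`, window sizes and the `lm` fit.
#' @export
compare_prepost <- function(records, pre_condition = "NewPhys",
                            post_condition = "NewSoc", post_min_week = 5,
                            alpha = 0.05) {
  stopifnot_cols(records, c("ln_distance", "sex", "week", "condition"),
                 "records")
  pre <- records[records$condition == pre_condition, , drop = FALSE]
  post <- records[records$condition == post_condition &
                    records$week >= post_min_week, , drop = FALSE]
  if (!nrow(pre) || !nrow(post)) {
    stop("empty pre or post window", call. = FALSE)
  }
  dat <- rbind(pre, post)
  dat$period <- factor(ifelse(dat$condition == pre_condition, "pre", "post"),
                       levels = c("pre", "post"))
  dat$sex <- stats::relevel(factor(dat$sex), ref = "F")
  two_sexes <- nlevels(dat$sex) > 1L

  fit <- if (two_sexes) stats::lm(ln_distance ~ period * sex, data = dat)
         else stats::lm(ln_distance ~ period, data = dat)
  cf <- summary(fit)$coefficients
  interaction_kept <- FALSE
  if (two_sexes) {
    int_p <- cf["periodpost:sexM", "Pr(>|t|)"]
    if (int_p >= alpha) {
      fit <- stats::lm(ln_distance ~ period + sex, data = dat)
      cf <- summary(fit)$coefficients
    } else {
      interaction_kept <- TRUE
    }
  }
  est <- stats::coef(fit)
  effect <- est[["periodpost"]] +
    if (interaction_kept) 0.5 * est[["periodpost:sexM"]] else 0
  structure(list(
    call_type = if (!is.null(records$call_type)) records$call_type[1]
                else NA_character_,
    coefficients = cf,
    condition_effect = unname(effect),
    condition_p = cf["periodpost", "Pr(>|t|)"],
    interaction_kept = interaction_kept,
    n_pre = nrow(pre), n_post = nrow(post),
    fit = fit
  ), class = "prepost_lm")
}

#' @export
print.prepost_lm <- function(x, ...) {
  cat(sprintf("Pre/post comparison%s: %d pre, %d post calls\n",
              if (is.na(x$call_type)) "" else paste0(" [", x$call_type, "]"),
              x$n_pre, x$n_post))
  cat(sprintf("  condition effect (post - pre, sexes averaged): %.4f\n",
              x$condition_effect))
  cat(sprintf("  condition p = %.4g %s; interaction %s\n", x$condition_p,
              sig_marker(x$condition_p),
              if (x$interaction_kept) "kept" else "dropped"))
  invisible(x)
}

#' Weekly mean vocal distance with bootstrapped confidence intervals
#'
#' Per (caller, call type, week) cell with at least `min_calls` calls:
#' the mean ln vocal distance and a percentile bootstrap 95% confidence
#' interval over calls; the plot-ready summary behind weekly accommodation
#' trajectories.
#'
#' @param records `distance_records`.
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed RNG seed.
#' @param min_calls minimum calls per cell (cells below are excluded,
#'   consistent with [weekly_inclusion_filter()]).
#' @param conf confidence level.
#' @return Data frame: `caller`, `call_type`, `week`, `n_calls`,
#'   `mean_ln_distance`, `ci_lower`, `ci_upper`.
#' @export
weekly_bootstrap_summary <- function(records, n_boot = 2000, seed = 1L,
                                     min_calls = 5, conf = 0.95) {
  stopifnot_cols(records, c("caller", "call_type", "week", "ln_distance"),
                 "records")
  alpha <- (1 - conf) / 2
  groups <- split(records,
                  interaction(records$caller, records$call_type,
                              records$week, drop = TRUE))
  with_seed(seed, {
    rows <- lapply(groups, function(g) {
      n <- nrow(g)
      if (n < min_calls) return(NULL)
      v <- g$ln_distance
      boots <- vapply(seq_len(n_boot),
                      function(b) mean(v[sample.int(n, n, replace = TRUE)]),
                      numeric(1))
      ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
      data.frame(caller = g$caller[1], call_type = g$call_type[1],
                 week = g$week[1], n_calls = n,
                 mean_ln_distance = mean(v),
                 ci_lower = ci[1], ci_upper = ci[2])
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) return(NULL)   # no cell met the inclusion threshold
    out <- out[order(out$call_type, out$caller, out$week), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' @export
print.accommodation_lme <- function(x, ...) {
  cat(sprintf("Accommodation LME%s (ML): ln vocal distance ~ %s\n",
              if (is.na(x$call_type)) "" else paste0(" [", x$call_type, "]"),
              if (x$interaction_kept) "sex * week" else "sex + week"))
  ct <- x$coefficients
  for (i in seq_len(nrow(ct))) {
    cat(sprintf("  %-14s B = %8.4f  SE = %.4f  t = %7.3f  P = %.4g %s\n",
                ct$term[i], ct$B[i], ct$SE[i], ct$t[i], ct$P[i],
                sig_marker(ct$P[i])))
  }
  cat(sprintf("  N = %d calls from %d individuals%s\n", x$n_obs,
              x$n_individuals, if (x$singular) " [singular fit]" else ""))
  cat(sprintf("  R2m = %.3f, R2c = %.3f; LRT chi2(%d) = %.3f, p = %.4g\n",
              x$R2_marginal, x$R2_conditional, x$lrt$df, x$lrt$chisq,
              x$lrt$p))
  invisible(x)
}

#' @export
summary.accommodation_lme <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.accommodation_lme <- function(object, ...) {
  stats::setNames(object$coefficients$B, object$coefficients$term)
}

#' @export
predict.accommodation_lme <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::predict(object$fit, ...)
  else stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.accommodation_lme <- function(object, ...) {
  stats::residuals(object$fit, ...)
}
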