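# Per-call-type parameter matrix: keeps only this call type's rows and its
# own parameter columns (15-parameter types carry NA in para_16/para_17).
calltype_matrix <- function(features, ct) {
  rows <- features$call_type == ct
  x <- as.matrix(features[rows, param_cols(features), drop = FALSE])
  x <- x[, colSums(is.na(x)) == 0, drop = FALSE]
  list(x = x, meta = features[rows, setdiff(names(features),
                                            param_cols(features)),
                              drop = FALSE])
}

#' Run the environmental-accommodation analysis (experiment 1)
#'
#' Per call type: z-transform + PCA with parallel-analysis retention on
#' all calls, projection, then one crossed pDFA per condition comparison
#' (by default "Before" vs "After1" and "Before" vs "After2") with caller
#' identity as the control factor. Returns a report table shaped like the
#' study's short/long-term accommodation tables: call type, number of
#' animals, number of calls, % expected correct, % actual correct and the
#' permutation p-value per comparison.
#'
#' @param features feature table (e.g. from [simulate_features()] with an
#'   [experiment1_scenario()], or a measured-call CSV).
#' @param comparisons list of length-2 character vectors of condition
#'   labels to compare.
#' @param n_permutations,n_selection_rounds pDFA settings.
#' @param pa_iter parallel-analysis iterations (default 10000).
#' @param seed RNG seed for thresholds and permutations.
#' @param out_dir optional directory; when given, the report, scores and a
#'   reproducibility manifest are written there.
#' @return An `experiment1_report`: `table` (report rows), `pdfa` (the
#'   fitted `pdfa` objects), `pca` (per call type).
#' @export
run_experiment1 <- function(features,
                            comparisons = list(c("Before", "After1"),
                                               c("Before", "After2")),
                            n_permutations = 1000,
                            n_selection_rounds = 100,
                            pa_iter = 10000,
                            seed = 1L,
                            out_dir = NULL) {
  stopifnot_cols(features, c("caller", "call_type", "condition"),
                 "feature table")
  present <- unique(features$condition)
  for (cmp in comparisons) {
    if (!all(cmp %in% present)) {
      stop(sprintf("condition(s) %s not in data; available: %s",
                   paste(setdiff(cmp, present), collapse = ", "),
                   paste(present, collapse = ", ")), call. = FALSE)
    }
  }
  call_types <- unique(features$call_type)
  seeds <- derive_seeds(seed, length(call_types) * (1 + length(comparisons)))
  si <- 0L
  rows <- list(); pdfas <- list(); pcas <- list()
  for (ct in call_types) {
    ctm <- calltype_matrix(features, ct)
    si <- si + 1L
    pca <- retained_pca(ctm$x, n_iter = pa_iter, seed = seeds[si],
                        call_type = ct)
    pcas[[ct]] <- pca
    scores <- as.data.frame(predict(pca, ctm$x))
    vars <- colnames(scores)
    scores <- cbind(ctm$meta, scores)
    for (cmp in comparisons) {
      si <- si + 1L
      sub <- scores[scores$condition %in% cmp, , drop = FALSE]
      res <- crossed_pdfa(sub, pdfa_design(
        variables = vars, n_permutations = n_permutations,
        n_selection_rounds = n_selection_rounds, seed = seeds[si]))
      key <- paste(ct, paste(cmp, collapse = "-"), sep = ":")
      pdfas[[key]] <- res
      rows[[key]] <- data.frame(
        call_type = ct, comparison = paste(cmp, collapse = " vs "),
        n_animals = res$n_individuals, n_calls = res$n_calls,
        pct_expected_correct = res$pct_expected_correct,
        pct_actual_correct = res$pct_actual_correct,
        p_value = res$p_value,
        flag = sig_marker(res$p_value))
    }
  }
  report <- structure(list(table = do.call(rbind, c(rows,
                                                    make.row.names = FALSE)),
                           pdfa = pdfas, pca = pcas, seed = as.integer(seed)),
                      class = "experiment1_report")
  if (!is.null(out_dir)) {
    write_report_outputs(report, out_dir, features,
                         list(comparisons = comparisons,
                              n_permutations = n_permutations,
                              n_selection_rounds = n_selection_rounds,
                              pa_iter = pa_iter, seed = seed))
  }
  report
}

#' @export
print.experiment1_report <- function(x, ...) {
  cat("Environmental accommodation: crossed pDFA per call type\n")
  tab <- x$table
  tab$pct_expected_correct <- sprintf("%.2f", tab$pct_expected_correct)
  tab$pct_actual_correct <- sprintf("%.2f", tab$pct_actual_correct)
  tab$p_value <- sprintf("%.4g", tab$p_value)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Run the social-accommodation analysis (experiment 2)
#'
#' Per call type, on calls passing the weekly inclusion filter: a pooled
#' PCA (translocated + baseline calls) with parallel-analysis retention;
#' projection of all calls; a frozen population centroid from the baseline
#' individuals' 10% trimmed means; per-call variance-weighted vocal
#' distances for the translocated animals; the accommodation mixed model
#' over exposure weeks with its likelihood-ratio test and R-squared; the
#' pre- vs 5+-weeks linear model; and the weekly bootstrap summary behind
#' trajectory plots.
#'
#' @param features feature table containing both colonies.
#' @param translocated,baseline colony labels of the focal and reference
#'   population (defaults "MA" and "ZH").
#' @param min_calls weekly inclusion threshold (default 5).
#' @param pa_iter parallel-analysis iterations (default 10000).
#' @param pa_thresholds optional named list (by call type) of precomputed
#'   [parallel_analysis_thresholds()], e.g. when running many replicates
#'   of the same design.
#' @param n_boot bootstrap resamples for weekly summaries.
#' @param seed RNG seed.
#' @param out_dir optional output directory (report CSVs + manifest).
#' @return An `experiment2_report`: per call type the `retained_pca`,
#'   `population_centroid`, `distance_records`, `accommodation_lme`,
#'   `prepost_lm` and weekly summary, plus a coefficient table across call
#'   types.
#' @export
run_experiment2 <- function(features, translocated = "MA", baseline = "ZH",
                            min_calls = 5, pa_iter = 10000,
                            pa_thresholds = NULL, n_boot = 2000,
                            seed = 1L, out_dir = NULL) {
  stopifnot_cols(features, c("caller", "colony", "sex", "call_type",
                             "condition", "week"), "feature table")
  if (length(unique(features$caller[features$colony == baseline])) < 2L) {
    stop("need >= 2 baseline individuals", call. = FALSE)
  }
  features <- weekly_inclusion_filter(features, min_calls = min_calls)
  call_types <- unique(features$call_type)
  seeds <- derive_seeds(seed, 2L * length(call_types))
  per_type <- list(); rows <- list()
  for (i in seq_along(call_types)) {
    ct <- call_types[i]
    ctm <- calltype_matrix(features, ct)
    pca <- retained_pca(ctm$x, thresholds = pa_thresholds[[ct]],
                        n_iter = pa_iter, seed = seeds[2 * i - 1L],
                        call_type = ct)
    scores <- predict(pca, ctm$x)
    is_base <- ctm$meta$colony == baseline
    centroid <- population_centroid(scores[is_base, , drop = FALSE],
                                    ctm$meta$caller[is_base],
                                    call_type = ct)
    records <- build_distance_records(scores[!is_base, , drop = FALSE],
                                      ctm$meta[!is_base, , drop = FALSE],
                                      centroid, pca)
    model <- fit_accommodation(records)
    prepost <- tryCatch(compare_prepost(records),
                        error = function(e) NULL)
    weekly <- weekly_bootstrap_summary(records, n_boot = n_boot,
                                       seed = seeds[2 * i],
                                       min_calls = min_calls)
    per_type[[ct]] <- list(pca = pca, centroid = centroid,
                           records = records, model = model,
                           prepost = prepost, weekly = weekly)
    rows[[ct]] <- cbind(call_type = ct, model$coefficients,
                        R2_marginal = model$R2_marginal,
                        R2_conditional = model$R2_conditional,
                        lrt_chisq = model$lrt$chisq, lrt_p = model$lrt$p,
                        n_obs = model$n_obs)
  }
  report <- structure(list(per_type = per_type,
                           table = do.call(rbind, c(rows,
                                                    make.row.names = FALSE)),
                           seed = as.integer(seed)),
                      class = "experiment2_report")
  if (!is.null(out_dir)) {
    write_report_outputs(report, out_dir, features,
                         list(translocated = translocated,
                              baseline = baseline, min_calls = min_calls,
                              pa_iter = pa_iter, n_boot = n_boot,
                              seed = seed))
  }
  report
}

#' @export
print.experiment2_report <- function(x, ...) {
  cat("Social accommodation over exposure time\n")
  for (ct in names(x$per_type)) {
    comp <- x$per_type[[ct]]
    cat(sprintf("\n-- %s: %d components retained (%.1f%% of variance) --\n",
                ct, comp$pca$n_retained,
                100 * sum(comp$pca$proportions[seq_len(comp$pca$n_retained)])))
    print(comp$model)
    if (!is.null(comp$prepost)) print(comp$prepost)
  }
  invisible(x)
}

# Writes plot-ready CSVs plus a manifest (settings, seeds, version) that
# suffices to reproduce the run.
write_report_outputs <- function(report, out_dir, features, settings) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$table, file.path(out_dir, "report_table.csv"),
                   row.names = FALSE)
  if (inherits(report, "experiment2_report")) {
    for (ct in names(report$per_type)) {
      comp <- report$per_type[[ct]]
      utils::write.csv(comp$records,
                       file.path(out_dir, paste0("distances_", ct, ".csv")),
                       row.names = FALSE)
      utils::write.csv(comp$weekly,
                       file.path(out_dir, paste0("weekly_", ct, ".csv")),
                       row.names = FALSE)
      write_pca_model(comp$pca,
                      file.path(out_dir, paste0("pca_", ct, ".json")))
    }
  }
  manifest <- list(
    package = "vocalaccom",
    version = as.character(utils::packageVersion("vocalaccom")),
    settings = settings,
    n_input_calls = nrow(features),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
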