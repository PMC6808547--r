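#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state so that explicitly seeded operations
# never disturb (or depend on) the caller's global stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one parent seed; keeps every stochastic
# sub-step independently reproducible while staying inside 32-bit range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_cols <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Names of the per-call parameter columns in a feature table.
param_cols <- function(df) grep("^para_[0-9]+$", names(df), value = TRUE)

#' Significance marker used in report tables
#'
#' Returns `"*"` for p below `alpha`, `"(trend)"` for p below `trend`
#' (results the study convention flags as trends), otherwise `""`.
#' @param p p-value(s).
#' @param alpha significance level (default 0.05).
#' @param trend trend level (default 0.1).
#' @return character vector of markers.
#' @keywords internal
sig_marker <- function(p, alpha = 0.05, trend = 0.1) {
  ifelse(p < alpha, "*", ifelse(p < trend, "(trend)", ""))
}
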