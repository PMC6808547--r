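# Gaussian linear discriminant with pooled within-class covariance.
# Returns what the classifier needs: class labels (sorted), a weight
# matrix and per-class offsets so prediction is a single matrix product.
lda_train <- function(x, y) {
  x <- as.matrix(x)
  classes <- sort(unique(as.character(y)))
  if (length(classes) < 2L) stop("need >= 2 classes", call. = FALSE)
  p <- ncol(x)
  means <- matrix(0, length(classes), p)
  sw <- matrix(0, p, p)
  for (k in seq_along(classes)) {
    xk <- x[y == classes[k], , drop = FALSE]
    if (nrow(xk) < p + 1L) {
      stop(sprintf("class '%s' has %d rows; need >= %d (variables + 1)",
                   classes[k], nrow(xk), p + 1L), call. = FALSE)
    }
    means[k, ] <- colMeans(xk)
    sw <- sw + crossprod(sweep(xk, 2, means[k, ]))
  }
  sw <- sw / (nrow(x) - length(classes))
  w <- tryCatch(solve(sw, t(means)), error = function(e) NULL)
  if (is.null(w) || !all(is.finite(w))) {
    # ridge fallback for singular pooled covariance
    lambda <- 1e-8 * sum(diag(sw)) / p
    message(sprintf("lda_train: singular pooled covariance, ridge fallback (lambda = %.3g)",
                    lambda))
    w <- solve(sw + diag(lambda, p), t(means))
  }
  offsets <- -0.5 * colSums(t(means) * w)      # -1/2 mu_k' S^-1 mu_k
  list(classes = classes, w = w, offsets = offsets)
}

# Predict class labels; ties (identical discriminant scores) go to the
# first class in sorted label order via max.col("first").
lda_classify <- function(fit, newx) {
  scores <- as.matrix(newx) %*% fit$w
  scores <- sweep(scores, 2, fit$offsets, "+")
  fit$classes[max.col(scores, ties.method = "first")]
}

#' Linear discriminant fit-and-classify
#'
#' Fisher/Gaussian linear discriminant with pooled within-class covariance
#' and equal priors; the DFA core used inside [crossed_pdfa()]. A singular
#' pooled covariance falls back to a small ridge
#' (`lambda = 1e-8 * trace / p`) with a message.
#'
#' @param train_x,train_y training variables (matrix) and class labels.
#' @param test_x rows to classify.
#' @return Character vector of predicted labels for `test_x`.
#' @export
lda_fit_classify <- function(train_x, train_y, test_x) {
  lda_classify(lda_train(train_x, train_y), test_x)
}

#' Design for a crossed permuted discriminant function analysis
#'
#' @param test_factor column holding the factor under test (e.g. condition
#'   with levels "Before"/"After1").
#' @param control_factor column holding the repeated-measures grouping
#'   whose non-independence must be respected (caller identity).
#' @param variables character vector of score columns used as discriminant
#'   variables.
#' @param n_permutations permutations for the null distribution (>= 100).
#' @param n_selection_rounds balanced train/test splits averaged for the
#'   observed statistic.
#' @param n_selection_rounds_null splits averaged per permutation; `NULL`
#'   (default) uses `n_selection_rounds`, so the permuted statistics are
#'   computed exactly like the observed one and the permutation test is
#'   exchangeable. Setting 1 gives a cheaper variant (one random selection
#'   per permutation) that is conservative because the single-split null
#'   statistics are noisier than the averaged observed one.
#' @param cell_quota training calls drawn from each (control x test) cell;
#'   default `min cell size - 1`, at least 2.
#' @param seed RNG seed.
#' @return A `pdfa_design` list.
#' @export
pdfa_design <- function(test_factor = "condition",
                        control_factor = "caller",
                        variables,
                        n_permutations = 1000,
                        n_selection_rounds = 100,
                        n_selection_rounds_null = NULL,
                        cell_quota = NULL,
                        seed = 1L) {
  if (n_permutations < 100) stop("n_permutations must be >= 100",
                                 call. = FALSE)
  structure(list(test_factor = test_factor, control_factor = control_factor,
                 variables = variables,
                 n_permutations = as.integer(n_permutations),
                 n_selection_rounds = as.integer(n_selection_rounds),
                 n_selection_rounds_null =
                   as.integer(n_selection_rounds_null %||% n_selection_rounds),
                 cell_quota = cell_quota, seed = as.integer(seed)),
            class = "pdfa_design")
}

#' Crossed permuted discriminant function analysis
#'
#' Tests whether calls differ between the levels of a test factor while
#' controlling for individual identity. The observed statistic is the mean
#' percentage of held-out calls correctly cross-classified over
#' `n_selection_rounds` balanced splits: each split draws `cell_quota`
#' calls per (individual x condition) cell for training and classifies the
#' remainder. The null distribution repeats the computation on data whose
#' condition labels are permuted *blockwise within each individual* (all
#' calls of an individual's condition block are relabelled together), the
#' restricted permutation that preserves individual differences. The
#' p-value uses the add-one convention,
#' `p = (# permuted >= observed + 1) / (n_permutations + 1)`, and the
#' chance-expected correct classification is the mean of the permuted
#' statistics.
#'
#' @param scores data frame holding the discriminant variables plus the
#'   test- and control-factor columns.
#' @param design a [pdfa_design()].
#' @return A `pdfa` object: `pct_expected_correct`, `pct_actual_correct`,
#'   `p_value`, `n_calls`, `n_individuals`, `n_permutations_used`, and the
#'   permuted statistics. Errors if any (individual x condition) cell is
#'   empty (the design would not be crossed).
#' @export
crossed_pdfa <- function(scores, design) {
  stopifnot(inherits(design, "pdfa_design"))
  stopifnot_cols(scores, c(design$test_factor, design$control_factor,
                           design$variables), "scores")
  x <- as.matrix(scores[, design$variables, drop = FALSE])
  storage.mode(x) <- "double"
  cond <- as.character(scores[[design$test_factor]])
  ind <- as.character(scores[[design$control_factor]])
  cond_levels <- sort(unique(cond))
  ind_levels <- sort(unique(ind))
  if (length(cond_levels) < 2L) {
    stop("test factor needs >= 2 levels", call. = FALSE)
  }

  # per-individual list of per-condition row-index blocks
  cells <- lapply(ind_levels, function(i) {
    lapply(stats::setNames(nm = cond_levels),
           function(cl) which(ind == i & cond == cl))
  })
  sizes <- vapply(cells, function(b) vapply(b, length, integer(1)),
                  integer(length(cond_levels)))
  if (any(sizes == 0L)) {
    stop("design not crossed: empty (individual x condition) cell(s)",
         call. = FALSE)
  }
  quota <- design$cell_quota %||% max(2L, min(sizes) - 1L)
  if (quota > min(sizes)) {
    stop(sprintf("cell_quota %d exceeds the smallest cell (%d calls)",
                 quota, min(sizes)), call. = FALSE)
  }
  if (quota == min(sizes)) {
    message("cell_quota equals the smallest cell; that cell contributes no test calls")
  }

  # one balanced split: train on `quota` calls per cell, classify the rest
  split_accuracy <- function(labels) {
    train <- unlist(lapply(cells, function(blocks) {
      unlist(lapply(blocks, function(idx) {
        if (length(idx) == quota) idx else idx[sample.int(length(idx), quota)]
      }), use.names = FALSE)
    }), use.names = FALSE)
    test <- setdiff(seq_len(nrow(x)), train)
    if (!length(test)) return(NA_real_)
    fit <- lda_train(x[train, , drop = FALSE], labels[train])
    mean(lda_classify(fit, x[test, , drop = FALSE]) == labels[test])
  }

  # blockwise label permutation: each individual's condition blocks are
  # relabelled by a random permutation of the condition levels
  permute_labels <- function() {
    out <- cond
    for (b in cells) {
      perm <- sample(cond_levels)
      for (k in seq_along(cond_levels)) out[b[[k]]] <- perm[k]
    }
    out
  }

  with_seed(design$seed, {
    observed <- mean(vapply(seq_len(design$n_selection_rounds),
                            function(r) split_accuracy(cond), numeric(1)),
                     na.rm = TRUE)
    null_stats <- vapply(seq_len(design$n_permutations), function(b) {
      labs <- permute_labels()
      mean(vapply(seq_len(design$n_selection_rounds_null),
                  function(r) split_accuracy(labs), numeric(1)), na.rm = TRUE)
    }, numeric(1))
    p <- (sum(null_stats >= observed) + 1) / (design$n_permutations + 1)
    structure(list(
      pct_expected_correct = 100 * mean(null_stats),
      pct_actual_correct = 100 * observed,
      p_value = p,
      n_calls = nrow(x),
      n_individuals = length(ind_levels),
      n_permutations_used = design$n_permutations,
      cell_quota = quota,
      test_levels = cond_levels,
      null_stats = 100 * null_stats,
      design = design
    ), class = "pdfa")
  })
}

#' @export
print.pdfa <- function(x, ...) {
  cat(sprintf("Crossed pDFA (%s): %d calls, %d individuals\n",
              paste(x$test_levels, collapse = " vs "),
              x$n_calls, x$n_individuals))
  cat(sprintf("  %% expected correct: %.2f\n", x$pct_expected_correct))
  cat(sprintf("  %% actual correct:   %.2f\n", x$pct_actual_correct))
  cat(sprintf("  p = %.4g (%d permutations) %s\n", x$p_value,
              x$n_permutations_used, sig_marker(x$p_value)))
  invisible(x)
}
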