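#' Trimmed mean
#'
#' Drops the `floor(trim * n)` smallest and largest values, then averages
#' the rest. With fewer than `1 / trim` values nothing is dropped and the
#' ordinary mean is returned.
#'
#' @param values numeric vector.
#' @param trim trim proportion per tail (default 0.10).
#' @return The trimmed mean; error if no values survive the trim.
#' @export
trimmed_mean <- function(values, trim = 0.10) {
  values <- as.numeric(values)
  n <- length(values)
  k <- floor(trim * n)
  if (n - 2 * k < 1L) stop("no values left after trimming", call. = FALSE)
  s <- sort(values)
  mean(s[(k + 1L):(n - k)])
}

#' Population centroid in retained component space
#'
#' The population's average vocalization: along each retained component
#' axis, each baseline individual's 10% trimmed mean of call scores is
#' computed first, and the centroid coordinate is the unweighted mean of
#' those per-individual trimmed means. The two-stage construction gives
#' every individual equal weight regardless of call count and resists
#' outlier calls.
#'
#' @param scores matrix of retained-component scores for the baseline
#'   population's calls.
#' @param individuals caller ID per row of `scores` (>= 2 distinct).
#' @param trim per-tail trim proportion (default 0.10).
#' @param call_type optional label.
#' @return A `population_centroid`: `coordinates`, `individuals`, `trim`.
#' @export
population_centroid <- function(scores, individuals, trim = 0.10,
                                call_type = NA_character_) {
  scores <- as.matrix(scores)
  individuals <- as.character(individuals)
  stopifnot(nrow(scores) == length(individuals))
  ids <- sort(unique(individuals))
  if (length(ids) < 2L) {
    stop("need >= 2 contributing individuals for a population centroid",
         call. = FALSE)
  }
  per_ind <- t(vapply(ids, function(i) {
    apply(scores[individuals == i, , drop = FALSE], 2, trimmed_mean,
          trim = trim)
  }, numeric(ncol(scores))))
  structure(list(coordinates = colMeans(per_ind),
                 per_individual = per_ind,
                 individuals = ids, trim = trim, call_type = call_type),
            class = "population_centroid")
}

#' Variance-weighted Euclidean distance to a population centroid
#'
#' Each retained component axis is multiplied by the proportion of the
#' total variance that component explains before taking the Euclidean
#' norm:
#' \deqn{d = \sqrt{\sum_k \left(p_k (s_k - c_k)\right)^2}}
#' An alternative reading -- proportions as weights of the squared terms,
#' \eqn{d = \sqrt{\sum_k p_k (s_k - c_k)^2}} -- is available via
#' `method = "sqrt"` for sensitivity analysis.
#'
#' @param score numeric vector (or matrix, one call per row) of retained
#'   component scores.
#' @param centroid a `population_centroid` or numeric coordinate vector.
#' @param proportions explained-variance proportions `p_k` of the retained
#'   components (from the same `retained_pca`).
#' @param method `"scale"` (default) or `"sqrt"`.
#' @return Distance(s), one per call.
#' @export
weighted_distance <- function(score, centroid, proportions,
                              method = c("scale", "sqrt")) {
  method <- match.arg(method)
  coords <- if (inherits(centroid, "population_centroid")) {
    centroid$coordinates
  } else {
    as.numeric(centroid)
  }
  s <- if (is.matrix(score)) score else matrix(score, nrow = 1)
  if (ncol(s) != length(coords) || length(proportions) != length(coords)) {
    stop("score, centroid and proportions must share dimensionality",
         call. = FALSE)
  }
  diff <- sweep(s, 2, coords)
  if (method == "scale") {
    sqrt(rowSums(sweep(diff, 2, proportions, "*")^2))
  } else {
    sqrt(rowSums(sweep(diff^2, 2, proportions, "*")))
  }
}

#' Per-call vocal-distance records
#'
#' One record per call of the focal (translocated) animals: the
#' variance-weighted distance of the call's retained-PC scores from the
#' frozen population centroid, plus its natural log (the outcome used by
#' all accommodation models). A distance of exactly zero (probability zero
#' for real data) is clamped at 1e-12 before the log, with a warning.
#'
#' @param scores score matrix for the focal calls (rows match `meta`).
#' @param meta data frame with at least `caller`, `sex`, `call_type`,
#'   `week`, `condition` for the same calls.
#' @param centroid a `population_centroid`.
#' @param model the `retained_pca` whose proportions weight the axes.
#' @param method passed to [weighted_distance()].
#' @return Data frame of `distance_records`: metadata plus `distance` and
#'   `ln_distance`.
#' @export
build_distance_records <- function(scores, meta, centroid, model,
                                   method = c("scale", "sqrt")) {
  stopifnot(inherits(model, "retained_pca"))
  stopifnot_cols(meta, c("caller", "sex", "call_type", "week", "condition"),
                 "meta")
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == nrow(meta))
  p_k <- model$proportions[seq_len(model$n_retained)]
  d <- weighted_distance(scores, centroid, p_k, method = method)
  if (any(d == 0)) {
    warning("distance of exactly 0 clamped at 1e-12 before ln transform")
    d <- pmax(d, 1e-12)
  }
  out <- data.frame(caller = meta$caller, sex = meta$sex,
                    call_type = meta$call_type, week = meta$week,
                    condition = meta$condition,
                    distance = d, ln_distance = log(d),
                    stringsAsFactors = FALSE)
  class(out) <- c("distance_records", "data.frame")
  out
}
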