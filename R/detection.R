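#' One-sided Wilcoxon rank-sum test (cells greater)
#'
#' Tests whether the cell-sample values are stochastically larger than the
#' debris (background) values. For combined sample sizes up to
#' `exact_max_n` the p-value is exact under the permutation null: ties are
#' handled by mid-ranks and the rank sum is enumerated exhaustively over
#' all group assignments. For larger samples a tie-corrected normal
#' approximation with continuity correction is used. The returned p lies
#' in (0, 1].
#'
#' @param cells numeric vector of cell-sample intensities (length >= 2).
#' @param debris numeric vector of debris-sample intensities (length >= 2).
#' @param exact_max_n combined sample size up to which the exact
#'   enumeration is used (default 12).
#' @return one-sided p-value for the alternative "cells greater".
#' @export
#' @examples
#' rank_sum_one_sided(c(4, 5, 6), c(1, 2, 3))  # 1/20
rank_sum_one_sided <- function(cells, debris, exact_max_n = 12) {
  cells <- as.numeric(cells); debris <- as.numeric(debris)
  if (length(cells) < 2 || length(debris) < 2)
    stop("each group needs at least 2 values")
  if (anyNA(cells) || anyNA(debris)) stop("missing values are not allowed")
  n1 <- length(cells); n2 <- length(debris); n <- n1 + n2
  r <- rank(c(cells, debris))   # mid-ranks for ties
  w_obs <- sum(r[seq_len(n1)])
  if (n <= exact_max_n) {
    combos <- utils::combn(n, n1)
    w_all <- colSums(matrix(r[combos], nrow = n1))
    # exact permutation p: fraction of assignments with rank sum >= observed
    # (>= with a small tolerance so mid-rank ties compare exactly)
    p <- mean(w_all >= w_obs - 1e-9)
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(1)
    p <- stats::pnorm(w_obs - 0.5, mean = mu, sd = sqrt(sigma2),
                      lower.tail = FALSE)
  }
  min(max(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns FDR-adjusted values in the input order:
#' `q_(i) = min over j >= i of min(1, p_(j) * m / j)` over the sorted
#' p-values.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.005, 0.1))  # 0.01, 0.1
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, m / seq_len(m) * p[ord])
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Detection above sorted-debris background across an event-count series
#'
#' For every event level shared by cell and debris samples, each
#' metabolite is tested with the one-sided rank-sum test (cells greater
#' than debris) and p-values are BH-adjusted across the metabolites of
#' that level. A metabolite is *significant* at a level when its q-value
#' is below `alpha`, and *detected* under the chained rule: at the highest
#' level detection equals significance; at any lower level the metabolite
#' must be significant there *and* detected at the next higher level.
#' Internal standards are excluded from the tested family but reported
#' alongside with untouched one-sided p-values.
#'
#' @param table a preprocessed (complete, outlier-filtered)
#'   [peak_table()] with cell and debris samples at common event levels.
#' @param alpha FDR threshold, default 0.05.
#' @param chain `"recursive"` (default; detection at a level requires
#'   detection at every higher level), `"single"` (only the next higher
#'   level must be significant) or `"off"` (detected = significant).
#' @return an object of class `detection_result`: data.frame with columns
#'   `metabolite`, `event_level`, `p_value`, `q_value`, `significant`,
#'   `detected`, `is_internal_standard`; attribute `alpha`.
#' @export
detect_above_background <- function(table, alpha = 0.05,
                                    chain = c("recursive", "single", "off")) {
  validate_peak_table(table)
  chain <- match.arg(chain)
  s <- table$samples
  levels_cell <- unique(s$event_count[s$role == "cell"])
  levels_debris <- unique(s$event_count[s$role == "debris"])
  levels <- sort(intersect(levels_cell, levels_debris))
  if (length(levels) == 0)
    stop("no event level with both cell and debris samples")
  is_std <- table$metabolites$is_internal_standard
  mids <- table$metabolites$metabolite_id
  res <- do.call(rbind, lapply(levels, function(k) {
    ci <- which(s$role == "cell" & s$event_count == k)
    di <- which(s$role == "debris" & s$event_count == k)
    if (length(ci) < 2 || length(di) < 2)
      stop("event level ", k, " lacks >= 2 cell and >= 2 debris samples")
    p <- vapply(mids, function(m) {
      x <- table$intensities[ci, m]; y <- table$intensities[di, m]
      if (anyNA(x) || anyNA(y))
        stop("missing values at level ", k, " for metabolite '", m,
             "'; run preprocessing (imputation) first")
      rank_sum_one_sided(x, y)
    }, numeric(1))
    q <- rep(NA_real_, length(p))
    q[!is_std] <- bh_adjust(p[!is_std])   # BH family: tested metabolites of this level
    data.frame(metabolite = mids, event_level = k, p_value = unname(p),
               q_value = q,
               significant = !is.na(q) & q < alpha,
               is_internal_standard = is_std,
               stringsAsFactors = FALSE)
  }))
  res$detected <- res$significant
  if (chain != "off" && length(levels) > 1) {
    for (k in rev(seq_along(levels))[-1]) {
      cur <- res$event_level == levels[k]
      nxt <- res$event_level == levels[k + 1]
      upper <- if (chain == "recursive") res$detected[nxt] else res$significant[nxt]
      res$detected[cur] <- res$significant[cur] &
        upper[match(res$metabolite[cur], res$metabolite[nxt])]
    }
  }
  structure(res, alpha = alpha, chain = chain, class = c("detection_result",
                                                         "data.frame"))
}

#' Detection-count curve over event levels
#'
#' Counts detected metabolites per event level and collects the detected
#' id sets. Under the recursive chained rule the sets are nested upward,
#' so the counts are non-decreasing in the event count; this is asserted
#' on every call.
#'
#' @param result a `detection_result` from [detect_above_background()].
#' @return an object of class `detection_curve`: data.frame with
#'   `event_level` and `n_detected`; attribute `detected_sets` holds the
#'   per-level id sets.
#' @export
detection_curve <- function(result) {
  stopifnot(inherits(result, "detection_result"))
  tested <- result[!result$is_internal_standard, ]
  levels <- sort(unique(tested$event_level))
  sets <- lapply(levels, function(k)
    tested$metabolite[tested$event_level == k & tested$detected])
  names(sets) <- as.character(levels)
  if (identical(attr(result, "chain"), "recursive") && length(levels) > 1) {
    for (i in seq_len(length(levels) - 1))
      if (!all(sets[[i]] %in% sets[[i + 1]]))
        stop("internal error: chained detection sets are not nested upward")
  }
  structure(data.frame(event_level = levels,
                       n_detected = vapply(sets, length, integer(1)),
                       row.names = NULL),
            detected_sets = sets,
            class = c("detection_curve", "data.frame"))
}

#' Per-cell-type detection above background
#'
#' For each cell type, tests every metabolite against that cell type's own
#' matched debris samples at their shared event count (single level, no
#' chaining), BH-adjusting within the cell type. Returns the per-type
#' detected sets plus union and intersection summaries (e.g. how many
#' metabolites are detected in at least one, and in all, cell types).
#'
#' @param table a preprocessed [peak_table()] with `cell_type` metadata.
#' @param alpha FDR threshold, default 0.05.
#' @return list with `sets` (cell type -> detected metabolite ids),
#'   `union`, `intersection`, `n_union`, `n_intersection` and `per_type`
#'   (data.frame of per-type detection counts).
#' @export
detect_per_celltype <- function(table, alpha = 0.05) {
  validate_peak_table(table)
  s <- table$samples
  types <- unique(s$cell_type[s$role == "cell"])
  if (length(types) == 0) return(list(sets = list(), union = character(),
                                      intersection = character(),
                                      n_union = 0L, n_intersection = 0L,
                                      per_type = data.frame()))
  is_std <- table$metabolites$is_internal_standard
  mids <- table$metabolites$metabolite_id[!is_std]
  sets <- lapply(stats::setNames(types, types), function(t) {
    ci <- which(s$role == "cell" & s$cell_type == t)
    di <- which(s$role == "debris" & s$cell_type == t &
                  s$event_count %in% s$event_count[ci])
    if (length(di) < 2)
      stop("cell type '", t, "' has no matched debris samples at its event count")
    p <- vapply(mids, function(m)
      rank_sum_one_sided(table$intensities[ci, m], table$intensities[di, m]),
      numeric(1))
    mids[bh_adjust(p) < alpha]
  })
  un <- Reduce(union, sets)
  it <- Reduce(intersect, sets)
  list(sets = sets, union = un, intersection = it,
       n_union = length(un), n_intersection = length(it),
       per_type = data.frame(cell_type = names(sets),
                             n_detected = vapply(sets, length, integer(1)),
                             row.names = NULL))
}
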