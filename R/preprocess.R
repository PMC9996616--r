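#' Remove metabolites detected in too few samples
#'
#' A metabolite is "detected" in a sample when its peak value is
#' non-missing. Metabolites detected in fewer than `min_samples` samples
#' are dropped (the default 10 is the conventional floor for this kind of
#' batch). Applied before normalization.
#'
#' @param table a [peak_table()].
#' @param min_samples minimum number of samples with a non-missing value.
#' @return the filtered [peak_table()]; attribute `"dropped"` lists the
#'   removed metabolite ids.
#' @export
filter_low_detection <- function(table, min_samples = 10) {
  validate_peak_table(table)
  n_obs <- colSums(!is.na(table$intensities))
  keep <- n_obs >= min_samples
  out <- table[, which(keep)]
  attr(out, "dropped") <- names(n_obs)[!keep]
  out
}

#' Best-matched internal-standard normalization
#'
#' Every non-standard metabolite is normalized to the internal standard
#' whose ratio to it is most stable across samples: for each candidate
#' standard `i` the coefficient of variation of the ratio `m/i` is
#' computed over samples where both are present, and the standard with the
#' smallest CV wins (ties broken by standard id order). The normalized
#' value is `(m/i*) * median(i*)`, which removes the per-sample technical
#' factor while keeping values on the original intensity scale so that
#' half-minimum imputation downstream remains meaningful. Internal
#' standards themselves pass through unchanged.
#'
#' @param table a [peak_table()] containing at least one internal
#'   standard. Standards missing in more than `max_missing` of samples are
#'   excluded from candidacy with a warning.
#' @param max_missing maximum tolerated fraction of missing values for a
#'   standard to be a candidate (default 0.5).
#' @return list with `table` (normalized [peak_table()]) and `report`
#'   (data.frame: `metabolite`, `matched_standard`, `match_score` = the
#'   winning CV, plus a `scale_factor` attribute with each standard's
#'   median).
#' @export
best_matched_normalize <- function(table, max_missing = 0.5) {
  validate_peak_table(table)
  v <- table$intensities
  std_idx <- pt_standards(table)
  if (length(std_idx) == 0) stop("no internal standards present")
  std_ids <- table$metabolites$metabolite_id[std_idx]
  miss_frac <- colMeans(is.na(v[, std_idx, drop = FALSE]))
  usable <- miss_frac <= max_missing
  if (any(!usable))
    warning("internal standard(s) missing in > ", 100 * max_missing,
            "% of samples excluded from candidacy: ",
            paste(std_ids[!usable], collapse = ", "))
  std_ids <- std_ids[usable]
  if (length(std_ids) == 0) stop("no internal standard with sufficient coverage")
  scale_factor <- vapply(std_ids, function(s)
    stats::median(v[, s], na.rm = TRUE), numeric(1))
  target <- setdiff(table$metabolites$metabolite_id,
                    table$metabolites$metabolite_id[std_idx])
  match_std <- character(length(target))
  match_cv <- numeric(length(target))
  out <- v
  for (k in seq_along(target)) {
    m <- target[k]
    cvs <- vapply(std_ids, function(s) {
      r <- v[, m] / v[, s]
      r <- r[is.finite(r)]
      if (length(r) < 2) return(Inf)
      mu <- mean(r)
      if (mu == 0) return(Inf)
      stats::sd(r) / mu
    }, numeric(1))
    best <- which.min(cvs)   # which.min takes the first minimum: id-order tie-break
    match_std[k] <- std_ids[best]
    match_cv[k] <- cvs[best]
    out[, m] <- v[, m] / v[, std_ids[best]] * scale_factor[std_ids[best]]
  }
  res <- table
  res$intensities <- out
  list(table = res,
       report = structure(data.frame(metabolite = target,
                                     matched_standard = match_std,
                                     match_score = match_cv,
                                     stringsAsFactors = FALSE),
                          scale_factor = scale_factor))
}

#' Half-minimum imputation of missing values
#'
#' Every missing entry of a metabolite is replaced by half the smallest
#' observed value of that metabolite; observed entries are untouched. A
#' metabolite with no observed value at all cannot be imputed and raises
#' an error (it should have been removed by [filter_low_detection()]).
#'
#' @param table a [peak_table()].
#' @return the imputed [peak_table()].
#' @export
impute_half_min <- function(table) {
  validate_peak_table(table)
  v <- table$intensities
  n_obs <- colSums(!is.na(v))
  if (any(n_obs == 0))
    stop("metabolite(s) with no observed values cannot be imputed: ",
         paste(colnames(v)[n_obs == 0], collapse = ", "))
  half_min <- apply(v, 2, min, na.rm = TRUE) / 2
  for (j in seq_len(ncol(v))) {
    miss <- is.na(v[, j])
    v[miss, j] <- half_min[j]
  }
  table$intensities <- v
  table
}

#' z-score removal of outlier samples
#'
#' Each sorted sample (role cell or debris) is summarised by a single
#' statistic on event-number-normalized data — by default the median over
#' metabolites of `intensity / event_count` — and compared with the other
#' samples of its (cell type x role x event count) group. The z-score of
#' sample `i` is computed leave-one-out: against the mean and standard
#' deviation of the remaining group members. A plain within-group z is
#' bounded by `(n-1)/sqrt(n)` (about 2.47 for n = 8) and could never cross
#' the conventional threshold of 3; the leave-one-out form removes that
#' masking and flags genuine whole-sample outliers. Samples with
#' `|z| > threshold` are removed. Groups whose remaining members have zero
#' spread remove nothing unless the sample itself deviates; groups smaller
#' than 3 are skipped with a warning. Blank/medium samples (no event
#' count) pass through unfiltered.
#'
#' @param table a [peak_table()].
#' @param threshold absolute z-score above which a sample is removed
#'   (default 3).
#' @param statistic per-sample summary of event-normalized intensities:
#'   `"median"` (default), `"mean"` or `"total"`.
#' @return list with `table` (filtered [peak_table()]) and `report`
#'   (data.frame: `sample_id`, `group`, `statistic`, `z`, `removed`).
#' @export
zscore_outlier_filter <- function(table, threshold = 3,
                                  statistic = c("median", "mean", "total")) {
  validate_peak_table(table)
  statistic <- match.arg(statistic)
  v <- table$intensities
  s <- table$samples
  sorted <- s$role %in% c("cell", "debris")
  ev <- as.numeric(s$event_count)
  stat <- rep(NA_real_, nrow(s))
  fun <- switch(statistic, median = stats::median,
                mean = mean, total = sum)
  for (i in which(sorted))
    stat[i] <- fun(v[i, ] / ev[i], na.rm = TRUE)
  ct <- if ("cell_type" %in% names(s)) as.character(s$cell_type) else ""
  grp <- ifelse(sorted, paste(ct, s$role, ev, sep = "|"), NA_character_)
  z <- rep(NA_real_, nrow(s))
  for (g in unique(grp[sorted])) {
    idx <- which(!is.na(grp) & grp == g)
    if (length(idx) < 3) {
      warning("group '", g, "' has fewer than 3 samples; skipped by the z-filter")
      next
    }
    for (i in idx) {
      rest <- stat[setdiff(idx, i)]
      mu <- mean(rest)
      sdv <- stats::sd(rest)
      dev <- stat[i] - mu
      z[i] <- if (dev == 0) 0 else if (sdv == 0) Inf * sign(dev) else dev / sdv
    }
  }
  removed <- !is.na(z) & abs(z) > threshold
  report <- data.frame(sample_id = s$sample_id,
                       group = grp,
                       statistic = stat,
                       z = z,
                       removed = removed,
                       stringsAsFactors = FALSE)
  list(table = table[which(!removed), ], report = report)
}

#' Run the full preprocessing chain
#'
#' Applies low-detection filtering, best-matched internal-standard
#' normalization, half-minimum imputation and z-score outlier removal.
#' The outlier z statistic is computed on the *event-number-normalized
#' raw* intensities (after filtering, before internal-standard
#' normalization): a whole-sample technical outlier inflates biological
#' signals and internal standards alike, so internal-standard
#' normalization cancels it exactly and a z-filter applied downstream of
#' it could never see such samples. The flagged samples are removed from
#' the normalized, imputed table.
#'
#' @param table a [peak_table()].
#' @param min_samples see [filter_low_detection()].
#' @param z_threshold,z_statistic see [zscore_outlier_filter()].
#' @param normalize set `FALSE` to skip internal-standard normalization
#'   (e.g. when no standards were measured).
#' @return list with `table` (the processed [peak_table()]),
#'   `dropped_metabolites`, `normalization` (report or `NULL`) and
#'   `outliers` (report).
#' @export
preprocess <- function(table, min_samples = 10, z_threshold = 3,
                       z_statistic = "median", normalize = TRUE) {
  filtered <- filter_low_detection(table, min_samples = min_samples)
  dropped <- attr(filtered, "dropped")
  zf <- zscore_outlier_filter(filtered, threshold = z_threshold,
                              statistic = z_statistic)
  norm_report <- NULL
  out <- filtered
  if (normalize) {
    norm <- best_matched_normalize(out)
    out <- norm$table
    norm_report <- norm$report
  }
  out <- impute_half_min(out)
  keep <- !out$samples$sample_id %in% zf$report$sample_id[zf$report$removed]
  list(table = out[which(keep), ],
       dropped_metabolites = dropped,
       normalization = norm_report,
       outliers = zf$report)
}
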