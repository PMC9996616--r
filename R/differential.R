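#' Blank-gated volcano comparison of two sample groups
#'
#' Metabolites are first gated on being above blank in *both* groups: for
#' each group, a one-sided rank-sum test of that group's cell samples
#' against the blank-role samples, BH-adjusted across metabolites within
#' the group, must give q < `alpha_blank`. For included metabolites the
#' log2 fold change is computed from the ratio of group means (medians by
#' option) of processed intensities and the p-value from a two-sided
#' Welch (unequal-variance) t test. A metabolite is a *hit* when it is
#' included, `|log2FC| > 1` (a fold change beyond +-2) and `p < p_hit`.
#' A BH-adjusted column over the included Welch p-values is emitted as
#' well.
#'
#' @param table a preprocessed [peak_table()].
#' @param group_a,group_b values of the sample `group` column to compare
#'   (fold change is A over B).
#' @param blank_role sample role used as blank, default `"debris"`.
#' @param alpha_blank FDR threshold of the above-blank gate.
#' @param p_hit two-sided p threshold of the hit call (default 0.05).
#' @param center `"mean"` (default) or `"median"` group summary for the
#'   fold change.
#' @return an object of class `volcano_result`: data.frame with columns
#'   `metabolite`, `log2_fold_change`, `p_value`, `q_value`, `included`,
#'   `hit`.
#' @export
volcano <- function(table, group_a, group_b, blank_role = "debris",
                    alpha_blank = 0.05, p_hit = 0.05,
                    center = c("mean", "median")) {
  validate_peak_table(table)
  center <- match.arg(center)
  s <- table$samples
  ai <- which(s$group %in% group_a & s$role == "cell")
  bi <- which(s$group %in% group_b & s$role == "cell")
  if (length(ai) < 2 || length(bi) < 2)
    stop("both groups need >= 2 cell samples (found ", length(ai), " and ",
         length(bi), ")")
  bl <- which(s$role == blank_role)
  if (length(bl) < 2) stop("need >= 2 samples with blank role '", blank_role, "'")
  is_std <- table$metabolites$is_internal_standard
  mids <- table$metabolites$metabolite_id[!is_std]
  gate_q <- function(gi) {
    p <- vapply(mids, function(m)
      rank_sum_one_sided(table$intensities[gi, m], table$intensities[bl, m]),
      numeric(1))
    bh_adjust(p)
  }
  included <- gate_q(ai) < alpha_blank & gate_q(bi) < alpha_blank
  cen <- if (center == "mean") colMeans(table$intensities[, mids, drop = FALSE][ai, , drop = FALSE])
         else apply(table$intensities[ai, mids, drop = FALSE], 2, stats::median)
  cen_b <- if (center == "mean") colMeans(table$intensities[bi, mids, drop = FALSE])
           else apply(table$intensities[bi, mids, drop = FALSE], 2, stats::median)
  l2fc <- log2(cen / cen_b)
  p <- vapply(mids, function(m)
    stats::t.test(table$intensities[ai, m], table$intensities[bi, m],
                  var.equal = FALSE)$p.value, numeric(1))
  q <- rep(NA_real_, length(mids))
  if (any(included)) q[included] <- bh_adjust(p[included])
  res <- data.frame(metabolite = mids,
                    log2_fold_change = unname(l2fc),
                    p_value = unname(p),
                    q_value = q,
                    included = unname(included),
                    stringsAsFactors = FALSE)
  res$hit <- res$included & abs(res$log2_fold_change) > 1 & res$p_value < p_hit
  structure(res, alpha_blank = alpha_blank,
            class = c("volcano_result", "data.frame"))
}

#' Retention-time and intensity deltas of a buffer against a reference
#'
#' Compares per-metabolite retention time and signal intensity measured
#' with a buffer (e.g. 5 g/L NaCl or PBS) against a water reference:
#' `delta_rt = treatment - reference` (minutes) and
#' `log2_intensity_ratio = log2(treatment / reference)`. Metabolites
#' missing in either condition are dropped with a warning.
#'
#' @param reference,treatment data.frames with columns `metabolite`, `rt`
#'   (minutes) and `intensity`.
#' @return data.frame with `metabolite`, `delta_rt`,
#'   `log2_intensity_ratio`; attribute `summary` holds the median
#'   `|delta_rt|` and the median log2 ratio.
#' @export
buffer_effect <- function(reference, treatment) {
  need <- c("metabolite", "rt", "intensity")
  stopifnot(all(need %in% names(reference)), all(need %in% names(treatment)))
  common <- intersect(reference$metabolite, treatment$metabolite)
  lost <- setdiff(union(reference$metabolite, treatment$metabolite), common)
  if (length(lost))
    warning("metabolite(s) missing in one condition dropped: ",
            paste(lost, collapse = ", "))
  ri <- match(common, reference$metabolite)
  ti <- match(common, treatment$metabolite)
  out <- data.frame(metabolite = common,
                    delta_rt = treatment$rt[ti] - reference$rt[ri],
                    log2_intensity_ratio = log2(treatment$intensity[ti] /
                                                  reference$intensity[ri]),
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- c(median_abs_delta_rt = stats::median(abs(out$delta_rt)),
                            median_log2_ratio = stats::median(out$log2_intensity_ratio))
  out
}

#' PCA of metabolic profiles
#'
#' Log10-transforms the selected metabolites, autoscales each metabolite
#' (zero mean, unit variance across samples) and decomposes the result
#' with [stats::prcomp()]. Metabolites with zero variance after the log
#' transform are dropped with a warning. Typically run on the metabolites
#' detected above background in all cell types.
#'
#' @param table a preprocessed, complete (imputed) [peak_table()] with
#'   strictly positive intensities.
#' @param metabolite_subset metabolite ids to use; default all.
#' @return list with `scores` (samples x components), `loadings`,
#'   `variance_fraction` (non-increasing, sums to 1) and `samples` (the
#'   sample metadata, for plotting).
#' @export
pca_profiles <- function(table, metabolite_subset = NULL) {
  validate_peak_table(table)
  if (is.null(metabolite_subset))
    metabolite_subset <- table$metabolites$metabolite_id
  if (length(metabolite_subset) == 0) stop("metabolite_subset is empty")
  missing_ids <- setdiff(metabolite_subset, table$metabolites$metabolite_id)
  if (length(missing_ids))
    stop("unknown metabolite(s): ", paste(missing_ids, collapse = ", "))
  if (nrow(table$intensities) < 3) stop("PCA needs >= 3 samples")
  v <- table$intensities[, metabolite_subset, drop = FALSE]
  if (anyNA(v) || any(v <= 0))
    stop("PCA input must be complete and strictly positive; impute first")
  lv <- log10(v)
  vars <- apply(lv, 2, stats::var)
  if (any(vars == 0)) {
    warning("zero-variance metabolite(s) dropped: ",
            paste(colnames(lv)[vars == 0], collapse = ", "))
    lv <- lv[, vars > 0, drop = FALSE]
  }
  if (ncol(lv) == 0) stop("no metabolite with non-zero variance")
  pc <- stats::prcomp(lv, center = TRUE, scale. = TRUE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, variance_fraction = vf,
       samples = table$samples)
}

#' Cross-study correlation of log abundance ratios
#'
#' Correlates two per-metabolite signed log ratios (e.g. the log ratio of
#' median signal intensity between two cell types in this study and in a
#' published one) over their common metabolites, with Pearson's R and a
#' two-sided p-value.
#'
#' @param ratios_a,ratios_b named numeric vectors, metabolite -> signed
#'   log ratio.
#' @return list with `r`, `n_common`, `p_value` and `common` (the ids
#'   used).
#' @export
cross_study_correlation <- function(ratios_a, ratios_b) {
  if (is.null(names(ratios_a)) || is.null(names(ratios_b)))
    stop("ratio maps must be named by metabolite")
  common <- intersect(names(ratios_a), names(ratios_b))
  common <- common[is.finite(ratios_a[common]) & is.finite(ratios_b[common])]
  if (length(common) < 3)
    stop("need >= 3 common metabolites (found ", length(common), ")")
  ct <- stats::cor.test(ratios_a[common], ratios_b[common], method = "pearson")
  list(r = unname(ct$estimate), n_common = length(common),
       p_value = ct$p.value, common = common)
}
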