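# Small peak-table fixtures built in code.

make_table <- function(mat, roles, event_count = 5000, cell_type = "A",
                       group = NA_character_, is_standard = NULL) {
  n <- nrow(mat)
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("s%02d", seq_len(n))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("m%02d", seq_len(ncol(mat)))
  if (is.null(is_standard)) is_standard <- rep(FALSE, ncol(mat))
  peak_table(mat,
    samples = data.frame(sample_id = rownames(mat),
                         role = rep_len(roles, n),
                         event_count = rep_len(event_count, n),
                         cell_type = rep_len(cell_type, n),
                         group = rep_len(group, n),
                         experiment = "e1",
                         replicate = seq_len(n),
                         stringsAsFactors = FALSE),
    metabolites = data.frame(metabolite_id = colnames(mat),
                             is_internal_standard = is_standard,
                             standard_kind = ifelse(is_standard, "c13", "none"),
                             stringsAsFactors = FALSE))
}

# config shorthand used by several files: quiet, uncensored, no outliers
quiet_config <- function(...) {
  synthetic_config(lognormal_sigma_metabolite = 0,
                   lognormal_sigma_technical = 0,
                   lognormal_sigma_experiment = 0,
                   lod_quantile = 0, outlier_rate = 0, ...)
}
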