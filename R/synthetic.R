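#' Configuration for the synthetic peak-table generator
#'
#' The generator emulates the statistical structure of targeted MRM peak
#' tables from FACS-sorted cells and matched sorted-debris backgrounds:
#' cell signal proportional to the number of sorted events for
#' intracellular compounds, event-independent background shared by cell
#' and debris samples for extracellular compounds (the spiked-standard
#' pattern), both components for mixed compounds, internal standards
#' carrying only the per-sample technical factor, multiplicative
#' log-normal noise, censoring below a per-metabolite limit of detection,
#' occasional whole-sample outliers, treatment fold changes and cell-type
#' content multipliers.
#'
#' @param n_metabolites number of biological metabolites (internal
#'   standards come on top).
#' @param n_internal_standards number of internal standards.
#' @param event_levels strictly increasing vector of sorted-event counts;
#'   the default series is 100, 500, 1000, 2000, 3000, 4000, 5000.
#' @param replicates_per_group replicate samples per (role x level) or per
#'   treatment group; default 8.
#' @param class_fractions named proportions over
#'   `c(intracellular, extracellular, mixed)`; must sum to 1.
#' @param per_cell_content_range uniform range for per-cell content,
#'   intensity-units per cell.
#' @param background_level_range uniform range for extracellular
#'   background, intensity units.
#' @param lognormal_sigma_metabolite sdlog of per-measurement noise.
#' @param lognormal_sigma_technical sdlog of the shared per-sample
#'   technical factor.
#' @param lognormal_sigma_experiment sdlog of the experiment-level factor
#'   (cell-type panel only).
#' @param lod_quantile fraction in `[0, 1)` steering each metabolite's
#'   limit of detection: for purely intracellular compounds the LOD is
#'   this quantile of the noise-free cell-signal series over the event
#'   levels (so debris and low-event cell samples censor); for compounds
#'   with a flat background or spiked component the LOD is the same
#'   fraction of that flat level (effectively uncensored). Values strictly
#'   below the LOD are recorded as missing. 0 disables censoring of
#'   everything except the zero debris signal of intracellular compounds.
#' @param outlier_rate probability that a sample is an injected outlier.
#' @param outlier_magnitude multiplicative factor applied to all
#'   intensities of an outlier sample.
#' @param treatment_log2fc named numeric vector metabolite -> log2 fold
#'   change for the treatment design; `NULL` asks
#'   [generate_treatment_pair()] to designate one strongly increased (+3)
#'   and one strongly decreased (-3) compound.
#' @param celltype_profiles named list cell type -> per-metabolite content
#'   multiplier vector; `NULL` asks [generate_celltype_panel()] to draw
#'   profiles for 8 canonical cell types.
#' @param n_experiments number of experiments the cell-type panel is
#'   spread over (default 5).
#' @param seed integer RNG seed; identical (config, seed) pairs produce
#'   bit-identical output.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_metabolites = 40,
                             n_internal_standards = 2,
                             event_levels = c(100, 500, 1000, 2000, 3000, 4000, 5000),
                             replicates_per_group = 8,
                             class_fractions = c(intracellular = 0.5,
                                                 extracellular = 0.2,
                                                 mixed = 0.3),
                             per_cell_content_range = c(0.5, 20),
                             background_level_range = c(500, 20000),
                             lognormal_sigma_metabolite = 0.25,
                             lognormal_sigma_technical = 0.15,
                             lognormal_sigma_experiment = 0.1,
                             lod_quantile = 0.15,
                             outlier_rate = 0.02,
                             outlier_magnitude = 10,
                             treatment_log2fc = NULL,
                             celltype_profiles = NULL,
                             n_experiments = 5,
                             seed = 1L) {
  if (length(event_levels) < 1 || any(diff(event_levels) <= 0))
    stop("event_levels must be strictly increasing")
  if (any(event_levels <= 0)) stop("event_levels must be positive")
  if (abs(sum(class_fractions) - 1) > 1e-8)
    stop("class_fractions must sum to 1")
  if (any(class_fractions < 0)) stop("class_fractions must be >= 0")
  if (!all(c("intracellular", "extracellular", "mixed") %in% names(class_fractions)))
    stop("class_fractions must be named over intracellular, extracellular, mixed")
  if (lognormal_sigma_metabolite < 0 || lognormal_sigma_technical < 0 ||
      lognormal_sigma_experiment < 0)
    stop("log-normal sigmas must be >= 0")
  if (replicates_per_group < 2) stop("replicates_per_group must be >= 2")
  if (lod_quantile < 0 || lod_quantile >= 1)
    stop("lod_quantile must be in [0, 1)")
  if (outlier_rate < 0 || outlier_rate > 1) stop("outlier_rate must be in [0, 1]")
  if (any(per_cell_content_range <= 0) || any(background_level_range <= 0))
    stop("content and background ranges must be positive")
  structure(list(n_metabolites = n_metabolites,
                 n_internal_standards = n_internal_standards,
                 event_levels = event_levels,
                 replicates_per_group = replicates_per_group,
                 class_fractions = class_fractions,
                 per_cell_content_range = per_cell_content_range,
                 background_level_range = background_level_range,
                 lognormal_sigma_metabolite = lognormal_sigma_metabolite,
                 lognormal_sigma_technical = lognormal_sigma_technical,
                 lognormal_sigma_experiment = lognormal_sigma_experiment,
                 lod_quantile = lod_quantile,
                 outlier_rate = outlier_rate,
                 outlier_magnitude = outlier_magnitude,
                 treatment_log2fc = treatment_log2fc,
                 celltype_profiles = celltype_profiles,
                 n_experiments = n_experiments,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# draw per-metabolite ground truth (classes, contents, backgrounds, LODs).
# Classes are assigned in blocks (intracellular first) so fixtures can refer
# to "the first intracellular metabolite" deterministically.
draw_truth <- function(config) {
  n <- config$n_metabolites
  counts <- floor(config$class_fractions * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(config$class_fractions * n - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  class_label <- rep(c("intracellular", "extracellular", "mixed"),
                     counts[c("intracellular", "extracellular", "mixed")])
  met_ids <- sprintf("met%03d", seq_len(n))
  is_ids <- if (config$n_internal_standards > 0)
    sprintf("IS%d", seq_len(config$n_internal_standards)) else character()
  content <- stats::runif(n, config$per_cell_content_range[1],
                          config$per_cell_content_range[2])
  content[class_label == "extracellular"] <- 0
  background <- stats::runif(n, config$background_level_range[1],
                             config$background_level_range[2])
  background[class_label == "intracellular"] <- 0
  is_amount <- stats::runif(length(is_ids), config$background_level_range[1],
                            config$background_level_range[2])
  per_cell_content <- stats::setNames(c(content, rep(0, length(is_ids))),
                                      c(met_ids, is_ids))
  extracellular_background <- stats::setNames(c(background, rep(0, length(is_ids))),
                                              c(met_ids, is_ids))
  class_label <- stats::setNames(c(class_label, rep("internal_standard", length(is_ids))),
                                 c(met_ids, is_ids))
  # LOD: for purely intracellular metabolites the event-dependent signal
  # traverses the detection limit, so the LOD is the lod_quantile quantile of
  # the noise-free cell-signal series (censors debris and low-event cells).
  # Metabolites with a flat signal component (extracellular background or a
  # spiked standard amount) are observable in blanks by construction, so
  # their LOD is the same fraction *of* that flat level and effectively
  # never censors. Censoring is strict (<), so a noise-free flat signal
  # exactly at its LOD is retained.
  # the intracellular quantile grid starts at 0 so lod_quantile = 0 censors
  # nothing (debris then carries an observed zero rather than a missing)
  lod <- vapply(c(met_ids, is_ids), function(m) {
    switch(class_label[m],
      intracellular = unname(stats::quantile(
        c(0, config$event_levels * per_cell_content[m]), config$lod_quantile,
        type = 7)),
      internal_standard = config$lod_quantile * is_amount[match(m, is_ids)],
      config$lod_quantile * extracellular_background[m])
  }, numeric(1))
  list(per_cell_content = per_cell_content,
       extracellular_background = extracellular_background,
       lod = lod,
       class_label = class_label,
       is_amount = stats::setNames(is_amount, is_ids),
       met_ids = met_ids, is_ids = is_ids)
}

metabolite_meta_from_truth <- function(truth) {
  ids <- c(truth$met_ids, truth$is_ids)
  data.frame(metabolite_id = ids,
             display_name = ids,
             is_internal_standard = ids %in% truth$is_ids,
             standard_kind = ifelse(ids %in% truth$is_ids, "c13", "none"),
             stringsAsFactors = FALSE)
}

# expected (noise-free) intensity for one sample row over all metabolites
expected_row <- function(truth, role, events, content_multiplier = 1,
                         log2fc = NULL) {
  content <- truth$per_cell_content * content_multiplier
  if (!is.null(log2fc)) {
    idx <- match(names(log2fc), names(content))
    content[idx[!is.na(idx)]] <- content[idx[!is.na(idx)]] *
      2^log2fc[!is.na(idx)]
  }
  mu <- if (role == "cell") events * content + truth$extracellular_background
        else truth$extracellular_background
  is_idx <- names(mu) %in% truth$is_ids
  mu[is_idx] <- truth$is_amount[names(mu)[is_idx]]
  mu
}

# apply technical factors, measurement noise, outliers and LOD censoring
finish_table <- function(expected, samples, truth, config) {
  n_s <- nrow(expected)
  n_m <- ncol(expected)
  g <- exp(stats::rnorm(n_s, 0, config$lognormal_sigma_technical))
  eps <- matrix(exp(stats::rnorm(n_s * n_m, 0, config$lognormal_sigma_metabolite)),
                n_s, n_m)
  out_flag <- stats::runif(n_s) < config$outlier_rate
  fac <- g * ifelse(out_flag, config$outlier_magnitude, 1)
  if (!is.null(samples$experiment_factor)) fac <- fac * samples$experiment_factor
  intens <- expected * eps * fac
  lod <- truth$lod[colnames(expected)]
  censored <- sweep(intens, 2, lod, "<")
  intens[censored] <- NA_real_
  samples$experiment_factor <- NULL
  tbl <- peak_table(intens, samples, metabolite_meta_from_truth(truth))
  list(table = tbl, outliers = samples$sample_id[out_flag])
}

new_synthetic_truth <- function(truth, config, outliers, extra = list()) {
  structure(c(list(per_cell_content = truth$per_cell_content,
                   extracellular_background = truth$extracellular_background,
                   lod = truth$lod,
                   class_label = truth$class_label,
                   is_amount = truth$is_amount,
                   injected_outlier_samples = outliers,
                   seed = config$seed),
              extra),
            class = "synthetic_truth")
}

#' Generate a sorted-event dilution series with matched debris samples
#'
#' For every event level the design holds `replicates_per_group` cell
#' samples and the same number of sorted-debris samples. The expected
#' intensity of sample `s` and metabolite `m` is
#' `(events_s * content_m * [s is cell] + background_m) * g_s * eps_sm`
#' with `g_s` the sample's log-normal technical factor and `eps` the
#' per-measurement log-normal noise; internal standards carry a constant
#' per-sample amount instead of the biological term. Values strictly below
#' the metabolite's LOD are recorded as missing.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `table` (a [peak_table()]) and `truth`
#'   (a `synthetic_truth`).
#' @export
#' @examples
#' sim <- generate_sorting_series(synthetic_config(n_metabolites = 10, seed = 7))
#' sim$table
generate_sorting_series <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  truth <- draw_truth(config)
  reps <- config$replicates_per_group
  grid <- expand.grid(replicate = seq_len(reps),
                      role = c("cell", "debris"),
                      event_count = config$event_levels,
                      stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("%s_%d_r%d", grid$role, grid$event_count, grid$replicate),
    role = grid$role,
    event_count = grid$event_count,
    cell_type = "B_spleen",
    group = NA_character_,
    experiment = "exp1",
    replicate = grid$replicate,
    stringsAsFactors = FALSE)
  expected <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i)
    expected_row(truth, samples$role[i], samples$event_count[i])))
  rownames(expected) <- samples$sample_id
  fin <- finish_table(expected, samples, truth, config)
  list(table = fin$table,
       truth = new_synthetic_truth(truth, config, fin$outliers))
}

#' Generate a treated-vs-control pair with matched debris samples
#'
#' Two cell groups (`treated`, `control`) at a single event level (the
#' highest configured level, 5000 by default) plus matched sorted-debris
#' samples. The treated expected content of metabolite `m` is the control
#' content times `2^log2fc_m`. When `config$treatment_log2fc` is `NULL`,
#' the generator designates the first intracellular metabolite as strongly
#' increased (+3) and the second as strongly decreased (-3), so the design
#' always contains one extreme compound on each side.
#'
#' @param config a [synthetic_config()].
#' @return list with `table` and `truth` (truth gains a `treatment_log2fc`
#'   element).
#' @export
generate_treatment_pair <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  truth <- draw_truth(config)
  lfc <- config$treatment_log2fc
  if (is.null(lfc)) {
    intra <- names(truth$class_label)[truth$class_label == "intracellular"]
    if (length(intra) < 2)
      stop("default treatment_log2fc needs >= 2 intracellular metabolites")
    lfc <- stats::setNames(c(3, -3), intra[1:2])
  }
  if (length(lfc) == 0) stop("treatment_log2fc must be non-empty")
  if (is.null(names(lfc)) || any(!nzchar(names(lfc))))
    stop("treatment_log2fc must be a named vector (metabolite -> log2FC)")
  level <- max(config$event_levels)
  reps <- config$replicates_per_group
  samples <- data.frame(
    sample_id = c(sprintf("treated_r%d", seq_len(reps)),
                  sprintf("control_r%d", seq_len(reps)),
                  sprintf("debris_r%d", seq_len(reps))),
    role = rep(c("cell", "cell", "debris"), each = reps),
    event_count = level,
    cell_type = "Jurkat",
    group = rep(c("treated", "control", NA), each = reps),
    experiment = "exp1",
    replicate = rep(seq_len(reps), 3),
    stringsAsFactors = FALSE)
  expected <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    fc <- if (identical(samples$group[i], "treated")) lfc else NULL
    expected_row(truth, samples$role[i], samples$event_count[i], log2fc = fc)
  }))
  rownames(expected) <- samples$sample_id
  fin <- finish_table(expected, samples, truth, config)
  list(table = fin$table,
       truth = new_synthetic_truth(truth, config, fin$outliers,
                                   extra = list(treatment_log2fc = lfc)))
}

#' Generate a multi-cell-type panel at a fixed event count
#'
#' Each cell type contributes `replicates_per_group` cell samples and the
#' same number of matched debris samples at the highest configured event
#' level. A cell type's expected content is the base content times its
#' profile multiplier; debris expectations are cell-type independent up to
#' a small experiment-level technical factor. Cell types are spread
#' round-robin over `n_experiments` experiments. When
#' `config$celltype_profiles` is `NULL`, profiles for 8 canonical sorted
#' populations are drawn as independent log-normal multipliers.
#'
#' @param config a [synthetic_config()] with at least 2 cell types.
#' @return list with `table` and `truth` (truth gains `celltype_profiles`
#'   and `experiment_factors`).
#' @export
generate_celltype_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  truth <- draw_truth(config)
  profiles <- config$celltype_profiles
  n_all <- length(truth$per_cell_content)
  if (is.null(profiles)) {
    types <- c("HSC", "MPP", "B_blood", "T_blood", "macrophage",
               "mast_cell", "B_spleen", "T_spleen")
    profiles <- lapply(stats::setNames(types, types), function(t)
      stats::setNames(exp(stats::rnorm(n_all, 0, 0.5)),
                      names(truth$per_cell_content)))
  } else {
    profiles <- lapply(profiles, function(p) {
      p <- rep_len(as.numeric(p), n_all)
      stats::setNames(p, names(truth$per_cell_content))
    })
  }
  if (length(profiles) < 2) stop("celltype_profiles must contain >= 2 cell types")
  types <- names(profiles)
  exper <- stats::setNames(sprintf("exp%d", ((seq_along(types) - 1) %% config$n_experiments) + 1),
                           types)
  exp_ids <- unique(exper)
  exp_factor <- stats::setNames(exp(stats::rnorm(length(exp_ids), 0,
                                                 config$lognormal_sigma_experiment)),
                                exp_ids)
  level <- max(config$event_levels)
  reps <- config$replicates_per_group
  samples <- do.call(rbind, lapply(types, function(t) data.frame(
    sample_id = sprintf("%s_%s_r%d", t, rep(c("cell", "debris"), each = reps),
                        rep(seq_len(reps), 2)),
    role = rep(c("cell", "debris"), each = reps),
    event_count = level,
    cell_type = t,
    group = NA_character_,
    experiment = unname(exper[t]),
    replicate = rep(seq_len(reps), 2),
    stringsAsFactors = FALSE)))
  samples$experiment_factor <- exp_factor[samples$experiment]
  expected <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i)
    expected_row(truth, samples$role[i], samples$event_count[i],
                 content_multiplier = profiles[[samples$cell_type[i]]])))
  rownames(expected) <- samples$sample_id
  fin <- finish_table(expected, samples, truth, config)
  list(table = fin$table,
       truth = new_synthetic_truth(truth, config, fin$outliers,
                                   extra = list(celltype_profiles = profiles,
                                                experiment_factors = exp_factor)))
}

#' Write a synthetic data set to disk
#'
#' Writes the peak table as tidy CSV plus metadata CSVs (via
#' [write_peak_table()]) and the ground truth as JSON.
#'
#' @param sim a list with `table` and `truth` as returned by the
#'   generators.
#' @param out_dir output directory.
#' @param prefix filename prefix.
#' @return named vector of written paths, invisibly.
#' @export
write_synthetic <- function(sim, out_dir, prefix = "synthetic") {
  paths <- write_peak_table(sim$table, out_dir, prefix = prefix)
  truth_path <- file.path(out_dir, paste0(prefix, "_truth.json"))
  truth <- sim$truth
  truth_list <- lapply(unclass(truth), function(x)
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x)
  jsonlite::write_json(truth_list, truth_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(c(paths, truth = truth_path))
}
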