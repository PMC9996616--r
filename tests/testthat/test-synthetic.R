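test_that("config invariants are enforced", {
  expect_error(synthetic_config(event_levels = c(100, 100, 500)),
               "strictly increasing")
  expect_error(synthetic_config(event_levels = c(500, 100)),
               "strictly increasing")
  expect_error(synthetic_config(class_fractions = c(intracellular = 0.5,
                                                    extracellular = 0.5,
                                                    mixed = 0.5)),
               "sum to 1")
  expect_error(synthetic_config(lognormal_sigma_metabolite = -1), ">= 0")
  expect_error(synthetic_config(replicates_per_group = 1), ">= 2")
  expect_error(synthetic_config(lod_quantile = 1), "lod_quantile")
})

test_that("noise-free intracellular signal is exactly linear in event count", {
  cfg <- quiet_config(n_metabolites = 1, n_internal_standards = 0,
                      class_fractions = c(intracellular = 1, extracellular = 0,
                                          mixed = 0),
                      per_cell_content_range = c(1, 1), seed = 5)
  sim <- generate_sorting_series(cfg)
  v <- sim$table$intensities[, "met001"]
  s <- sim$table$samples
  cells <- s$role == "cell"
  # exact proportionality at sigma = 0
  expect_equal(unname(v[cells]), s$event_count[cells])
  expect_equal(unname(v[cells & s$event_count == 5000][1]),
               50 * unname(v[cells & s$event_count == 100][1]))
  # debris has zero biological content: observed zero when censoring is off
  expect_true(all(v[!cells] == 0))
  # with censoring on, the zero debris signal is below LOD -> missing
  cfg2 <- synthetic_config(n_metabolites = 1, n_internal_standards = 0,
                           class_fractions = c(intracellular = 1,
                                               extracellular = 0, mixed = 0),
                           lognormal_sigma_metabolite = 0,
                           lognormal_sigma_technical = 0,
                           lod_quantile = 0.15, outlier_rate = 0, seed = 5)
  sim2 <- generate_sorting_series(cfg2)
  s2 <- sim2$table$samples
  expect_true(all(is.na(sim2$table$intensities[s2$role == "debris", 1])))
})

test_that("extracellular-only compounds are identical in cell and debris at sigma = 0", {
  cfg <- quiet_config(n_metabolites = 3, n_internal_standards = 0,
                      class_fractions = c(intracellular = 0, extracellular = 1,
                                          mixed = 0), seed = 8)
  sim <- generate_sorting_series(cfg)
  s <- sim$table$samples
  for (k in cfg$event_levels) {
    cells <- sim$table$intensities[s$role == "cell" & s$event_count == k, ]
    debris <- sim$table$intensities[s$role == "debris" & s$event_count == k, ]
    expect_equal(unname(cells), unname(debris))
  }
  expect_false(anyNA(sim$table$intensities))
})

test_that("identical (config, seed) pairs are bit-identical; seeds differ", {
  cfg <- synthetic_config(n_metabolites = 8, seed = 42)
  a <- generate_sorting_series(cfg)
  b <- generate_sorting_series(cfg)
  expect_identical(a$table$intensities, b$table$intensities)
  expect_identical(a$truth$per_cell_content, b$truth$per_cell_content)
  expect_identical(a$truth$injected_outlier_samples,
                   b$truth$injected_outlier_samples)
  c <- generate_sorting_series(synthetic_config(n_metabolites = 8, seed = 43))
  expect_false(identical(a$table$intensities, c$table$intensities))
})

test_that("raising lod_quantile never decreases the number of missing entries", {
  n_missing <- vapply(c(0, 0.1, 0.3, 0.6), function(q) {
    sim <- generate_sorting_series(synthetic_config(n_metabolites = 20,
                                                    lod_quantile = q,
                                                    outlier_rate = 0,
                                                    seed = 9))
    sum(is.na(sim$table$intensities))
  }, numeric(1))
  expect_true(all(diff(n_missing) >= 0))
})

test_that("truth invariants hold on default generation", {
  sim <- generate_sorting_series(synthetic_config(seed = 4))
  tr <- sim$truth
  expect_true(all(tr$per_cell_content[tr$class_label == "extracellular"] == 0))
  expect_true(all(tr$extracellular_background[tr$class_label == "intracellular"] == 0))
  expect_true(all(tr$class_label %in% c("intracellular", "extracellular",
                                        "mixed", "internal_standard")))
  # class fractions realized over the 40 biological metabolites
  expect_equal(unname(table(tr$class_label)[c("intracellular", "extracellular",
                                              "mixed")]),
               c(20, 8, 12), ignore_attr = TRUE)
  # design: 8 cells + 8 debris per level
  s <- sim$table$samples
  expect_equal(nrow(s), 7 * 2 * 8)
  expect_true(all(table(s$event_count, s$role) == 8))
})

test_that("treatment pair: zero fold changes at sigma = 0 give identical groups", {
  cfg <- quiet_config(n_metabolites = 6, seed = 3,
                      treatment_log2fc = c(met001 = 0, met002 = 0))
  sim <- generate_treatment_pair(cfg)
  s <- sim$table$samples
  tre <- sim$table$intensities[which(s$group == "treated"), ]
  ctl <- sim$table$intensities[which(s$group == "control"), ]
  expect_equal(unname(tre), unname(ctl))
})

test_that("treatment pair: injected log2FC is recovered from group means", {
  hits <- 0
  for (sd in 1:20) {
    cfg <- synthetic_config(n_metabolites = 10, seed = sd,
                            outlier_rate = 0,
                            treatment_log2fc = c(met003 = 3))
    sim <- generate_treatment_pair(cfg)
    s <- sim$table$samples
    est <- log2(mean(sim$table$intensities[which(s$group == "treated"), "met003"]) /
                mean(sim$table$intensities[which(s$group == "control"), "met003"]))
    if (abs(est - 3) <= 0.5) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("default treatment config designates one strong up and one strong down", {
  sim <- generate_treatment_pair(synthetic_config(seed = 2))
  lfc <- sim$truth$treatment_log2fc
  expect_equal(sort(unname(lfc)), c(-3, 3))
  expect_true(all(sim$truth$class_label[names(lfc)] == "intracellular"))
  expect_error(generate_treatment_pair(
    synthetic_config(treatment_log2fc = numeric(0))), "non-empty")
  expect_error(generate_treatment_pair(
    synthetic_config(treatment_log2fc = c(1, -1))), "named")
})

test_that("cell-type panel separates orthogonal profiles", {
  profs <- list(typeA = c(10, 10, 0.1, 0.1, 1, 1),
                typeB = c(0.1, 0.1, 10, 10, 1, 1))
  cfg <- synthetic_config(n_metabolites = 6, n_internal_standards = 1,
                          class_fractions = c(intracellular = 1,
                                              extracellular = 0, mixed = 0),
                          lognormal_sigma_metabolite = 0.05,
                          lognormal_sigma_technical = 0.05,
                          lognormal_sigma_experiment = 0,
                          lod_quantile = 0, outlier_rate = 0,
                          celltype_profiles = profs, seed = 6)
  sim <- generate_celltype_panel(cfg)
  s <- sim$table$samples
  lv <- log(sim$table$intensities[, 1:6])
  a <- lv[which(s$role == "cell" & s$cell_type == "typeA"), ]
  b <- lv[which(s$role == "cell" & s$cell_type == "typeB"), ]
  d2 <- function(u, v) sqrt(sum((u - v)^2))
  within <- mean(c(as.matrix(dist(a)), as.matrix(dist(b))))
  between <- mean(outer(seq_len(nrow(a)), seq_len(nrow(b)),
                        Vectorize(function(i, j) d2(a[i, ], b[j, ]))))
  expect_gt(between, within)
})

test_that("cell-type panel: identical profiles at sigma = 0 give identical cells", {
  profs <- list(t1 = rep(1, 4), t2 = rep(1, 4), t3 = rep(1, 4))
  cfg <- quiet_config(n_metabolites = 4, n_internal_standards = 0,
                      class_fractions = c(intracellular = 1, extracellular = 0,
                                          mixed = 0),
                      celltype_profiles = profs, seed = 7)
  sim <- generate_celltype_panel(cfg)
  cells <- sim$table$intensities[sim$table$samples$role == "cell", ]
  expect_true(all(apply(cells, 2, function(x) diff(range(x)) == 0)))
  expect_error(generate_celltype_panel(
    quiet_config(celltype_profiles = list(only = rep(1, 42)))), ">= 2")
})

test_that("debris samples differ across types only by sample-level factors", {
  # metabolite noise off, technical noise on: each debris sample's log vector
  # is the background vector plus one per-sample offset
  cfg <- synthetic_config(n_metabolites = 6, n_internal_standards = 0,
                          class_fractions = c(intracellular = 0,
                                              extracellular = 1, mixed = 0),
                          lognormal_sigma_metabolite = 0,
                          lognormal_sigma_technical = 0.2,
                          lod_quantile = 0, outlier_rate = 0, seed = 10)
  sim <- generate_celltype_panel(cfg)
  deb <- log(sim$table$intensities[sim$table$samples$role == "debris", ])
  centered <- sweep(deb, 2, colMeans(deb))
  # after removing per-metabolite means, rows are constant offsets
  expect_true(all(apply(centered, 1, function(x) diff(range(x))) < 1e-10))
  # and those offsets genuinely vary (technical noise is on)
  expect_gt(stats::sd(rowMeans(centered)), 0)
})

test_that("write_synthetic produces CSVs plus a truth JSON that round-trips", {
  sim <- generate_sorting_series(synthetic_config(n_metabolites = 4, seed = 1))
  dir <- withr::local_tempdir()
  paths <- write_synthetic(sim, dir)
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(unlist(truth$per_cell_content),
               sim$truth$per_cell_content)
  expect_equal(unlist(truth$class_label), sim$truth$class_label)
})
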