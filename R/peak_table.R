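#' Peak table: the pipeline's central data object
#'
#' A `peak_table` bundles a sample x metabolite matrix of MRM peak areas
#' (non-negative, with explicit missingness as `NA`) with per-sample and
#' per-metabolite metadata. Rows of `intensities` correspond to rows of
#' `samples`, columns to rows of `metabolites`.
#'
#' @param intensities numeric matrix, samples in rows and metabolites in
#'   columns; dimnames taken from the metadata if absent. Values must be
#'   `NA` or `>= 0`.
#' @param samples data.frame of sample annotations with at least
#'   `sample_id` and `role` (one of `"cell"`, `"debris"`, `"blank"`,
#'   `"medium"`); optional columns `event_count`, `cell_type`, `group`,
#'   `experiment`, `replicate`.
#' @param metabolites data.frame of metabolite annotations with at least
#'   `metabolite_id`; optional `display_name`, `is_internal_standard`,
#'   `standard_kind` (one of `"c13"`, `"spiked_extracellular"`, `"none"`).
#'
#' @return An object of class `peak_table`.
#' @export
#' @examples
#' m <- matrix(c(10, 20, NA, 5), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("ala", "glu")))
#' pt <- peak_table(m,
#'   samples = data.frame(sample_id = c("s1", "s2"),
#'                        role = c("cell", "debris"),
#'                        event_count = c(5000, 5000)),
#'   metabolites = data.frame(metabolite_id = c("ala", "glu")))
#' dim(pt)
peak_table <- function(intensities, samples, metabolites) {
  stopifnot(is.matrix(intensities))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(samples))
    stop("samples metadata must contain a 'sample_id' column")
  if (!"role" %in% names(samples))
    stop("samples metadata must contain a 'role' column")
  if (!"metabolite_id" %in% names(metabolites))
    stop("metabolite metadata must contain a 'metabolite_id' column")
  if (!"is_internal_standard" %in% names(metabolites))
    metabolites$is_internal_standard <- FALSE
  if (!"standard_kind" %in% names(metabolites))
    metabolites$standard_kind <- ifelse(metabolites$is_internal_standard,
                                        "c13", "none")
  if (!"display_name" %in% names(metabolites))
    metabolites$display_name <- metabolites$metabolite_id
  if (!"event_count" %in% names(samples))
    samples$event_count <- rep(NA_real_, nrow(samples))
  rownames(intensities) <- as.character(samples$sample_id)
  colnames(intensities) <- as.character(metabolites$metabolite_id)
  obj <- structure(list(intensities = intensities,
                        samples = samples,
                        metabolites = metabolites),
                   class = "peak_table")
  validate_peak_table(obj)
}

#' Validate a peak table
#'
#' Checks the invariants of the `peak_table` class: unique sample and
#' metabolite ids, matching dimensions, admitted role vocabulary,
#' non-negative intensities, event counts present for sorted samples, and
#' consistency of the internal-standard flag with `standard_kind`.
#'
#' @param x a `peak_table`.
#' @return `x`, invisibly unchanged, or an error locating the violation.
#' @export
validate_peak_table <- function(x) {
  stopifnot(inherits(x, "peak_table"))
  ids <- x$samples$sample_id
  if (anyDuplicated(ids))
    stop("duplicate sample_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mids <- x$metabolites$metabolite_id
  if (anyDuplicated(mids))
    stop("duplicate metabolite_id: ", paste(unique(mids[duplicated(mids)]), collapse = ", "))
  if (nrow(x$intensities) != length(ids) || ncol(x$intensities) != length(mids))
    stop("intensity matrix is ", nrow(x$intensities), " x ", ncol(x$intensities),
         " but metadata describe ", length(ids), " samples and ",
         length(mids), " metabolites")
  bad_role <- setdiff(unique(x$samples$role), c("cell", "debris", "blank", "medium"))
  if (length(bad_role))
    stop("unknown sample role(s): ", paste(bad_role, collapse = ", "),
         " (admitted: cell, debris, blank, medium)")
  v <- x$intensities
  if (any(v < 0, na.rm = TRUE)) {
    idx <- which(v < 0, arr.ind = TRUE)[1, ]
    stop("negative intensity at sample '", rownames(v)[idx[1]],
         "', metabolite '", colnames(v)[idx[2]], "'")
  }
  sorted <- x$samples$role %in% c("cell", "debris")
  if (any(sorted & !is.finite(as.numeric(x$samples$event_count))))
    stop("cell/debris sample(s) without event_count: ",
         paste(ids[sorted & !is.finite(as.numeric(x$samples$event_count))],
               collapse = ", "))
  sk <- x$metabolites$standard_kind
  if (any(x$metabolites$is_internal_standard != (sk != "none")))
    stop("is_internal_standard must be TRUE exactly when standard_kind != 'none'")
  invisible(x)
}

#' @export
dim.peak_table <- function(x) dim(x$intensities)

#' @export
print.peak_table <- function(x, ...) {
  roles <- table(x$samples$role)
  cat("peak_table: ", nrow(x$intensities), " samples x ",
      ncol(x$intensities), " metabolites\n", sep = "")
  cat("  roles: ", paste(names(roles), roles, sep = "=", collapse = ", "), "\n", sep = "")
  cat("  internal standards: ", sum(x$metabolites$is_internal_standard), "\n", sep = "")
  cat("  missing values: ", sum(is.na(x$intensities)), " (",
      round(100 * mean(is.na(x$intensities)), 1), "%)\n", sep = "")
  invisible(x)
}

#' Subset a peak table
#'
#' `[.peak_table` subsets samples (rows) and metabolites (columns) keeping
#' matrix and metadata aligned.
#'
#' @param x a `peak_table`.
#' @param i,j sample and metabolite indices (numeric, logical or character).
#' @param ... ignored.
#' @export
`[.peak_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$intensities))
  if (missing(j)) j <- seq_len(ncol(x$intensities))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  if (is.character(j)) j <- match(j, x$metabolites$metabolite_id)
  structure(list(intensities = x$intensities[i, j, drop = FALSE],
                 samples = x$samples[i, , drop = FALSE],
                 metabolites = x$metabolites[j, , drop = FALSE]),
            class = "peak_table")
}

#' Read a peak table from CSV files
#'
#' Reads the canonical tidy layout (`sample_id, metabolite, intensity`; one
#' row per observed peak, empty intensity fields and absent pairs become
#' `NA`) or, for convenience, a wide layout whose header row holds
#' metabolite ids and whose first column holds sample ids. Metadata files
#' are plain CSV with the columns documented in [peak_table()].
#'
#' @param intensity_path path to the intensity CSV.
#' @param sample_meta_path path to the sample metadata CSV.
#' @param metabolite_meta_path path to the metabolite metadata CSV.
#' @param format `"tidy"` (default), `"wide"`, or `"auto"` to sniff from
#'   the header.
#' @param sep field delimiter; `","` by default, use `"\t"` for TSV.
#' @return a validated [peak_table()].
#' @export
read_peak_table <- function(intensity_path, sample_meta_path,
                            metabolite_meta_path,
                            format = c("auto", "tidy", "wide"), sep = ",") {
  format <- match.arg(format)
  for (p in c(intensity_path, sample_meta_path, metabolite_meta_path))
    if (!file.exists(p)) stop("file not found: ", p)
  samples <- utils::read.table(sample_meta_path, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE)
  metabolites <- utils::read.table(metabolite_meta_path, header = TRUE, sep = sep,
                                   stringsAsFactors = FALSE)
  if ("is_internal_standard" %in% names(metabolites))
    metabolites$is_internal_standard <- as.logical(metabolites$is_internal_standard)
  header <- strsplit(readLines(intensity_path, n = 1L), sep, fixed = TRUE)[[1]]
  if (format == "auto")
    format <- if (identical(header[1:3], c("sample_id", "metabolite", "intensity")))
      "tidy" else "wide"
  sid <- as.character(samples$sample_id)
  mid <- as.character(metabolites$metabolite_id)
  mat <- matrix(NA_real_, nrow = length(sid), ncol = length(mid),
                dimnames = list(sid, mid))
  if (format == "tidy") {
    tidy <- utils::read.table(intensity_path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE,
                              colClasses = c("character", "character", "numeric"))
    if (!all(c("sample_id", "metabolite", "intensity") %in% names(tidy)))
      stop("tidy intensity file must have columns sample_id, metabolite, intensity")
    unknown_s <- setdiff(unique(tidy$sample_id), sid)
    if (length(unknown_s))
      stop("intensity rows reference unknown sample_id: ",
           paste(unknown_s, collapse = ", "))
    unknown_m <- setdiff(unique(tidy$metabolite), mid)
    if (length(unknown_m))
      stop("intensity rows reference unknown metabolite: ",
           paste(unknown_m, collapse = ", "))
    mat[cbind(match(tidy$sample_id, sid), match(tidy$metabolite, mid))] <-
      tidy$intensity
  } else {
    wide <- utils::read.table(intensity_path, header = TRUE, sep = sep,
                              check.names = FALSE, stringsAsFactors = FALSE)
    wsid <- as.character(wide[[1]])
    if (anyDuplicated(wsid))
      stop("duplicate sample_id in wide intensity file: ",
           paste(unique(wsid[duplicated(wsid)]), collapse = ", "))
    wmat <- as.matrix(wide[, -1, drop = FALSE])
    storage.mode(wmat) <- "double"
    unknown_s <- setdiff(wsid, sid)
    if (length(unknown_s))
      stop("wide intensity file references unknown sample_id: ",
           paste(unknown_s, collapse = ", "))
    unknown_m <- setdiff(colnames(wmat), mid)
    if (length(unknown_m))
      stop("wide intensity file references unknown metabolite: ",
           paste(unknown_m, collapse = ", "))
    mat[wsid, colnames(wmat)] <- wmat
  }
  peak_table(mat, samples, metabolites)
}

#' Write a peak table to CSV files
#'
#' Writes the tidy intensity CSV plus the two metadata CSVs. Missing
#' intensities are written as empty fields (never 0); pairs that are
#' missing are still listed so the tidy file round-trips exactly.
#'
#' @param table a [peak_table()].
#' @param out_dir output directory, created if needed.
#' @param prefix filename prefix, default `"peaktable"`.
#' @return named character vector of the three paths written, invisibly.
#' @export
write_peak_table <- function(table, out_dir, prefix = "peaktable") {
  validate_peak_table(table)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  v <- table$intensities
  tidy <- data.frame(
    sample_id = rep(as.character(table$samples$sample_id), times = ncol(v)),
    metabolite = rep(as.character(table$metabolites$metabolite_id),
                     each = nrow(v)),
    intensity = as.vector(v),
    stringsAsFactors = FALSE)
  paths <- c(
    intensities = file.path(out_dir, paste0(prefix, "_intensities.csv")),
    samples = file.path(out_dir, paste0(prefix, "_samples.csv")),
    metabolites = file.path(out_dir, paste0(prefix, "_metabolites.csv")))
  utils::write.table(tidy, paths["intensities"], sep = ",", na = "",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(table$samples, paths["samples"], sep = ",", na = "",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(table$metabolites, paths["metabolites"], sep = ",",
                     na = "", row.names = FALSE, quote = FALSE)
  invisible(paths)
}

# internal helpers shared across modules ------------------------------------

#' @keywords internal
#' @noRd
pt_roles <- function(table, roles) which(table$samples$role %in% roles)

#' @keywords internal
#' @noRd
pt_standards <- function(table) which(table$metabolites$is_internal_standard)
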