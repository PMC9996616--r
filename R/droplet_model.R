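#' Volume of a sphere, in nanolitres
#'
#' Converts a diameter in micrometres to the enclosed spherical volume in
#' nanolitres (1 nL = 1e6 um^3). Used for the prototypic cell (10 um), the
#' cell-plus-suspension sphere (12 um) and the sorter droplet (124 um).
#'
#' @param diameter_um sphere diameter in micrometres, `>= 0` (vectorised).
#' @return volume in nL.
#' @export
#' @examples
#' sphere_volume(10)   # ~5.24e-4 nL, a prototypic cell
#' sphere_volume(124)  # ~0.998 nL, one sorter droplet
sphere_volume <- function(diameter_um) {
  if (any(diameter_um < 0)) stop("diameter must be >= 0")
  pi * diameter_um^3 / 6 / 1e6
}

#' Physical model of a sorted-droplet sample
#'
#' Bundles the geometric and operational parameters from which the
#' composition of a FACS-sorted sample is estimated: each sorted event is
#' one droplet (default 1 nL) carrying sheath fluid and a small core of
#' cell suspension (default sheath:sample 1000:1); a cell is modelled as a
#' sphere (default 10 um) suspended in buffer; sorted droplets land in a
#' well pre-filled with extraction solution (default 25,000 nL = 25 uL).
#'
#' @param cell_diameter cell diameter, um.
#' @param suspension_sphere_diameter diameter of the cell-plus-buffer
#'   sphere, um (used only by the `"shell"` buffer convention).
#' @param droplet_diameter droplet diameter, um (consistency reference for
#'   `droplet_volume`).
#' @param droplet_volume droplet volume, nL.
#' @param sheath_to_sample_ratio sheath:sample volume ratio inside a
#'   droplet, `>= 1`.
#' @param n_events number of sorted events (droplets), `>= 0`.
#' @param extraction_volume extraction solution per well, nL.
#' @param rounding_decimals decimal places (nL) of the printed-precision
#'   layer for per-droplet volumes.
#' @param buffer_convention how the suspension-buffer per-droplet volume is
#'   derived: `"sample-fraction"` (sample core minus cell volume; matches
#'   the printed composition table) or `"shell"` (spherical shell between
#'   `suspension_sphere_diameter` and `cell_diameter`).
#' @return an object of class `droplet_model`.
#' @export
droplet_model <- function(cell_diameter = 10,
                          suspension_sphere_diameter = 12,
                          droplet_diameter = 124,
                          droplet_volume = 1,
                          sheath_to_sample_ratio = 1000,
                          n_events = 5000,
                          extraction_volume = 25000,
                          rounding_decimals = 4,
                          buffer_convention = c("sample-fraction", "shell")) {
  buffer_convention <- match.arg(buffer_convention)
  if (any(c(cell_diameter, suspension_sphere_diameter, droplet_diameter,
            droplet_volume, extraction_volume) <= 0))
    stop("lengths and volumes must be > 0")
  if (sheath_to_sample_ratio < 1) stop("sheath_to_sample_ratio must be >= 1")
  if (n_events < 0) stop("n_events must be >= 0")
  structure(list(cell_diameter = cell_diameter,
                 suspension_sphere_diameter = suspension_sphere_diameter,
                 droplet_diameter = droplet_diameter,
                 droplet_volume = droplet_volume,
                 sheath_to_sample_ratio = sheath_to_sample_ratio,
                 n_events = n_events,
                 extraction_volume = extraction_volume,
                 rounding_decimals = rounding_decimals,
                 buffer_convention = buffer_convention),
            class = "droplet_model")
}

#' Estimated composition of a sorted sample
#'
#' Splits each droplet into cell, suspension buffer and sheath fluid, and
#' the final well into sorted droplets plus extraction solution. Per-droplet
#' volumes are reported raw and at printed precision
#' (`rounding_decimals` decimals); printed in-sample values are the rounded
#' per-droplet values times `n_events`, so the report reproduces the
#' composition table a bench scientist would write down.
#'
#' @param model a [droplet_model()].
#' @return an object of class `composition_table`: a data.frame with one
#'   row per component (`cells`, `cell_suspension_buffer`, `sheath_fluid`,
#'   `total_droplet`, `extraction_solution`, `total_sample`) and columns
#'   `diameter_um`, `per_droplet_nl`, `per_droplet_printed`,
#'   `in_sample_nl`, `in_sample_printed`; attribute `cell_volume_fraction`
#'   holds the raw cells / total-sample volume ratio.
#' @export
#' @examples
#' ct <- compose_sample(droplet_model(n_events = 5000))
#' ct["sheath_fluid", "in_sample_printed"]   # 4995
#' attr(ct, "cell_volume_fraction") < 1e-4   # cells < 0.01% of the sample
compose_sample <- function(model) {
  stopifnot(inherits(model, "droplet_model"))
  sample_core <- model$droplet_volume / (model$sheath_to_sample_ratio + 1)
  cell <- sphere_volume(model$cell_diameter)
  if (cell > sample_core)
    stop("cell volume (", signif(cell, 3), " nL) exceeds the droplet's sample core (",
         signif(sample_core, 3), " nL); check diameters and sheath ratio")
  buffer <- switch(model$buffer_convention,
    "sample-fraction" = sample_core - cell,
    "shell" = sphere_volume(model$suspension_sphere_diameter) - cell)
  sheath <- model$droplet_volume - sample_core
  per_droplet <- c(cells = cell,
                   cell_suspension_buffer = buffer,
                   sheath_fluid = sheath,
                   total_droplet = model$droplet_volume,
                   extraction_solution = NA_real_,
                   total_sample = NA_real_)
  n <- model$n_events
  in_sample <- c(per_droplet[1:4] * n,
                 extraction_solution = model$extraction_volume,
                 total_sample = n * model$droplet_volume + model$extraction_volume)
  printed_pd <- round(per_droplet, model$rounding_decimals)
  printed_is <- c(printed_pd[1:4] * n, in_sample[5:6])
  out <- data.frame(
    component = names(per_droplet),
    diameter_um = c(model$cell_diameter, model$suspension_sphere_diameter,
                    model$droplet_diameter, model$droplet_diameter, NA, NA),
    per_droplet_nl = unname(per_droplet),
    per_droplet_printed = unname(printed_pd),
    in_sample_nl = unname(in_sample),
    in_sample_printed = unname(printed_is),
    row.names = names(per_droplet),
    stringsAsFactors = FALSE)
  attr(out, "cell_volume_fraction") <-
    unname(in_sample["cells"] / in_sample["total_sample"])
  class(out) <- c("composition_table", "data.frame")
  out
}

#' @export
print.composition_table <- function(x, ...) {
  cat("Estimated sample composition (volumes in nL)\n")
  print.data.frame(x, row.names = FALSE, digits = 7)
  cat(sprintf("cell volume fraction: %.3g%% of total sample\n",
              100 * attr(x, "cell_volume_fraction")))
  invisible(x)
}

#' Make-up volume keeping solvent composition constant across event counts
#'
#' When fewer events than the reference number are sorted into the same
#' extraction volume, the missing droplet volume is replaced by pipetting
#' sheath fluid (5 g/L NaCl in water), keeping the organic:aqueous ratio
#' identical in every well.
#'
#' @param n_events events sorted into the well (vectorised),
#'   `0 <= n_events <= reference_events`.
#' @param reference_events event count the extraction volume is designed
#'   for (default 5000).
#' @param droplet_volume droplet volume in nL (default 1).
#' @param extraction_volume extraction solution per well in nL (default
#'   25,000).
#' @return data.frame with columns `n_events`, `extraction_uL`,
#'   `makeup_uL` (sheath fluid to add), `total_uL` (pipetted volume:
#'   extraction + make-up) and `final_uL` (pipetted + sorted droplets;
#'   constant across the series).
#' @export
#' @examples
#' makeup_volume(c(5000, 1000, 100))
makeup_volume <- function(n_events, reference_events = 5000,
                          droplet_volume = 1, extraction_volume = 25000) {
  if (any(n_events < 0)) stop("n_events must be >= 0")
  if (any(n_events > reference_events))
    stop("n_events exceeds reference_events (", reference_events,
         "); the scheme only tops up, never removes volume")
  makeup_nl <- (reference_events - n_events) * droplet_volume
  data.frame(n_events = n_events,
             extraction_uL = extraction_volume / 1000,
             makeup_uL = makeup_nl / 1000,
             total_uL = (extraction_volume + makeup_nl) / 1000,
             final_uL = (extraction_volume + makeup_nl +
                           n_events * droplet_volume) / 1000)
}
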