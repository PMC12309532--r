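#' Equivalent circular diameter from cross-sectional area
#'
#' `d = 2 * sqrt(area / pi)`: the diameter of the circle with the same
#' area. The standard size summary for near-circular adipocyte
#' cross-sections; under the default area gates of 315 and 40000 um^2 all
#' reported diameters fall in roughly 20-225 um.
#'
#' @param area Cross-sectional area(s) in um^2; strictly positive.
#' @return Diameter(s) in um.
#' @examples
#' area_to_diameter(315)    # ~20 um
#' area_to_diameter(40000)  # ~225 um
#' @export
area_to_diameter <- function(area) {
  if (any(!is.finite(area)) || any(area <= 0))
    stop("`area` must be strictly positive and finite")
  2 * sqrt(area / pi)
}

#' Cell-count quality-control gate
#'
#' Classifies a sample by how many cells were retained: at least 200 cells
#' is `"ok"`; 100-199 is `"inspect"` (results kept but flagged for visual
#' review of the slide, with manual re-thresholding available); fewer than
#' 100 is `"excluded"`, as too few cells give an unreliable mean size.
#'
#' @param n_detected Number of retained cells (>= 0); vectorised.
#' @return Character vector: `"ok"`, `"inspect"` or `"excluded"`.
#' @examples
#' qc_gate(c(95, 150, 500))
#' @export
qc_gate <- function(n_detected) {
  if (any(n_detected < 0)) stop("`n_detected` must be >= 0")
  ifelse(n_detected >= 200, "ok",
         ifelse(n_detected >= 100, "inspect", "excluded"))
}

#' Summarise retained particles as a per-sample measurement
#'
#' Converts each retained particle's area to an equivalent circular
#' diameter and aggregates: mean, sample standard deviation (n - 1
#' denominator) and the cell-count QC status. A sample with no retained
#' particles gets `qc_status = "excluded"` and `NA` summaries.
#'
#' @param sample_id Sample identifier.
#' @param depot Depot label, e.g. `"omental"`, `"subcutaneous"` or
#'   `"unspecified"`.
#' @param particles Filtered particle table (with `retained` column) from
#'   [filter_particles()], or a table of already-retained particles.
#' @param threshold_used Intensity level used for segmentation (recorded
#'   for provenance).
#' @param rethresholded Whether a manual threshold replaced the automatic
#'   one.
#' @return An object of class `sample_measurement`: list with `sample_id`,
#'   `depot`, `diameters` (um), `n_cells`, `mean_diameter`, `sd_diameter`,
#'   `qc_status`, `threshold_used`, `rethresholded`.
#' @export
summarize_sample <- function(sample_id, depot = "unspecified", particles,
                             threshold_used = NA_integer_,
                             rethresholded = FALSE) {
  if (!is.null(particles$retained)) particles <- particles[particles$retained, ]
  d <- if (nrow(particles)) area_to_diameter(particles$area_um2) else numeric()
  n <- length(d)
  structure(
    list(sample_id = as.character(sample_id),
         depot = as.character(depot),
         diameters = d,
         n_cells = n,
         mean_diameter = if (n > 0) mean(d) else NA_real_,
         sd_diameter = if (n > 1) sd(d) else NA_real_,
         qc_status = qc_gate(n),
         threshold_used = threshold_used,
         rethresholded = isTRUE(rethresholded)),
    class = "sample_measurement"
  )
}

#' @export
print.sample_measurement <- function(x, ...) {
  cat(sprintf(
    "<sample_measurement> %s (%s): %d cells, mean %.1f um, SD %.1f um, QC %s%s\n",
    x$sample_id, x$depot, x$n_cells,
    ifelse(is.na(x$mean_diameter), NA, x$mean_diameter),
    ifelse(is.na(x$sd_diameter), NA, x$sd_diameter),
    x$qc_status, if (x$rethresholded) " (rethresholded)" else ""))
  invisible(x)
}

#' Run the full sizing pipeline on one calibrated image
#'
#' Segmentation, particle analysis, gating and per-sample summary in one
#' call.
#'
#' @param image A [calibrated_image()].
#' @param sample_id Sample identifier (defaults to the image's source id).
#' @param depot Depot label.
#' @param params A [seg_params()].
#' @param filter A [particle_filter()].
#' @param include_holes Count interior holes toward particle area.
#' @return List with `measurement` (a [summarize_sample()] result),
#'   `particles` (full gated table) and `mask` (the [binary_mask()]).
#' @export
analyze_slide <- function(image, sample_id = image$source_id,
                          depot = "unspecified", params = seg_params(),
                          filter = particle_filter(),
                          include_holes = FALSE) {
  mask <- segment(image, params)
  particles <- measure_particles(mask, include_holes = include_holes)
  particles <- filter_particles(particles, filter)
  measurement <- summarize_sample(
    sample_id, depot, particles,
    threshold_used = mask$threshold_used,
    rethresholded = !is.null(params$manual_threshold_override))
  list(measurement = measurement, particles = particles, mask = mask)
}

#' Re-analyse a slide with a manually chosen threshold
#'
#' The manual-recovery hook of the QC workflow: when automatic thresholding
#' under-detects cells (for example on faintly stained slides), the slide
#' is re-run with a hand-picked level and flagged as rethresholded.
#'
#' @param image A [calibrated_image()].
#' @param manual_level Intensity level in `[0, 255]`.
#' @param sample_id,depot,params,filter,include_holes As in
#'   [analyze_slide()].
#' @return As [analyze_slide()]; the measurement carries
#'   `rethresholded = TRUE`.
#' @export
rethreshold_sample <- function(image, manual_level,
                               sample_id = image$source_id,
                               depot = "unspecified", params = seg_params(),
                               filter = particle_filter(),
                               include_holes = FALSE) {
  if (manual_level < 0 || manual_level > 255)
    stop("`manual_level` must lie in [0, 255]")
  params$manual_threshold_override <- manual_level
  analyze_slide(image, sample_id = sample_id, depot = depot, params = params,
                filter = filter, include_holes = include_holes)
}

#' Consolidate per-sample measurements into tidy tables
#'
#' One row per sample, whatever its QC fate, so a batch is a single table
#' rather than one spreadsheet per image. Excluded samples keep their row
#' but carry `NA` summary statistics and contribute no diameters to the
#' long-format companion table.
#'
#' @param measurements List of [summarize_sample()] results.
#' @return List with `summary` (columns `sample_id`, `depot`, `n_cells`,
#'   `mean_diameter_um`, `sd_diameter_um`, `qc_status`, `threshold_used`,
#'   `rethresholded`) and `diameters` (long format: `sample_id`,
#'   `diameter_um`).
#' @export
consolidate <- function(measurements) {
  if (length(measurements) == 0L) {
    return(list(
      summary = data.frame(
        sample_id = character(), depot = character(), n_cells = integer(),
        mean_diameter_um = numeric(), sd_diameter_um = numeric(),
        qc_status = character(), threshold_used = integer(),
        rethresholded = logical()),
      diameters = data.frame(sample_id = character(), diameter_um = numeric())
    ))
  }
  stopifnot(all(vapply(measurements, inherits, TRUE, "sample_measurement")))
  ids <- vapply(measurements, `[[`, "", "sample_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate sample_id: ", paste(dup, collapse = ", "))
  excluded <- vapply(measurements, `[[`, "", "qc_status") == "excluded"
  summary <- data.frame(
    sample_id = ids,
    depot = vapply(measurements, `[[`, "", "depot"),
    n_cells = vapply(measurements, `[[`, 0L, "n_cells"),
    mean_diameter_um = ifelse(
      excluded, NA_real_,
      vapply(measurements, `[[`, 0, "mean_diameter")),
    sd_diameter_um = ifelse(
      excluded, NA_real_,
      vapply(measurements, function(m) as.numeric(m$sd_diameter), 0)),
    qc_status = vapply(measurements, `[[`, "", "qc_status"),
    threshold_used = vapply(
      measurements, function(m) as.integer(m$threshold_used), 0L),
    rethresholded = vapply(measurements, `[[`, FALSE, "rethresholded")
  )
  keep <- measurements[!excluded]
  diameters <- if (length(keep)) {
    data.frame(
      sample_id = rep(vapply(keep, `[[`, "", "sample_id"),
                      vapply(keep, `[[`, 0L, "n_cells")),
      diameter_um = unlist(lapply(keep, `[[`, "diameters"), use.names = FALSE)
    )
  } else {
    data.frame(sample_id = character(), diameter_um = numeric())
  }
  list(summary = summary, diameters = diameters)
}
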