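#' Size every slide in a directory and write consolidated outputs
#'
#' Runs [analyze_slide()] on each TIFF in `input_dir` and writes a single
#' consolidated `summary.csv` (one row per sample, excluded samples with
#' blank summaries), a long-format `diameters.csv`, and one particle table
#' per slide under `particles/`. Sample ids are file names without
#' extension.
#'
#' @param input_dir Directory containing `.tif`/`.tiff` slides.
#' @param out_dir Output directory (created if missing).
#' @param pixel_size Optional micrometre-per-pixel override applied to
#'   every slide lacking (or overriding) TIFF calibration.
#' @param depot Depot label applied to all samples.
#' @param params A [seg_params()].
#' @param filter A [particle_filter()].
#' @param include_holes Count interior holes toward particle area.
#' @return The [consolidate()] result, invisibly.
#' @export
run_batch <- function(input_dir, out_dir, pixel_size = NULL,
                      depot = "unspecified", params = seg_params(),
                      filter = particle_filter(), include_holes = FALSE) {
  files <- list.files(input_dir, pattern = "\\.tiff?$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L) stop("no TIFF files found in ", input_dir)
  dir.create(file.path(out_dir, "particles"), recursive = TRUE,
             showWarnings = FALSE)
  measurements <- vector("list", length(files))
  for (i in seq_along(files)) {
    id <- sub("\\.[^.]+$", "", basename(files[i]))
    img <- load_slide(files[i], pixel_size_override = pixel_size)
    res <- analyze_slide(img, sample_id = id, depot = depot, params = params,
                         filter = filter, include_holes = include_holes)
    measurements[[i]] <- res$measurement
    write_particle_csv(res$particles,
                       file.path(out_dir, "particles", paste0(id, ".csv")))
  }
  out <- consolidate(measurements)
  write.csv(out$summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  write.csv(out$diameters, file.path(out_dir, "diameters.csv"),
            row.names = FALSE)
  invisible(out)
}
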