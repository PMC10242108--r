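#' Analysis run configuration
#'
#' Collects every tunable parameter of the pipeline. The configuration is
#' global for a run — thresholds are defined once for all images, never
#' tuned per field — and is serialized verbatim into the run manifest.
#'
#' @param th1,th2 Zone thresholds (see [zone_thresholds()]).
#' @param ball_radius Rolling-ball radius in px (see
#'   [subtract_background()]).
#' @param light_background Brightfield flag.
#' @param min_area,max_area Nucleus size bounds in px^2.
#' @param dab_fraction_threshold Per-nucleus DAB positivity fraction.
#' @param watershed_tolerance Watershed basin depth.
#' @param denominator Denominator convention for percent positive
#'   (`"zone"` or `"roi"`).
#' @param stain_matrix A [stain_matrix()] or a path readable by
#'   [read_stain_matrix()].
#' @param seed Integer seed recorded in the manifest.
#' @return A `run_config` object.
#' @export
run_config <- function(th1 = 100, th2 = 190, ball_radius = 50,
                       light_background = TRUE, min_area = 30,
                       max_area = 5000, dab_fraction_threshold = 0.5,
                       watershed_tolerance = 1,
                       denominator = c("zone", "roi"),
                       stain_matrix = NULL, seed = 1) {
  denominator <- match.arg(denominator)
  th <- zone_thresholds(th1, th2)
  if (ball_radius < 1) stop("`ball_radius` must be >= 1")
  if (!(min_area > 0 && min_area < max_area))
    stop("need 0 < min_area < max_area")
  if (dab_fraction_threshold < 0 || dab_fraction_threshold > 1)
    stop("`dab_fraction_threshold` must lie in [0, 1]")
  sm <- if (is.null(stain_matrix)) stain_matrix()
        else if (is.character(stain_matrix)) read_stain_matrix(stain_matrix)
        else stain_matrix
  structure(
    list(th1 = th1, th2 = th2, ball_radius = ball_radius,
         light_background = light_background, min_area = min_area,
         max_area = max_area,
         dab_fraction_threshold = dab_fraction_threshold,
         watershed_tolerance = watershed_tolerance,
         denominator = denominator, stain_matrix = sm,
         seed = as.integer(seed)),
    class = "run_config")
}

config_manifest <- function(config, extra = list()) {
  m <- unclass(config)
  m$stain_matrix <- list(
    stains = rownames(config$stain_matrix),
    vectors = apply(unclass(config$stain_matrix), 1, c, simplify = FALSE))
  c(m, list(package_version = as.character(packageVersion("andkit"))), extra)
}

#' Analyze a single field of view
#'
#' One pass of the field pipeline: illumination correction, colour
#' deconvolution, zone partition, nuclear detection/classification and
#' region statistics.
#'
#' @param field An [rgb_field()].
#' @param config A [run_config()].
#' @return List with `quantification` (an `roi_quantification`), the
#'   `nuclei` record table, the `channels` and the zone `masks`.
#' @export
analyze_field <- function(field, config = run_config()) {
  corrected <- subtract_background(field, config$ball_radius,
                                   config$light_background)
  channels <- deconvolve(corrected, config$stain_matrix)
  masks <- assign_zones(channels$fastred,
                        zone_thresholds(config$th1, config$th2))
  det <- detect_nuclei(channels, masks,
                       min_area = config$min_area,
                       max_area = config$max_area,
                       dab_fraction_threshold = config$dab_fraction_threshold,
                       watershed_tolerance = config$watershed_tolerance)
  quant <- quantify_roi(det$nuclei, masks, roi_id = field$roi_id,
                        denominator = config$denominator)
  list(quantification = quant, nuclei = det$nuclei,
       channels = channels, masks = masks)
}

#' Run the full analysis pipeline over a batch of fields
#'
#' For each input image: preprocess, deconvolve, partition into zones,
#' detect and classify nuclei, quantify; then aggregate per sample.
#' Unreadable or invalid images are skipped and logged as drop-outs with
#' their reason (mirroring drop-out of folded tissue fields). Outputs are
#' deterministic given config + inputs; rerunning writes byte-identical
#' CSVs.
#'
#' @param inputs Character vector of image paths, or a list of
#'   [rgb_field()] objects.
#' @param config A [run_config()].
#' @param output_dir Optional directory; when given, writes
#'   `nuclei_<roi>.csv` per field, `roi_summary.csv`,
#'   `sample_summary.csv` and `manifest.json`.
#' @param sample_id Sample identifier for the aggregate.
#' @return List with `summary` (a `sample_summary`), `rois` (list of
#'   `roi_quantification`), `nuclei` (named list of record tables),
#'   `roi_table` and `dropped`.
#' @export
run_pipeline <- function(inputs, config = run_config(), output_dir = NULL,
                         sample_id = "sample") {
  if (length(inputs) == 0L) stop("empty input set")
  rois <- list()
  nuclei <- list()
  dropped <- character(0)
  for (i in seq_along(inputs)) {
    inp <- if (is.list(inputs)) inputs[[i]] else inputs[[i]]
    id <- if (inherits(inp, "rgb_field")) inp$roi_id
          else tools::file_path_sans_ext(basename(inp))
    res <- tryCatch({
      field <- if (inherits(inp, "rgb_field")) inp else read_rgb_field(inp)
      analyze_field(field, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      dropped[id] <- conditionMessage(res)
      message("dropping field '", id, "': ", conditionMessage(res))
      next
    }
    rois[[id]] <- res$quantification
    nuclei[[id]] <- res$nuclei
  }
  if (length(rois) == 0L)
    stop("no analyzable fields (", length(dropped), " dropped)")
  summary <- aggregate_sample(rois, sample_id = sample_id, dropped = dropped)
  roi_table <- roi_zone_table(rois)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(nuclei))
      write.csv(format_num_df(nuclei[[id]]),
                file.path(output_dir, paste0("nuclei_", id, ".csv")),
                row.names = FALSE)
    write.csv(format_num_df(roi_table),
              file.path(output_dir, "roi_summary.csv"), row.names = FALSE)
    write.csv(format_num_df(sample_summary_table(summary)),
              file.path(output_dir, "sample_summary.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      config_manifest(config, list(
        sample_id = sample_id, n_inputs = length(inputs),
        n_analyzed = length(rois), dropped = as.list(dropped))),
      file.path(output_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(summary = summary, rois = rois, nuclei = nuclei,
       roi_table = roi_table, dropped = dropped)
}

# fixed-format numbers so CSV output is byte-stable across platforms
format_num_df <- function(df) {
  for (nm in names(df))
    if (is.numeric(df[[nm]])) df[[nm]] <- sprintf("%.6g", df[[nm]])
  df
}

sample_summary_table <- function(s) {
  data.frame(sample_id = s$sample_id, n_rois = s$n_rois,
             mean_total_nuclei = s$mean_total_nuclei,
             sd_total_nuclei = s$sd_total_nuclei,
             zone = zone_levels,
             pooled_pixel_fraction = as.numeric(s$pooled_pixel_fractions),
             mean_pct_mir_positive = as.numeric(s$mean_pct_mir_positive),
             n_rois_with_zone_nuclei =
               as.numeric(s$n_rois_with_zone_nuclei),
             n_dropped = length(s$dropped))
}
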