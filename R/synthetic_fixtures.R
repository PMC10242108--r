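#' Specification of a synthetic dual-stained scene
#'
#' Describes a renderable field of view: zones of graded FastRed (SSTR2)
#' intensity laid out as vertical bands, nuclei stamped as discs carrying
#' FastBlue counterstain and (for marker-positive nuclei) DAB, composed
#' through the same Beer-Lambert stain-mixing model the unmixing stage
#' inverts, plus planar shading and Gaussian sensor noise.
#'
#' The default zone layout reproduces the reference tissue composition —
#' 27% frankly positive (dark-red), 22% heterogeneous (light-pink), 51%
#' negative (white) — with band intensities 60 / 150 / 255 that fall
#' inside the default threshold intervals (`Th1 = 100`, `Th2 = 190`).
#'
#' @param width_px,height_px Image size in pixels.
#' @param n_nuclei Number of nuclei to place.
#' @param radius_range Numeric `(min, max)` nucleus radius in px (min >= 2).
#' @param overlap_fraction Expected fraction of nuclei placed touching an
#'   existing nucleus (0-1).
#' @param dab_positive_fraction Fraction of nuclei carrying the DAB
#'   marker (0-1).
#' @param zone_layout `data.frame` with columns `zone` (one of
#'   `dark_red`, `light_pink`, `white`), `red_intensity` (8-bit target
#'   intensity of the FastRed channel) and `area_fraction` (summing to 1).
#' @param noise_sd Gaussian noise SD in 8-bit units per channel.
#' @param illumination_gradient Maximum planar shading in 8-bit units
#'   (darkening ramp, the target of the rolling-ball stage).
#' @param fb_concentration,dab_concentration Stain concentrations stamped
#'   into nuclei (optical-density units).
#' @param seed Integer RNG seed; identical specs render bit-identically.
#' @param thresholds [zone_thresholds()] the layout must respect.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(width_px = 256, height_px = 256, n_nuclei = 100,
                       radius_range = c(5, 9), overlap_fraction = 0,
                       dab_positive_fraction = 0.5,
                       zone_layout = default_zone_layout(),
                       noise_sd = 3, illumination_gradient = 20,
                       fb_concentration = 0.85, dab_concentration = 0.9,
                       seed = 1, thresholds = zone_thresholds()) {
  if (abs(sum(zone_layout$area_fraction) - 1) > 1e-9)
    stop("zone area fractions must sum to 1")
  if (radius_range[1] < 2) stop("minimum nucleus radius must be >= 2 px")
  if (n_nuclei < 0) stop("`n_nuclei` must be >= 0")
  if (!all(zone_layout$zone %in% zone_levels))
    stop("unknown zone labels in layout")
  bad_dark <- zone_layout$zone == "dark_red" &
    zone_layout$red_intensity >= thresholds$th1
  bad_pink <- zone_layout$zone == "light_pink" &
    (zone_layout$red_intensity < thresholds$th1 |
     zone_layout$red_intensity >= thresholds$th2)
  bad_white <- zone_layout$zone == "white" &
    zone_layout$red_intensity < thresholds$th2
  if (any(bad_dark | bad_pink | bad_white))
    stop("zone target intensities fall outside the threshold intervals ",
         "they are meant to exercise")
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         n_nuclei = as.integer(n_nuclei), radius_range = radius_range,
         overlap_fraction = overlap_fraction,
         dab_positive_fraction = dab_positive_fraction,
         zone_layout = zone_layout, noise_sd = noise_sd,
         illumination_gradient = illumination_gradient,
         fb_concentration = fb_concentration,
         dab_concentration = dab_concentration,
         seed = as.integer(seed), thresholds = thresholds),
    class = "scene_spec")
}

#' @rdname scene_spec
#' @export
default_zone_layout <- function() {
  data.frame(zone = c("dark_red", "light_pink", "white"),
             red_intensity = c(60, 150, 255),
             area_fraction = c(0.27, 0.22, 0.51))
}

#' Render a synthetic scene with ground truth
#'
#' Renders the scene described by a [scene_spec()]: each pixel gets the
#' FastRed concentration of its zone band, nuclei are stamped as discs of
#' FastBlue (all) and DAB (marker-positive only) concentration, RGB is
#' composed via `I_c = 255 * 10^(-sum_s A_cs conc_s)` with the shared
#' stain matrix, and planar shading plus Gaussian noise are applied in
#' 8-bit space with clipping. Nucleus placement is rejection sampling
#' capped at `100 * n_nuclei` attempts; if fewer nuclei fit, the achieved
#' count is reported in the ground truth and a warning is raised.
#'
#' @param spec A [scene_spec()].
#' @param matrix [stain_matrix()] used for composition.
#' @return List with `field` (an [rgb_field()]) and `truth`: nucleus
#'   table (`row`, `col`, `radius`, `marker_class`, `zone`),
#'   `zone_mask_truth` (integer matrix, 0 = white, 1 = light_pink,
#'   2 = dark_red), `pixel_fraction_truth` (named, sums to 1) and
#'   `n_placed`.
#' @export
render_scene <- function(spec, matrix = stain_matrix()) {
  stopifnot(inherits(spec, "scene_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)
  H <- spec$height_px; W <- spec$width_px
  zl <- spec$zone_layout

  # vertical bands: exact area fractions up to one column of rounding
  bounds <- round(cumsum(zl$area_fraction) * W)
  bounds[length(bounds)] <- W
  starts <- c(0L, bounds[-length(bounds)]) + 1L
  zone_code <- c(white = 0L, light_pink = 1L, dark_red = 2L)
  ztruth <- matrix(0L, H, W)
  red_conc <- matrix(0, H, W)
  for (i in seq_len(nrow(zl))) {
    if (starts[i] > bounds[i]) next
    cols <- starts[i]:bounds[i]
    ztruth[, cols] <- zone_code[[zl$zone[i]]]
    red_conc[, cols] <- -log10(max(zl$red_intensity[i], 1) / 255)
  }
  frac_truth <- vapply(zone_levels, function(z)
    mean(ztruth == zone_code[[z]]), numeric(1))

  placed <- place_nuclei(spec, H, W)
  n <- nrow(placed)
  n_dab <- round(spec$dab_positive_fraction * n)
  marker <- rep("FB_only", n)
  if (n_dab > 0) marker[sample.int(n, n_dab)] <- "DAB_pos"

  fb_conc <- matrix(0, H, W)
  dab_conc <- matrix(0, H, W)
  if (n > 0) {
    for (i in seq_len(n)) {
      d <- disc_index(placed$row[i], placed$col[i], placed$radius[i], H, W)
      fb_conc[d] <- spec$fb_concentration
      if (marker[i] == "DAB_pos") dab_conc[d] <- spec$dab_concentration
    }
  }

  img <- compose_rgb(list(red_conc, fb_conc, dab_conc), matrix,
                     quantize = FALSE)
  if (spec$illumination_gradient > 0) {
    ramp <- matrix(rep((seq_len(W) - 1) / max(W - 1, 1), each = H), H, W)
    img <- img - c(ramp) * spec$illumination_gradient
  }
  if (spec$noise_sd > 0)
    img <- img + rnorm(length(img), sd = spec$noise_sd)
  img <- clip8(round_half_up(img))

  zone_at_centre <- zone_levels[match(ztruth[cbind(placed$row, placed$col)],
                                      c(2L, 1L, 0L))]
  truth <- list(
    nucleus_table = data.frame(row = placed$row, col = placed$col,
                               radius = placed$radius,
                               marker_class = marker,
                               zone = zone_at_centre),
    zone_mask_truth = ztruth,
    pixel_fraction_truth = frac_truth,
    n_placed = n)
  list(field = rgb_field(img, sample_id = "synthetic",
                         roi_id = sprintf("scene_seed%d", spec$seed)),
       truth = truth)
}

disc_index <- function(r0, c0, radius, H, W) {
  rr <- max(1L, floor(r0 - radius)):min(H, ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(W, ceiling(c0 + radius))
  grid <- expand.grid(row = rr, col = cc)
  keep <- (grid$row - r0)^2 + (grid$col - c0)^2 <= radius^2
  cbind(grid$row[keep], grid$col[keep])
}

place_nuclei <- function(spec, H, W) {
  n <- spec$n_nuclei
  out <- data.frame(row = numeric(0), col = numeric(0), radius = numeric(0))
  if (n == 0L) return(out)
  n_touch <- round(spec$overlap_fraction * n)
  rows <- cols <- rads <- numeric(0)
  attempts <- 0L
  cap <- 100L * n
  want_sep <- function(r0, c0, rad, margin) {
    if (length(rows) == 0L) return(TRUE)
    all((rows - r0)^2 + (cols - c0)^2 >= (rads + rad + margin)^2)
  }
  # isolated nuclei first (centre separation > sum of radii + 2 px)
  while (length(rows) < n - n_touch && attempts < cap) {
    attempts <- attempts + 1L
    rad <- runif(1, spec$radius_range[1], spec$radius_range[2])
    r0 <- round(runif(1, rad + 2, H - rad - 1))
    c0 <- round(runif(1, rad + 2, W - rad - 1))
    if (want_sep(r0, c0, rad, 2)) {
      rows <- c(rows, r0); cols <- c(cols, c0); rads <- c(rads, rad)
    }
  }
  # touching nuclei: anchored at distance 0.8 * (r1 + r2) from an
  # existing nucleus, clear of all others
  while (length(rows) < n && length(rows) > 0 && attempts < cap) {
    attempts <- attempts + 1L
    a <- sample.int(length(rows), 1L)
    rad <- runif(1, spec$radius_range[1], spec$radius_range[2])
    ang <- runif(1, 0, 2 * pi)
    d <- 0.8 * (rads[a] + rad)
    r0 <- round(rows[a] + d * sin(ang))
    c0 <- round(cols[a] + d * cos(ang))
    if (r0 < rad + 2 || r0 > H - rad - 1 || c0 < rad + 2 || c0 > W - rad - 1)
      next
    others <- setdiff(seq_along(rows), a)
    clear <- length(others) == 0L ||
      all((rows[others] - r0)^2 + (cols[others] - c0)^2 >=
            (rads[others] + rad + 2)^2)
    if (clear) {
      rows <- c(rows, r0); cols <- c(cols, c0); rads <- c(rads, rad)
    }
  }
  if (length(rows) < n)
    warning(sprintf("placed %d of %d nuclei before the attempt cap",
                    length(rows), n))
  data.frame(row = rows, col = cols, radius = rads)
}

#' Write a rendered scene to disk
#'
#' Writes the RGB image (PNG), the nucleus ground-truth table (CSV), the
#' zone-truth label image (PNG; 0 = white, 1 = light_pink, 2 = dark_red)
#' and the scene spec (JSON).
#'
#' @param scene Result of [render_scene()].
#' @param spec The [scene_spec()] that produced it.
#' @param dir Output directory (created if absent).
#' @param stem File-name stem (default `"scene"`).
#' @return Named vector of the written paths, invisibly.
#' @export
write_scene <- function(scene, spec, dir, stem = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    image = file.path(dir, paste0(stem, ".png")),
    nuclei = file.path(dir, paste0(stem, "_nuclei.csv")),
    zones = file.path(dir, paste0(stem, "_zones.png")),
    spec = file.path(dir, paste0(stem, "_spec.json")))
  write_rgb_field(scene$field, paths[["image"]])
  write.csv(scene$truth$nucleus_table, paths[["nuclei"]], row.names = FALSE)
  png::writePNG(scene$truth$zone_mask_truth / 255, target = paths[["zones"]])
  sp <- spec
  sp$thresholds <- unclass(sp$thresholds)
  jsonlite::write_json(unclass(sp), paths[["spec"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Simulate a two-group qPCR Ct table
#'
#' Two groups of per-sample (Ct_target, Ct_reference) pairs. The target
#' delta-CT of the second group (`FDG_pos`) is shifted by `-effect_log2`,
#' so its expected fold enrichment is `2^effect_log2` times the first
#' group's. Gaussian noise of SD `noise_sd` is added independently to the
#' target and the reference Ct of every sample, so the per-sample
#' delta-CT noise SD is `noise_sd * sqrt(2)`.
#'
#' @param n_per_group Samples per group (>= 1).
#' @param effect_log2 Group shift in log2 fold units.
#' @param ref_ct_mean Mean reference Ct in cycles (default 25).
#' @param noise_sd Ct noise SD in cycles (>= 0).
#' @param seed Integer RNG seed.
#' @param baseline_dct Baseline delta-CT of the unshifted group
#'   (default 5).
#' @param mirna Target miRNA name recorded in the table.
#' @return Long-format `data.frame` as accepted by [read_ct_table()].
#' @export
simulate_ct_table <- function(n_per_group, effect_log2 = 0,
                              ref_ct_mean = 25, noise_sd = 0.5, seed = 1,
                              baseline_dct = 5, mirna = "miR-sim") {
  if (n_per_group < 1) stop("`n_per_group` must be >= 1")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  n <- 2L * n_per_group
  group <- rep(c("FDG_neg", "FDG_pos"), each = n_per_group)
  shift <- ifelse(group == "FDG_pos", effect_log2, 0)
  ct_reference <- ref_ct_mean + rnorm(n, sd = noise_sd)
  ct_target <- ref_ct_mean + baseline_dct - shift + rnorm(n, sd = noise_sd)
  data.frame(sample_id = sprintf("s%03d", seq_len(n)),
             group = group, mirna = mirna,
             ct_target = ct_target, ct_reference = ct_reference)
}
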