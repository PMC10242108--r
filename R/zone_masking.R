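#' Zone thresholds for the FastRed expression partition
#'
#' Two fixed 8-bit intensity thresholds `th1 < th2` partition the FastRed
#' channel into three protein-expression zones: dark-red (high expression,
#' intensities `[0, th1)`), light-pink (intermediate, `[th1, th2)`) and
#' white (negative, `[th2, 255]`). Intervals are lower-inclusive so the
#' three zones always partition the image exactly. Defaults are
#' `th1 = 100`, `th2 = 190`; thresholds are global per analysis run, never
#' tuned per image.
#'
#' @param th1,th2 8-bit intensities with `0 < th1 < th2 < 255`.
#' @return A `zone_thresholds` object.
#' @export
zone_thresholds <- function(th1 = 100, th2 = 190) {
  if (!(th1 > 0 && th1 < th2 && th2 < 255))
    stop("thresholds must satisfy 0 < th1 < th2 < 255 (got th1 = ",
         th1, ", th2 = ", th2, ")")
  structure(list(th1 = th1, th2 = th2), class = "zone_thresholds")
}

zone_levels <- c("dark_red", "light_pink", "white")

#' Partition a FastRed channel into expression-zone masks
#'
#' @param fastred `H x W` 8-bit FastRed intensity map (255 = no stain).
#' @param th A [zone_thresholds()].
#' @return A `zone_masks` object: list of logical matrices `dark_red`,
#'   `light_pink`, `white` that are pairwise disjoint and cover every
#'   pixel.
#' @export
assign_zones <- function(fastred, th = zone_thresholds()) {
  stopifnot(inherits(th, "zone_thresholds"))
  fastred <- as.matrix(fastred)
  masks <- list(
    dark_red   = fastred < th$th1,
    light_pink = fastred >= th$th1 & fastred < th$th2,
    white      = fastred >= th$th2
  )
  structure(masks, class = "zone_masks", thresholds = th)
}

check_partition <- function(masks) {
  s <- masks$dark_red + masks$light_pink + masks$white
  if (!all(s == 1L))
    stop("zone masks do not partition the image (", sum(s != 1L),
         " pixels covered != once)")
  invisible(TRUE)
}

#' Per-zone pixel counts and fractions
#'
#' @param masks A `zone_masks` object from [assign_zones()].
#' @return List with integer `counts` and numeric `fractions`, both named
#'   by zone; fractions are counts over total pixels and sum to 1.
#' @export
pixel_fractions <- function(masks) {
  check_partition(masks)
  counts <- vapply(masks[zone_levels], sum, numeric(1))
  list(counts = counts, fractions = counts / sum(counts))
}

#' Encode zone masks as a single 8-bit label image
#'
#' Labels: 0 = white, 1 = light_pink, 2 = dark_red.
#'
#' @param masks A `zone_masks` object.
#' @return Integer matrix of labels.
#' @export
zone_label_image <- function(masks) {
  check_partition(masks)
  lab <- matrix(0L, nrow(masks$white), ncol(masks$white))
  lab[masks$light_pink] <- 1L
  lab[masks$dark_red] <- 2L
  lab
}

#' Write zone masks as an 8-bit label PNG
#'
#' @param masks A `zone_masks` object.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_zone_masks <- function(masks, path) {
  png::writePNG(zone_label_image(masks) / 255, target = path)
  invisible(path)
}
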