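marker_class_levels <- c("DAB_pos", "FB_only")

#' Region statistics for one analyzed field
#'
#' Counts pixels per expression zone and nuclei per zone and marker class,
#' and computes the percentage of marker-positive (DAB) nuclei among
#' analyzed nuclei. The default denominator is the set of retained nuclei
#' within the same zone; `denominator = "roi"` uses all retained nuclei of
#' the field instead. Zones with zero nuclei report `NA`, never 0%.
#'
#' @param nuclei Nucleus record table from [detect_nuclei()] (needs
#'   `label`, `marker_class`, `zone` columns).
#' @param masks `zone_masks` from [assign_zones()].
#' @param roi_id Identifier of the field.
#' @param denominator `"zone"` (default) or `"roi"`.
#' @return An `roi_quantification` object: list with `roi_id`,
#'   `pixel_counts`, `pixel_fractions`, `nucleus_counts` (zone x class
#'   matrix), `total_nuclei` and `pct_mir_positive` per zone.
#' @export
quantify_roi <- function(nuclei, masks, roi_id = "roi",
                         denominator = c("zone", "roi")) {
  denominator <- match.arg(denominator)
  if (anyDuplicated(nuclei$label))
    stop("duplicated nucleus labels in record table")
  px <- pixel_fractions(masks)
  cnt <- matrix(0, length(zone_levels), length(marker_class_levels),
                dimnames = list(zone_levels, marker_class_levels))
  if (nrow(nuclei)) {
    t0 <- table(factor(nuclei$zone, levels = zone_levels),
                factor(nuclei$marker_class, levels = marker_class_levels))
    cnt[] <- as.numeric(t0)
  }
  zone_tot <- rowSums(cnt)
  denom <- if (denominator == "zone") zone_tot
           else rep(sum(cnt), length(zone_levels))
  pct <- ifelse(zone_tot > 0, 100 * cnt[, "DAB_pos"] / pmax(denom, 1), NA_real_)
  structure(
    list(roi_id = roi_id,
         pixel_counts = px$counts,
         pixel_fractions = px$fractions,
         nucleus_counts = cnt,
         total_nuclei = sum(cnt),
         pct_mir_positive = setNames(pct, zone_levels),
         denominator = denominator),
    class = "roi_quantification")
}

#' Aggregate per-field quantifications into a sample summary
#'
#' Pools pixel counts across fields, averages per-zone marker-positive
#' percentages (unweighted over the fields where the zone holds nuclei)
#' and records dropped fields with their reasons.
#'
#' @param rois List of `roi_quantification` objects.
#' @param sample_id Sample identifier.
#' @param dropped Named character vector: names are dropped ROI ids,
#'   values the drop reasons.
#' @return A `sample_summary` object.
#' @export
aggregate_sample <- function(rois, sample_id = "sample",
                             dropped = character(0)) {
  if (length(rois) == 0L) stop("no analyzed fields to aggregate")
  pooled_counts <- Reduce(`+`, lapply(rois, `[[`, "pixel_counts"))
  totals <- vapply(rois, `[[`, numeric(1), "total_nuclei")
  pct <- vapply(rois, `[[`, numeric(length(zone_levels)),
                "pct_mir_positive")
  pct <- matrix(pct, nrow = length(zone_levels),
                dimnames = list(zone_levels, NULL))
  n_pct <- rowSums(!is.na(pct))
  mean_pct <- ifelse(n_pct > 0, rowMeans(pct, na.rm = TRUE), NA_real_)
  structure(
    list(sample_id = sample_id,
         n_rois = length(rois),
         roi_ids = vapply(rois, `[[`, character(1), "roi_id"),
         mean_total_nuclei = mean(totals),
         sd_total_nuclei = if (length(totals) > 1) sd(totals) else NA_real_,
         pooled_pixel_counts = pooled_counts,
         pooled_pixel_fractions = pooled_counts / sum(pooled_counts),
         mean_pct_mir_positive = setNames(mean_pct, zone_levels),
         n_rois_with_zone_nuclei = setNames(n_pct, zone_levels),
         dropped = dropped),
    class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("<sample_summary> '%s': %d fields (%d dropped)\n",
              x$sample_id, x$n_rois, length(x$dropped)))
  cat(sprintf("  nuclei/field: %.1f +/- %.1f\n",
              x$mean_total_nuclei, x$sd_total_nuclei))
  cat("  pooled pixel fractions:",
      paste(sprintf("%s %.1f%%", zone_levels,
                    100 * x$pooled_pixel_fractions), collapse = ", "), "\n")
  cat("  mean %miR+ nuclei:",
      paste(sprintf("%s %.1f", zone_levels, x$mean_pct_mir_positive),
            collapse = ", "), "\n")
  invisible(x)
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Average-rank Spearman correlation. The two-sided p-value uses the exact
#' permutation distribution (full enumeration) for `n <= 10` and the
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` beyond.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return List with `rho`, `p_value`, `n` and the `method` used.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("correlation undefined: one variable is constant")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 10) {
    p <- cpp_spearman_perm_p(rx, ry)
    method <- "exact_permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
    method <- "t_approximation"
  }
  list(rho = rho, p_value = min(p, 1), n = n, method = method)
}

#' Correlate marker positivity against SSTR2 expression zone
#'
#' The tissue-level result of the pipeline: Spearman rank correlation
#' between the ordinal zone level (white = 0 < light_pink = 1 <
#' dark_red = 2) and the percentage of marker-positive nuclei, over
#' ROI-level or sample-level observations.
#'
#' @param data `data.frame` with columns `zone` (zone name or ordinal
#'   level) and `pct_mir_positive`.
#' @return List with `rho`, `p_value`, `n`, `method`.
#' @export
correlate_mir_vs_zone <- function(data) {
  z <- data$zone
  if (!is.numeric(z)) {
    lev <- match(as.character(z), rev(zone_levels)) - 1  # white=0 .. dark_red=2
    if (anyNA(lev)) stop("unknown zone labels: ",
                         paste(unique(z[is.na(lev)]), collapse = ", "))
    z <- lev
  }
  keep <- !is.na(data$pct_mir_positive) & !is.na(z)
  if (sum(keep) < 3) stop("need at least 3 complete (zone, pct) pairs")
  spearman_cor(z[keep], data$pct_mir_positive[keep])
}

#' Flatten quantifications to tables
#'
#' @param rois List of `roi_quantification` objects.
#' @return `data.frame` with one row per ROI x zone, suitable for
#'   [correlate_mir_vs_zone()] and for CSV export.
#' @export
roi_zone_table <- function(rois) {
  do.call(rbind, lapply(rois, function(r) {
    data.frame(roi_id = r$roi_id,
               zone = zone_levels,
               pixel_count = as.numeric(r$pixel_counts),
               pixel_fraction = as.numeric(r$pixel_fractions),
               n_dab_pos = r$nucleus_counts[, "DAB_pos"],
               n_fb_only = r$nucleus_counts[, "FB_only"],
               pct_mir_positive = as.numeric(r$pct_mir_positive),
               row.names = NULL)
  }))
}
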