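intensity_class_levels <- c("background", "weak_cytoplasmic", "nuclear")

#' Intensity-based k-means classification of a stain channel
#'
#' Partitions the pixels of a single-stain intensity map into `k = 3`
#' classes — white background (lightest), weak cytoplasmic signal and
#' nuclear signal (darkest) — by k-means on the 1-D intensity histogram.
#' Because the problem is one-dimensional, the globally optimal clustering
#' is computed exactly by dynamic programming over the sorted unique
#' intensity values (weighted by pixel counts), so the result is
#' deterministic and always attains the minimum within-cluster sum of
#' squares. If the channel has fewer than `k` distinct values the
#' classification degrades to the available number of classes, the darkest
#' cluster being nuclear; a constant channel yields a single background
#' class and an empty nuclear mask.
#'
#' Nuclear signal must be dark: if the darkest cluster centre lies above
#' `nuclear_max_center` the channel is considered free of nuclear signal
#' and the nuclear mask is empty (the class partition itself is
#' unaffected). This guards against quantisation-level clusters in
#' channels that carry no stain.
#'
#' @param channel `H x W` 8-bit intensity matrix (255 = no stain).
#' @param k Number of classes (default 3; must be >= 2).
#' @param nuclear_max_center Maximum mean intensity for the darkest
#'   cluster to count as nuclear (default 200).
#' @return An `intensity_classes` object: list with `labels` (integer
#'   matrix, 1 = background ... up to `k` = nuclear), `class_of` (character
#'   vector naming each label code), `centers` (cluster mean intensities
#'   sorted descending, background first), and `nuclear` (logical matrix).
#' @export
classify_intensities <- function(channel, k = 3, nuclear_max_center = 200) {
  if (k < 2) stop("`k` must be >= 2")
  channel <- as.matrix(channel)
  if (length(channel) == 0L) stop("`channel` is empty")
  tab <- table(channel)
  v <- as.numeric(names(tab))
  w <- as.numeric(tab)
  m <- length(v)
  g <- min(k, m)
  if (m == 1L) {
    # constant channel: single class, treated as background (no nuclei)
    labels <- matrix(1L, nrow(channel), ncol(channel))
    out <- list(labels = labels, class_of = "background",
                centers = c(background = v),
                nuclear = matrix(FALSE, nrow(channel), ncol(channel)))
    class(out) <- "intensity_classes"
    return(out)
  }
  breaks <- kmeans1d_breaks(v, w, g)   # g intervals over ascending values
  # cluster index per unique value, ascending by intensity (1 = darkest)
  cl_of_value <- rep(seq_len(g), times = diff(c(0L, breaks)))
  centers_asc <- vapply(seq_len(g), function(j) {
    idx <- cl_of_value == j
    sum(v[idx] * w[idx]) / sum(w[idx])
  }, numeric(1))
  # class names: darkest = nuclear, lightest = background
  nm <- if (g >= 3) c("nuclear", rep("weak_cytoplasmic", g - 2), "background")
        else c("nuclear", "background")
  # label codes count upward in darkness: 1 = background ... g = nuclear
  code_of_value <- (g + 1L) - cl_of_value
  class_of <- rev(nm)
  lut <- code_of_value[match(as.numeric(channel), v)]
  labels <- matrix(lut, nrow(channel), ncol(channel))
  nuclear <- if (centers_asc[1] <= nuclear_max_center) labels == g
             else matrix(FALSE, nrow(channel), ncol(channel))
  out <- list(labels = labels,
              class_of = class_of,
              # descending intensity: background (lightest) first
              centers = setNames(rev(centers_asc), class_of),
              nuclear = nuclear)
  class(out) <- "intensity_classes"
  out
}

# exact weighted 1-D k-means: returns the ascending break positions
# (indices into v of the last member of each cluster)
kmeans1d_breaks <- function(v, w, g) {
  m <- length(v)
  cw <- cumsum(w); cwv <- cumsum(w * v); cwv2 <- cumsum(w * v^2)
  cost <- function(i, j) {
    # SSE of one cluster spanning unique values i..j (vectorised over i)
    W <- cw[j] - c(0, cw)[i]
    S <- cwv[j] - c(0, cwv)[i]
    Q <- cwv2[j] - c(0, cwv2)[i]
    Q - S^2 / W
  }
  D <- matrix(Inf, g, m)
  B <- matrix(0L, g, m)
  D[1, ] <- vapply(seq_len(m), function(j) cost(1, j), numeric(1))
  B[1, ] <- 1L
  if (g > 1) {
    for (q in 2:g) {
      for (j in q:m) {
        i <- q:j                      # first index of the last cluster
        tot <- D[q - 1, i - 1] + cost(i, j)
        b <- which.min(tot)
        D[q, j] <- tot[b]
        B[q, j] <- i[b]
      }
    }
  }
  breaks <- integer(g)
  j <- m
  for (q in g:1) {
    breaks[q] <- j
    j <- B[q, j] - 1L
  }
  breaks
}

#' Total within-cluster sum of squares of an intensity classification
#'
#' @param channel Intensity matrix used for the classification.
#' @param classes The matching [classify_intensities()] result.
#' @return The within-cluster SSE (numeric scalar).
#' @export
intensity_class_sse <- function(channel, classes) {
  x <- as.numeric(channel)
  lab <- as.integer(classes$labels)
  mu <- tapply(x, lab, mean)
  sum((x - mu[as.character(lab)])^2)
}

#' Watershed segmentation of the nuclear signal
#'
#' Splits touching nuclei by the standard watershed transform on the
#' negated Euclidean distance map of the nuclear mask: distance maxima act
#' as basins and shallow maxima (depth below `tolerance`) are suppressed,
#' an h-maxima-style control of over-segmentation.
#'
#' @param classes An `intensity_classes` object, or a logical nuclear mask.
#' @param tolerance Minimum basin depth in distance units (default 1).
#' @return Integer label matrix; labels contiguous from 1, 0 = background.
#' @export
segment_nuclei <- function(classes, tolerance = 1) {
  mask <- if (inherits(classes, "intensity_classes")) classes$nuclear
          else as.matrix(classes)
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  dist <- EBImage::distmap(mask)
  labs <- EBImage::watershed(dist, tolerance = tolerance, ext = 1)
  relabel_contiguous(matrix(as.integer(EBImage::imageData(labs)),
                            nrow(mask), ncol(mask)))
}

relabel_contiguous <- function(labels) {
  u <- sort(unique(labels[labels > 0L]))
  if (length(u) == 0L) return(labels)
  lut <- integer(max(u))
  lut[u] <- seq_along(u)
  pos <- labels > 0L
  labels[pos] <- lut[labels[pos]]
  labels
}

#' Remove objects whose area is not compliant with a nucleus
#'
#' @param labels Integer label matrix (0 = background).
#' @param min_area,max_area Area bounds in px^2 (defaults 30 and 5000);
#'   objects outside `[min_area, max_area]` are removed.
#' @return Label matrix with surviving objects renumbered contiguously.
#' @export
filter_by_size <- function(labels, min_area = 30, max_area = 5000) {
  if (!(min_area > 0 && min_area < max_area))
    stop("need 0 < min_area < max_area")
  n <- max(labels)
  if (n == 0L) return(labels)
  areas <- tabulate(labels[labels > 0L], nbins = n)
  drop <- which(areas < min_area | areas > max_area)
  if (length(drop)) labels[labels %in% drop] <- 0L
  relabel_contiguous(labels)
}

#' Classify each nucleus as marker-positive or counterstain-only
#'
#' A nucleus is `DAB_pos` when at least `dab_fraction_threshold` of its
#' pixels carry nuclear-level DAB signal; otherwise it is `FB_only`
#' (FastBlue counterstain without the marker). The two classes are
#' disjoint and exhaustive over retained nuclei.
#'
#' @param labels Integer label matrix.
#' @param dab_classes [classify_intensities()] result for the DAB channel.
#' @param dab_fraction_threshold Fraction of nuclear-DAB pixels required
#'   (default 0.5).
#' @return Character vector, one of `"DAB_pos"`/`"FB_only"` per label.
#' @export
classify_marker <- function(labels, dab_classes,
                            dab_fraction_threshold = 0.5) {
  dabnuc <- if (inherits(dab_classes, "intensity_classes"))
    dab_classes$nuclear else as.matrix(dab_classes)
  if (!all(dim(labels) == dim(dabnuc)))
    stop("label map and DAB classification have different shapes")
  n <- max(labels)
  if (n == 0L) return(character(0))
  pos <- labels > 0L
  area <- tabulate(labels[pos], nbins = n)
  dab_px <- tabulate(labels[pos & dabnuc], nbins = n)
  ifelse(dab_px / area >= dab_fraction_threshold, "DAB_pos", "FB_only")
}

#' Assign each nucleus to an expression zone
#'
#' Each nucleus gets the zone containing the plurality of its pixels; ties
#' break toward the higher-expression zone (dark_red > light_pink >
#' white).
#'
#' @param labels Integer label matrix.
#' @param masks `zone_masks` from [assign_zones()].
#' @return Character vector of zone names per label.
#' @export
assign_nucleus_zone <- function(labels, masks) {
  if (!all(dim(labels) == dim(masks$white)))
    stop("label map and zone masks have different shapes")
  n <- max(labels)
  if (n == 0L) return(character(0))
  pos <- labels > 0L
  cnt <- vapply(zone_levels, function(z)
    tabulate(labels[pos & masks[[z]]], nbins = n), numeric(n))
  cnt <- matrix(cnt, nrow = n)
  zone_levels[max.col(cnt, ties.method = "first")]
}

#' Single-nucleus morphology and intensity features
#'
#' @param labels Integer label matrix.
#' @param channels `stain_channels` from [deconvolve()].
#' @return `data.frame` with one row per nucleus: `label`, centroid
#'   (`row`, `col`), `area` (px^2), `perimeter` (px), `eccentricity`
#'   (0 = circle), and per-channel mean intensities.
#' @export
nucleus_features <- function(labels, channels) {
  n <- max(labels)
  if (n == 0L) {
    return(data.frame(label = integer(0), row = numeric(0), col = numeric(0),
                      area = numeric(0), perimeter = numeric(0),
                      eccentricity = numeric(0), mean_fastred = numeric(0),
                      mean_fastblue = numeric(0), mean_dab = numeric(0)))
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rows <- ((idx - 1L) %% nrow(labels)) + 1L
  cols <- ((idx - 1L) %/% nrow(labels)) + 1L
  area <- tabulate(lab, nbins = n)
  cr <- rowsum(as.numeric(rows), lab)[, 1] / area
  cc <- rowsum(as.numeric(cols), lab)[, 1] / area
  # central second moments -> eccentricity of the equivalent ellipse
  mu20 <- rowsum((rows - cr[lab])^2, lab)[, 1] / area
  mu02 <- rowsum((cols - cc[lab])^2, lab)[, 1] / area
  mu11 <- rowsum((rows - cr[lab]) * (cols - cc[lab]), lab)[, 1] / area
  disc <- sqrt(pmax((mu20 - mu02)^2 + 4 * mu11^2, 0))
  l1 <- (mu20 + mu02 + disc) / 2
  l2 <- (mu20 + mu02 - disc) / 2
  ecc <- ifelse(l1 > 0, sqrt(pmax(1 - l2 / l1, 0)), 0)
  perim <- boundary_edge_count(labels, n)
  means <- lapply(channels[c("fastred", "fastblue", "dab")], function(ch)
    rowsum(as.numeric(ch[idx]), lab)[, 1] / area)
  data.frame(label = seq_len(n), row = cr, col = cc, area = area,
             perimeter = perim, eccentricity = ecc,
             mean_fastred = means$fastred, mean_fastblue = means$fastblue,
             mean_dab = means$dab)
}

# 4-connectivity boundary length: number of pixel edges facing a
# different label (image border counts)
boundary_edge_count <- function(labels, n) {
  H <- nrow(labels); W <- ncol(labels)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- labels
  core <- pad[2:(H + 1L), 2:(W + 1L)]
  edges <- numeric(n)
  for (sh in list(pad[1:H, 2:(W + 1L)], pad[3:(H + 2L), 2:(W + 1L)],
                  pad[2:(H + 1L), 1:W], pad[2:(H + 1L), 3:(W + 2L)])) {
    diffmask <- core > 0L & sh != core
    if (any(diffmask))
      edges <- edges + tabulate(core[diffmask], nbins = n)
  }
  edges
}

#' Detect, split, filter and classify nuclei on one field
#'
#' Runs the whole nuclear stage: the FastBlue and DAB channels are each
#' classified into background / weak cytoplasmic / nuclear intensity
#' levels, nuclear pixels from either channel are pooled (marker-positive
#' nuclei may lack counterstain), touching nuclei are split by watershed,
#' objects of non-nuclear size are discarded, and each retained nucleus is
#' classified as `DAB_pos` or `FB_only` and assigned an expression zone.
#'
#' @param channels `stain_channels` from [deconvolve()].
#' @param masks `zone_masks` from [assign_zones()].
#' @param min_area,max_area Nucleus size bounds in px^2.
#' @param dab_fraction_threshold See [classify_marker()].
#' @param watershed_tolerance See [segment_nuclei()].
#' @return List with the `nuclei` record table (see [nucleus_features()],
#'   plus `marker_class` and `zone` columns) and the final `labels` map.
#' @export
detect_nuclei <- function(channels, masks, min_area = 30, max_area = 5000,
                          dab_fraction_threshold = 0.5,
                          watershed_tolerance = 1) {
  fb <- classify_intensities(channels$fastblue)
  dab <- classify_intensities(channels$dab)
  labels <- segment_nuclei(fb$nuclear | dab$nuclear,
                           tolerance = watershed_tolerance)
  labels <- filter_by_size(labels, min_area, max_area)
  feats <- nucleus_features(labels, channels)
  feats$marker_class <- classify_marker(labels, dab, dab_fraction_threshold)
  feats$zone <- assign_nucleus_zone(labels, masks)
  list(nuclei = feats, labels = labels)
}
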