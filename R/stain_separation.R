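#' Stain matrix for optical-density colour deconvolution
#'
#' A stain matrix holds one unit-norm optical-density absorbance vector per
#' stain (rows = stains, columns = R, G, B). The default is the published
#' "FastRed FastBlue DAB" basis of the classic ImageJ/Fiji Colour
#' Deconvolution plugin: FastRed marks SSTR2 protein, FastBlue is the
#' counterstain-associated channel, DAB marks the hybridized microRNA.
#'
#' @param vectors Optional 3 x 3 numeric matrix of absorbances (rows =
#'   stains, columns = RGB). Rows are re-normalized to unit Euclidean norm.
#' @param stain_names Character vector of three stain names (row order).
#'
#' @return A `stain_matrix` object (a 3 x 3 matrix with class attribute).
#' @examples
#' M <- stain_matrix()
#' rowSums(M^2)  # each ~1
#' @export
stain_matrix <- function(vectors = NULL,
                         stain_names = c("fastred", "fastblue", "dab")) {
  if (is.null(vectors)) {
    vectors <- matrix(c(
      0.21393921, 0.85112669, 0.47794022,   # FastRed
      0.74890292, 0.60624161, 0.26731082,   # FastBlue
      0.26800000, 0.57000000, 0.77600000),  # DAB
      nrow = 3, byrow = TRUE)
  }
  vectors <- as.matrix(vectors)
  if (!all(dim(vectors) == c(3L, 3L))) stop("stain matrix must be 3 x 3")
  if (length(stain_names) != 3L) stop("need exactly three stain names")
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) stop("zero stain vector in rows: ",
                          paste(stain_names[nrm == 0], collapse = ", "))
  vectors <- vectors / nrm
  if (abs(det(vectors)) < 1e-8 || kappa(vectors) > 1e8)
    stop("stain matrix is singular or ill-conditioned; stain vectors (",
         paste(stain_names, collapse = ", "), ") are not independent")
  dimnames(vectors) <- list(stain_names, c("R", "G", "B"))
  structure(vectors, class = c("stain_matrix", "matrix"))
}

#' Read a stain matrix from a JSON or CSV file
#'
#' JSON files hold a 3 x 3 array (rows = stains) or a named list of
#' three-element RGB absorbance vectors; CSV files hold three rows with
#' optional row names in the first column.
#'
#' @param path File path (.json or .csv).
#' @return A [stain_matrix()].
#' @export
read_stain_matrix <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.list(x) && !is.data.frame(x))
      return(stain_matrix(do.call(rbind, x), stain_names = names(x)))
    return(stain_matrix(x))
  }
  if (ext == "csv") {
    x <- read.csv(path, header = FALSE, stringsAsFactors = FALSE)
    if (!is.numeric(x[[1]])) {
      nm <- x[[1]]
      return(stain_matrix(as.matrix(x[, -1]), stain_names = nm))
    }
    return(stain_matrix(as.matrix(x)))
  }
  stop("unsupported stain-matrix format '", ext, "'")
}

#' Convert 8-bit transmitted intensities to optical density
#'
#' Beer-Lambert optical density `od = -log10(max(I, 1) / i0)` per channel
#' per pixel. Zero intensities are floored at 1 so the density stays
#' finite; `od(i0) = 0`.
#'
#' @param pixels Numeric array or matrix of 8-bit intensities.
#' @param i0 Incident (blank) intensity; default 255.
#' @return Array of the same shape with non-negative optical densities.
#' @export
rgb_to_od <- function(pixels, i0 = 255) {
  if (i0 <= 0) stop("`i0` must be positive")
  -log10(pmax(pixels, 1) / i0)
}

#' Compose an RGB image from per-stain concentration maps
#'
#' Forward Beer-Lambert model: transmitted intensity
#' `I_c = 255 * 10^(-sum_s M[s, c] * conc_s)` for colour channel `c`.
#' This is the exact inverse used by [deconvolve()], so rendering and
#' unmixing round-trip up to 8-bit quantisation.
#'
#' @param concentrations List of three `H x W` non-negative concentration
#'   matrices, in the stain order of `matrix`.
#' @param matrix A [stain_matrix()].
#' @param quantize Round the result half-away-from-zero to integers
#'   (default `TRUE`).
#' @return `H x W x 3` array of intensities in `[0, 255]`.
#' @export
compose_rgb <- function(concentrations, matrix = stain_matrix(),
                        quantize = TRUE) {
  stopifnot(length(concentrations) == 3L)
  d <- dim(concentrations[[1]])
  conc <- vapply(concentrations, as.numeric, numeric(prod(d)))
  od <- conc %*% unclass(matrix)            # N x 3 channel densities
  img <- 255 * 10^(-od)
  if (quantize) img <- round_half_up(img)
  array(clip8(img), c(d, 3L))
}

#' Unmix an RGB field into single-stain intensity maps
#'
#' Inverts the Beer-Lambert mixing model: per pixel the optical-density
#' vector is solved against the stain matrix, negative concentrations
#' (pixels outside the stain simplex) are clipped to zero, and each stain
#' map is rendered back to 8-bit transmitted intensity
#' `255 * 10^(-conc)` (255 = no stain, 0 = maximal stain).
#'
#' @param field An [rgb_field()] or an `H x W x 3` array.
#' @param matrix A [stain_matrix()].
#' @return A `stain_channels` object: list with `H x W` 8-bit matrices
#'   named after the stains (default `fastred`, `fastblue`, `dab`), plus a
#'   `concentrations` attribute holding the clipped concentration maps.
#' @export
deconvolve <- function(field, matrix = stain_matrix()) {
  px <- if (inherits(field, "rgb_field")) field$pixels else field
  d <- dim(px)[1:2]
  od <- matrix(rgb_to_od(px), ncol = 3L)    # N x 3, column-major over H*W
  conc <- od %*% solve(unclass(matrix))     # od = conc %*% M
  conc <- pmax(conc, 0)
  maps <- lapply(seq_len(3L), function(s) {
    m <- clip8(round_half_up(255 * 10^(-conc[, s])))
    dim(m) <- d
    m
  })
  names(maps) <- rownames(matrix)
  attr(maps, "concentrations") <- lapply(seq_len(3L), function(s) {
    m <- conc[, s]; dim(m) <- d; m
  })
  class(maps) <- "stain_channels"
  maps
}

#' @export
print.stain_channels <- function(x, ...) {
  d <- dim(x[[1]])
  cat(sprintf("<stain_channels> %s; %d x %d px\n",
              paste(names(x), collapse = ", "), d[1], d[2]))
  invisible(x)
}
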