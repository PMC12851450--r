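# Binary tumor slices and the 8-component geometric summary statistic.

#' Extract a binary tumor slice from a lattice
#'
#' Cuts one plane out of the 3D cell-count lattice and binarizes it: a pixel
#' is tumor if its voxel holds at least `threshold_cells` cells.  This is the
#' simulated analogue of a segmented histology section.
#'
#' @param x A `lattice_state` or 3D integer array of counts.
#' @param axis Slice axis: 1/2/3 or `"x"`/`"y"`/`"z"`.
#' @param index Plane index along `axis` (1-based).
#' @param threshold_cells Minimum cell count for a pixel to be tumor
#'   (default 1).
#' @param spacing_um Pixel spacing, carried along for provenance.
#' @return An object of class `tumor_slice` with elements `pixels` (logical
#'   matrix), `spacing_um`, `axis`, `index`, `provenance`.
#' @export
extract_slice <- function(x, axis = 3, index, threshold_cells = 1,
                          spacing_um = 43) {
  counts <- if (inherits(x, "lattice_state")) x$counts else x
  stopifnot(is.array(counts), length(dim(counts)) == 3L)
  if (is.character(axis)) axis <- match(axis, c("x", "y", "z"))
  if (!axis %in% 1:3) abort("`axis` must be 1, 2, 3 or 'x', 'y', 'z'")
  if (index < 1 || index > dim(counts)[axis]) abort("slice `index` out of range")
  plane <- switch(axis,
                  counts[index, , ],
                  counts[, index, ],
                  counts[, , index])
  new_tumor_slice(plane >= threshold_cells, spacing_um = spacing_um,
                  provenance = list(axis = axis, index = index))
}

#' Construct a tumor slice from a binary matrix
#'
#' @param pixels Logical (or 0/1 numeric) matrix.
#' @param spacing_um Pixel spacing in micrometres.
#' @param provenance Either a list `(axis, index)` or the string
#'   `"histology"`.
#' @return A `tumor_slice`.
#' @export
new_tumor_slice <- function(pixels, spacing_um = 43, provenance = "histology") {
  if (is.numeric(pixels)) pixels <- pixels > 0.5
  if (!is.matrix(pixels) || !is.logical(pixels))
    abort("`pixels` must be a logical matrix")
  if (any(dim(pixels) < 1L)) abort("slice must be at least 1 x 1")
  structure(list(pixels = pixels, spacing_um = spacing_um,
                 provenance = provenance),
            class = "tumor_slice")
}

#' @export
print.tumor_slice <- function(x, ...) {
  cat("<tumor_slice> ", nrow(x$pixels), " x ", ncol(x$pixels), " px @ ",
      x$spacing_um, " um, ", sum(x$pixels), " tumor pixels\n", sep = "")
  invisible(x)
}

.slice_pixels <- function(x) {
  if (inherits(x, "tumor_slice")) return(x$pixels)
  if (is.numeric(x) && is.matrix(x)) return(x > 0.5)
  if (is.logical(x) && is.matrix(x)) return(x)
  abort("expected a tumor_slice or binary matrix")
}

#' Label connected components of a binary image
#'
#' Maximal connected regions under 8-connectivity (edge- or corner-adjacent;
#' the conventional default for 2D region labeling) or 4-connectivity.
#'
#' @param img A `tumor_slice` or binary matrix.
#' @param connectivity 8 (default) or 4.
#' @return An integer matrix of labels (0 = background), labels assigned in
#'   scan order.
#' @export
label_components <- function(img, connectivity = 8) {
  label_components_cpp(.slice_pixels(img), as.integer(connectivity))
}

# weighted border-configuration perimeter estimator: each border pixel (a
# foreground pixel with at least one background 4-neighbor, image border
# counting as background) contributes a weight determined by its local
# configuration of border neighbors — 1 for straight runs, sqrt(2) for
# diagonal runs, (1 + sqrt(2))/2 for corners.
.perimeter_weighted <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- img
  core <- pad[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
  up    <- pad[1:nr, 2:(nc + 1L), drop = FALSE]
  down  <- pad[3:(nr + 2L), 2:(nc + 1L), drop = FALSE]
  left  <- pad[2:(nr + 1L), 1:nc, drop = FALSE]
  right <- pad[2:(nr + 1L), 3:(nc + 2L), drop = FALSE]
  eroded <- core & up & down & left & right
  border <- core & !eroded
  bpad <- matrix(FALSE, nr + 2L, nc + 2L)
  bpad[2:(nr + 1L), 2:(nc + 1L)] <- border
  sh <- function(dr, dc) bpad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc, drop = FALSE]
  n_orth <- sh(-1, 0) + sh(1, 0) + sh(0, -1) + sh(0, 1)
  n_diag <- sh(-1, -1) + sh(-1, 1) + sh(1, -1) + sh(1, 1)
  code <- 1L + 2L * n_orth + 10L * n_diag
  w <- numeric(50)
  w[c(5, 7, 15, 17, 25, 27) + 1L] <- 1
  w[c(21, 33) + 1L] <- sqrt(2)
  w[c(13, 23) + 1L] <- (1 + sqrt(2)) / 2
  sum(w[code[border] + 1L])
}

# area after filling holes: background components (4-connectivity) of the
# padded bounding box that do not touch the frame are holes
.filled_area <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- img
  bg <- label_components_cpp(!pad, 4L)
  outside <- unique(c(bg[1, ], bg[nr + 2L, ], bg[, 1], bg[, nc + 2L]))
  holes <- !pad & !(bg %in% outside)
  sum(img) + sum(holes)
}

# eccentricity of the ellipse with the same normalized second central
# moments as the region; the 1/12 term accounts for the unit extent of each
# pixel, so a single pixel is a circle (eccentricity 0)
.eccentricity_moments <- function(rows, cols) {
  mr <- mean(rows); mc <- mean(cols)
  uxx <- mean((cols - mc)^2) + 1 / 12
  uyy <- mean((rows - mr)^2) + 1 / 12
  uxy <- mean((rows - mr) * (cols - mc))
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  major2 <- uxx + uyy + common
  minor2 <- max(uxx + uyy - common, 0)
  sqrt(max(1 - minor2 / major2, 0))
}

#' Per-region geometric properties
#'
#' For every 8-connected component: pixel count (`area`), the weighted
#' boundary-contour `perimeter`, the `filled_area` after hole filling, and
#' the `eccentricity` of the ellipse with identical second central moments
#' (0 for a disc, approaching 1 for a line).
#'
#' @param img A `tumor_slice` or binary matrix.
#' @return A tibble with one row per region: `label`, `area`, `perimeter`,
#'   `filled_area`, `eccentricity`.
#' @export
region_properties <- function(img) {
  px <- .slice_pixels(img)
  labs <- label_components_cpp(px, 8L)
  n <- max(labs)
  if (n == 0L)
    return(tibble::tibble(label = integer(), area = numeric(),
                          perimeter = numeric(), filled_area = numeric(),
                          eccentricity = numeric()))
  idx <- which(labs > 0, arr.ind = TRUE)
  lab <- labs[labs > 0]
  rows <- split(idx[, 1], lab)
  cols <- split(idx[, 2], lab)
  out <- purrr::map(seq_len(n), function(k) {
    r <- rows[[k]]; c <- cols[[k]]
    sub <- matrix(FALSE, max(r) - min(r) + 1L, max(c) - min(c) + 1L)
    sub[cbind(r - min(r) + 1L, c - min(c) + 1L)] <- TRUE
    tibble::tibble(label = k, area = length(r),
                   perimeter = .perimeter_weighted(sub),
                   filled_area = .filled_area(sub),
                   eccentricity = .eccentricity_moments(r, c))
  })
  dplyr::bind_rows(out)
}

.sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

.stat_names <- c("n_components", "mean_area", "sd_area", "mean_eccentricity",
                 "sd_eccentricity", "sd_perimeter", "max_perimeter",
                 "max_filled_area")

#' Geometric summary statistics of a binary tumor image
#'
#' The 8-component, location-free descriptor used to compare tumor slices:
#' number of 8-connected components, mean and standard deviation of region
#' area, mean and standard deviation of region eccentricity, standard
#' deviation and maximum of region perimeter, and maximum filled area.
#' Standard deviations are population standard deviations (divide by n), so
#' a single-region image has zero spread entries.  An empty image yields the
#' all-zero vector so that extinct tumors remain comparable.
#'
#' @param img A `tumor_slice` or binary matrix.
#' @return A named numeric vector of length 8.
#' @export
summary_statistics <- function(img) {
  props <- region_properties(img)
  if (nrow(props) == 0L) {
    s <- rep(0, 8)
    names(s) <- .stat_names
    return(s)
  }
  s <- c(nrow(props),
         mean(props$area), .sd_pop(props$area),
         mean(props$eccentricity), .sd_pop(props$eccentricity),
         .sd_pop(props$perimeter), max(props$perimeter),
         max(props$filled_area))
  names(s) <- .stat_names
  s
}

#' Jaccard index of two binary masks
#'
#' Intersection over union, the standard overlap measure for segmentations.
#' Identical nonempty masks give 1; disjoint masks give 0; two empty masks
#' are defined to agree perfectly (index 1).
#'
#' @param a,b `tumor_slice`s or binary matrices of the same shape.
#' @return A value in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  pa <- .slice_pixels(a); pb <- .slice_pixels(b)
  if (!identical(dim(pa), dim(pb))) abort("masks must have the same shape")
  uni <- sum(pa | pb)
  if (uni == 0) return(1)
  sum(pa & pb) / uni
}

#' Per-component scale for standardizing summary statistics
#'
#' The components of the geometric summary statistic span orders of magnitude
#' (counts vs areas), so distances are computed on statistics standardized by
#' a robust per-component scale: the median absolute deviation over the
#' simulation pool, floored at `1e-9` to keep degenerate components finite.
#'
#' @param stats A numeric matrix (simulations x 8) of summary statistics.
#' @return A positive numeric vector, one scale per component.
#' @export
stat_scale <- function(stats) {
  stats <- as.matrix(stats)
  pmax(apply(stats, 2, stats::mad), 1e-9)
}

#' Standardized Euclidean distance between summary statistics
#'
#' @param s,s_obs Numeric vectors of summary statistics.
#' @param scale Per-component positive scale (see [stat_scale()]); default 1.
#' @return A nonnegative scalar, zero iff `s == s_obs`.
#' @export
summary_distance <- function(s, s_obs, scale = 1) {
  if (length(s) != length(s_obs)) abort("statistic vectors differ in length")
  if (any(scale <= 0)) abort("`scale` must be positive")
  sqrt(sum(((s - s_obs) / scale)^2))
}
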