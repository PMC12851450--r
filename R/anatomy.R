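# Anatomical scaffolds: scalar volumes, binary masks, synthetic atlases, IO.

#' Scalar 3D volume with voxel spacing
#'
#' A minimal container for a scalar image volume (e.g. a fractional-anisotropy
#' map), stored as a 3D numeric array of voxel values plus an isotropic voxel
#' edge length in micrometres.
#'
#' @param values 3D numeric array of finite, nonnegative values.
#' @param spacing_um Voxel edge length in micrometres (default 43).
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, spacing_um = 43) {
  if (!is.array(values) || length(dim(values)) != 3L)
    abort("`values` must be a 3D array")
  if (any(dim(values) < 1L)) abort("all three dimensions must be >= 1")
  if (!all(is.finite(values))) abort("`values` must be finite")
  if (any(values < 0)) abort("`values` must be nonnegative")
  if (!is.numeric(spacing_um) || length(spacing_um) != 1L || spacing_um <= 0)
    abort("`spacing_um` must be a single positive number")
  structure(list(values = values, spacing_um = as.numeric(spacing_um)),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat("<scalar_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels @ ", x$spacing_um, " um; range [",
      signif(min(x$values), 4), ", ", signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

#' Threshold a fractional-anisotropy volume into a white-matter mask
#'
#' Voxels with FA greater than or equal to the threshold are classified as
#' white matter (the comparison is inclusive).  The conventional cutoff for
#' separating coherent fiber tracts from gray matter is 0.5.
#'
#' @param vol A [scalar_volume()] or 3D numeric array with values in `[0, 1]`.
#' @param threshold Scalar threshold in `[0, 1]` (default 0.5).
#' @return A 3D logical array, `TRUE` where `values >= threshold`.
#' @export
threshold_fa <- function(vol, threshold = 0.5) {
  values <- if (inherits(vol, "scalar_volume")) vol$values else vol
  if (!is.array(values) || length(dim(values)) != 3L)
    abort("`vol` must be a scalar_volume or 3D array")
  if (!all(is.finite(values))) abort("FA values must be finite")
  if (any(values < 0 | values > 1)) abort("FA values must lie in [0, 1]")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    abort("`threshold` must be a single value in [0, 1]")
  values >= threshold
}

#' Co-registered anatomical atlas
#'
#' Bundles the three binary volumes the simulator reads — brain mask, white
#' matter mask, and blood-vessel mask — with their common voxel spacing.
#' White matter and vessels are forced to be subsets of the brain mask; this
#' is asserted on every construction.
#'
#' @param brain,wm,bv 3D logical arrays of identical shape.
#' @param spacing_um Voxel edge length in micrometres (default 43).
#' @return An object of class `anatomy_atlas` with elements `brain`, `wm`,
#'   `bv`, `spacing_um`, `dim`.
#' @export
anatomy_atlas <- function(brain, wm, bv, spacing_um = 43) {
  as_mask <- function(m, what) {
    if (is.array(m) && is.numeric(m)) m <- m > 0.5
    if (!is.array(m) || !is.logical(m) || length(dim(m)) != 3L)
      abort(paste0("`", what, "` must be a 3D logical array"))
    m
  }
  brain <- as_mask(brain, "brain")
  wm <- as_mask(wm, "wm")
  bv <- as_mask(bv, "bv")
  if (!identical(dim(brain), dim(wm)) || !identical(dim(brain), dim(bv)))
    abort("atlas masks must have identical shapes")
  if (!any(brain)) abort("brain mask must contain at least one voxel")
  if (any(wm & !brain)) abort("white matter mask must be a subset of the brain mask")
  if (any(bv & !brain)) abort("vessel mask must be a subset of the brain mask")
  structure(list(brain = brain, wm = wm, bv = bv,
                 spacing_um = as.numeric(spacing_um), dim = dim(brain)),
            class = "anatomy_atlas")
}

#' @export
print.anatomy_atlas <- function(x, ...) {
  cat("<anatomy_atlas> ", paste(x$dim, collapse = " x "), " voxels @ ",
      x$spacing_um, " um\n", sep = "")
  cat("  brain: ", sum(x$brain), " voxels; white matter: ", sum(x$wm),
      "; vessels: ", sum(x$bv), "\n", sep = "")
  invisible(x)
}

# ---- geometric primitives (voxel centers at integer coordinates, 1-based) ----

.grid_coords <- function(shape) {
  list(x = seq_len(shape[1]), y = seq_len(shape[2]), z = seq_len(shape[3]))
}

.mask_ellipsoid <- function(shape, center, semi_axes) {
  g <- .grid_coords(shape)
  dx2 <- ((g$x - center[1]) / semi_axes[1])^2
  dy2 <- ((g$y - center[2]) / semi_axes[2])^2
  dz2 <- ((g$z - center[3]) / semi_axes[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

.mask_slab <- function(shape, axis, center, thickness, quiet = FALSE) {
  planes <- round(center) + seq_len(thickness) - 1L - floor((thickness - 1) / 2)
  inside <- planes >= 1L & planes <= shape[axis]
  if (!all(inside)) {
    if (!quiet) warn("slab extends beyond the grid; clipped")
    planes <- planes[inside]
  }
  m <- array(FALSE, shape)
  idx <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  idx[[axis]] <- planes
  do.call(`[<-`, c(list(m), idx, list(value = TRUE)))
}

.mask_shell <- function(shape, center, radius, thickness, axis = 3,
                        max_polar_deg = 90, quiet = FALSE) {
  if (!quiet && (any(center - radius - thickness / 2 < 1) ||
                 any(center + radius + thickness / 2 > shape)))
    warn("shell extends beyond the grid; clipped")
  g <- .grid_coords(shape)
  dx <- g$x - center[1]; dy <- g$y - center[2]; dz <- g$z - center[3]
  r <- sqrt(outer(outer(dx^2, dy^2, "+"), dz^2, "+"))
  in_shell <- abs(r - radius) <= thickness / 2
  # polar angle from the positive `axis` direction
  axial <- switch(axis,
                  outer(outer(dx, dy * 0, "+"), dz * 0, "+"),
                  outer(outer(dx * 0, dy, "+"), dz * 0, "+"),
                  outer(outer(dx * 0, dy * 0, "+"), dz, "+"))
  cosang <- ifelse(r > 0, axial / pmax(r, 1e-12), 1)
  in_shell & cosang >= cos(max_polar_deg * pi / 180)
}

.mask_capsule <- function(shape, p0, p1, radius, quiet = FALSE) {
  if (!quiet && (any(pmin(p0, p1) - radius < 1) ||
                 any(pmax(p0, p1) + radius > shape)))
    warn("capsule extends beyond the grid; clipped")
  m <- array(FALSE, shape)
  lo <- pmax(floor(pmin(p0, p1) - radius), 1)
  hi <- pmin(ceiling(pmax(p0, p1) + radius), shape)
  if (any(lo > hi)) return(m)
  g <- lapply(1:3, function(a) lo[a]:hi[a])
  pts <- as.matrix(expand.grid(x = g[[1]], y = g[[2]], z = g[[3]]))
  v <- p1 - p0
  len2 <- sum(v^2)
  w <- sweep(pts, 2, p0)
  t <- if (len2 > 0) pmin(pmax(as.vector(w %*% v) / len2, 0), 1) else rep(0, nrow(pts))
  closest <- outer(t, v) + rep(p0, each = nrow(pts))
  d2 <- rowSums((pts - closest)^2)
  keep <- pts[d2 <= radius^2, , drop = FALSE]
  if (nrow(keep)) m[keep] <- TRUE
  m
}

.apply_tract_spec <- function(shape, spec, quiet = FALSE) {
  switch(spec$type,
         slab = .mask_slab(shape, spec$axis, spec$center, spec$thickness,
                           quiet = quiet),
         shell = .mask_shell(shape, spec$center, spec$radius, spec$thickness,
                             axis = spec$axis %||% 3,
                             max_polar_deg = spec$max_polar_deg %||% 90,
                             quiet = quiet),
         abort(paste0("unknown tract spec type: ", spec$type)))
}

.apply_vessel_spec <- function(shape, spec, quiet = FALSE) {
  if (!identical(spec$type, "capsule"))
    abort(paste0("unknown vessel spec type: ", spec$type))
  .mask_capsule(shape, spec$p0, spec$p1, spec$radius, quiet = quiet)
}

# random branching vessel tree as a list of capsule specs
.random_vessel_tree <- function(shape, root, direction, length0, radius0,
                                depth = 3) {
  specs <- list()
  grow <- function(p0, dir, len, radius, level) {
    dir <- dir / sqrt(sum(dir^2))
    p1 <- p0 + dir * len
    specs[[length(specs) + 1L]] <<- list(type = "capsule", p0 = p0, p1 = p1,
                                         radius = radius)
    if (level >= depth) return(invisible())
    for (k in 1:2) {
      jitter <- runif(3, -0.8, 0.8)
      grow(p1, dir + jitter, len * 0.65, max(radius * 0.6, 1), level + 1L)
    }
  }
  grow(root, direction, length0, radius0, 1L)
  specs
}

.default_tract_specs <- function(shape) {
  c0 <- shape / 2
  list(
    # corpus-callosum-like arc: a dorsal spherical shell section
    list(type = "shell", center = c(c0[1], c0[2], c0[3] - 0.15 * shape[3]),
         radius = 0.28 * min(shape), thickness = 3, axis = 3,
         max_polar_deg = 65),
    # a deep horizontal tract slab
    list(type = "slab", axis = 3, center = round(c0[3] - 0.25 * shape[3]),
         thickness = 3)
  )
}

.default_vessel_specs <- function(shape, n_trees = 3) {
  c0 <- shape / 2
  specs <- list()
  for (i in seq_len(n_trees)) {
    theta <- runif(1, 0, 2 * pi)
    phi <- runif(1, pi / 4, 3 * pi / 4)
    u <- c(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
    root <- c0 + u * 0.35 * min(shape)
    specs <- c(specs, .random_vessel_tree(shape, root, -u,
                                          length0 = 0.22 * min(shape),
                                          radius0 = 2.5, depth = 3))
  }
  specs
}

#' Generate a synthetic anatomical atlas
#'
#' Builds a desk-scale stand-in for a real mouse-brain atlas: an ellipsoidal
#' brain mask, white-matter tracts as unions of slabs and curved (dome-like)
#' shells emulating corpus-callosum-style arcs, and a vasculature mask as
#' unions of capsules forming branching trees that taper down to
#' capillary-scale (1-voxel-radius) tubes.  All structural masks are clipped
#' to the brain mask, so the atlas invariants hold by construction.
#'
#' @param shape Integer vector of length 3, grid dimensions (default
#'   `c(120, 120, 120)`).
#' @param spacing_um Voxel edge length in micrometres (default 43).
#' @param tract_specs List of tract primitives (`type = "slab"` or `"shell"`),
#'   `NULL` for a seeded default set, `list()` for none.
#' @param vessel_specs List of vessel primitives (`type = "capsule"` with
#'   `p0`, `p1`, `radius`), `NULL` for a seeded default branching network,
#'   `list()` for none.
#' @param brain Either `"ellipsoid"` (default) or `"full"` (whole grid); a
#'   full-grid brain is convenient for controlled experiments.
#' @param n_vessel_trees Number of random vessel trees when `vessel_specs` is
#'   `NULL`.
#' @param seed Integer seed; the atlas is reproducible bit-for-bit under a
#'   fixed seed.
#' @return An [anatomy_atlas()].
#' @export
generate_synthetic_atlas <- function(shape = c(120, 120, 120), spacing_um = 43,
                                     tract_specs = NULL, vessel_specs = NULL,
                                     brain = c("ellipsoid", "full"),
                                     n_vessel_trees = 3, seed = 1) {
  brain <- match.arg(brain)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) abort("`shape` must be 3 positive integers")
  build <- function() {
    brain_mask <- switch(brain,
                         full = array(TRUE, shape),
                         ellipsoid = .mask_ellipsoid(shape, (shape + 1) / 2,
                                                     0.45 * shape))
    # auto-generated structures clip at the grid silently; explicit user
    # specs that leave the grid are clipped with a warning
    ts_quiet <- is.null(tract_specs)
    vs_quiet <- is.null(vessel_specs)
    ts <- tract_specs %||% .default_tract_specs(shape)
    vs <- vessel_specs %||% .default_vessel_specs(shape, n_vessel_trees)
    wm <- array(FALSE, shape)
    for (s in ts) wm <- wm | .apply_tract_spec(shape, s, quiet = ts_quiet)
    bv <- array(FALSE, shape)
    for (s in vs) bv <- bv | .apply_vessel_spec(shape, s, quiet = vs_quiet)
    anatomy_atlas(brain_mask, wm & brain_mask, bv & brain_mask,
                  spacing_um = spacing_um)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- NIfTI IO ----

#' Read and write volumes as NIfTI
#'
#' Volumes and masks are stored as `.nii`/`.nii.gz` with the voxel spacing
#' (in micrometres) carried in the pixdim header fields.  Binary masks
#' round-trip exactly.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param vol A [scalar_volume()], 3D numeric array, or 3D logical mask.
#' @param spacing_um Spacing used when `vol` is a bare array.
#' @return `read_volume()` returns a [scalar_volume()]; `write_volume()`
#'   returns `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- abs(RNifti::pixdim(img)[1])
  scalar_volume(array(as.numeric(img), dim = dim(img)), spacing_um = spacing)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path, spacing_um = 43) {
  if (inherits(vol, "scalar_volume")) {
    values <- vol$values
    spacing_um <- vol$spacing_um
  } else {
    values <- vol
  }
  if (is.logical(values)) {
    storage.mode(values) <- "integer"
  }
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- rep(spacing_um, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read or write an atlas directory
#'
#' An atlas is stored as three NIfTI files (`brain.nii.gz`, `wm.nii.gz`,
#' `bv.nii.gz`) in one directory.  On read, shapes and spacings must agree
#' across the three members or an error is raised.
#'
#' @param atlas An [anatomy_atlas()].
#' @param dir Directory path.
#' @return `read_atlas()` returns an [anatomy_atlas()]; `write_atlas()`
#'   returns `dir` invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "anatomy_atlas"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(atlas$brain, file.path(dir, "brain.nii.gz"), atlas$spacing_um)
  write_volume(atlas$wm, file.path(dir, "wm.nii.gz"), atlas$spacing_um)
  write_volume(atlas$bv, file.path(dir, "bv.nii.gz"), atlas$spacing_um)
  invisible(dir)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(dir) {
  vols <- lapply(c("brain", "wm", "bv"), function(nm) {
    read_volume(file.path(dir, paste0(nm, ".nii.gz")))
  })
  dims <- lapply(vols, function(v) dim(v$values))
  if (!identical(dims[[1]], dims[[2]]) || !identical(dims[[1]], dims[[3]]))
    abort("atlas members have mismatched shapes")
  spac <- vapply(vols, function(v) v$spacing_um, numeric(1))
  if (max(spac) - min(spac) > 1e-6 * max(spac))
    abort("atlas members have mismatched voxel spacing")
  anatomy_atlas(vols[[1]]$values > 0.5, vols[[2]]$values > 0.5,
                vols[[3]]$values > 0.5, spacing_um = spac[1])
}
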