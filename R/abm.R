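# Stochastic lattice agent-based model with anatomy-biased migration.

#' Simulation parameters
#'
#' Per-step cell behavior is governed by a migration probability `p_m`, a
#' proliferation probability `p_p`, and two attraction weights: `w_wm` toward
#' white matter and `w_bv` toward blood vessels, constrained by
#' `w_wm + w_bv <= 1` (the remainder is the isotropic component of movement).
#' `K` is the per-voxel carrying capacity, `steps` the number of time steps,
#' and `d` the sensing radius (in voxels) within which cells perceive
#' anatomical structures.
#'
#' @param p_m,p_p Per-step migration and proliferation probabilities in
#'   `[0, 1]`.
#' @param w_wm,w_bv Attraction weights in `[0, 1]`, `w_wm + w_bv <= 1`.
#' @param K Carrying capacity, cells per voxel (default 3).
#' @param steps Number of time steps (default 1800).
#' @param d Sensing radius in voxels (default 5).
#' @param variant `"full"` (white matter and vasculature) or `"wm-only"`
#'   (vessel attraction dropped; `w_bv` forced to 0).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(p_m, p_p, w_wm = 0, w_bv = 0, K = 3, steps = 1800,
                       d = 5, variant = c("full", "wm-only")) {
  variant <- match.arg(variant)
  if (variant == "wm-only") w_bv <- 0
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
      abort(paste0("`", nm, "` must be a single value in [0, 1]"))
  }
  chk01(p_m, "p_m"); chk01(p_p, "p_p"); chk01(w_wm, "w_wm"); chk01(w_bv, "w_bv")
  if (w_wm + w_bv > 1 + 1e-12) abort("`w_wm + w_bv` must not exceed 1")
  if (K < 1) abort("`K` must be >= 1")
  if (steps < 0) abort("`steps` must be >= 0")
  if (d < 1) abort("`d` must be >= 1")
  structure(list(p_m = p_m, p_p = p_p, w_wm = w_wm, w_bv = w_bv,
                 K = as.integer(K), steps = as.integer(steps), d = d,
                 variant = variant),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> p_m=", x$p_m, " p_p=", x$p_p, " w_wm=", x$w_wm,
      " w_bv=", x$w_bv, " K=", x$K, " steps=", x$steps, " d=", x$d,
      " (", x$variant, ")\n", sep = "")
  invisible(x)
}

.new_lattice_state <- function(counts, t = 0L, newborn_counts = NULL) {
  if (is.null(newborn_counts)) newborn_counts <- array(0L, dim(counts))
  structure(list(counts = counts, newborn_counts = newborn_counts,
                 t = as.integer(t), n_cells = sum(counts)),
            class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  cat("<lattice_state> ", paste(dim(x$counts), collapse = " x "),
      " lattice, t=", x$t, ", ", x$n_cells, " cells in ",
      sum(x$counts > 0), " voxels\n", sep = "")
  invisible(x)
}

#' Seed an initial tumor
#'
#' Places `cells_per_voxel` cells in every lattice site whose Euclidean
#' distance from `center` is at most `radius` (inclusive), emulating the
#' injection bolus.  With the default radius 8 and 3 cells per voxel this
#' yields 6327 cells.  None of the seeded cells are flagged newborn.
#'
#' @param atlas An [anatomy_atlas()].
#' @param center Integer voxel coordinate (1-based); defaults to the grid
#'   midpoint.  Must lie inside the brain mask.
#' @param radius Sphere radius in grid points (default 8).
#' @param cells_per_voxel Cells seeded per voxel (default 3; must not exceed
#'   the carrying capacity used for the simulation).
#' @return A `lattice_state` at `t = 0`.
#' @export
initialize_tumor <- function(atlas, center = NULL, radius = 8,
                             cells_per_voxel = 3) {
  stopifnot(inherits(atlas, "anatomy_atlas"))
  dims <- atlas$dim
  if (is.null(center)) center <- round(dims / 2)
  center <- as.integer(round(center))
  if (length(center) != 3L) abort("`center` must be a voxel coordinate of length 3")
  if (any(center < 1L) || any(center > dims))
    abort("`center` lies outside the grid")
  if (!atlas$brain[center[1], center[2], center[3]])
    abort("`center` must lie inside the brain mask")
  r <- floor(radius)
  off <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  off <- off[rowSums(off^2) <= radius^2, , drop = FALSE]
  vox <- sweep(off, 2, center, "+")
  if (any(vox < 1L) || any(sweep(vox, 2, dims, ">") ))
    abort("initial sphere exceeds the grid bounds")
  inside <- atlas$brain[vox]
  if (!all(inside))
    abort("initial sphere extends outside the brain mask")
  counts <- array(0L, dims)
  counts[vox] <- as.integer(cells_per_voxel)
  .new_lattice_state(counts)
}

#' Unit direction between voxels
#'
#' The vector from `from` toward `to`, divided by its Euclidean length.
#' Identical voxels are an error (the direction is undefined); callers must
#' exclude a cell's own voxel.
#'
#' @param from,to Voxel coordinates (length-3 numeric).
#' @return A unit 3-vector.
#' @export
unit_direction <- function(from, to) {
  v <- as.numeric(to) - as.numeric(from)
  n <- sqrt(sum(v^2))
  if (n == 0) abort("`from` and `to` must be distinct voxels")
  v / n
}

#' Fold a unit direction into the 6 axis slots
#'
#' Maps a unit 3-vector onto nonnegative weights for the six von Neumann
#' directions, ordered (+x, -x, +y, -y, +z, -z).  Each component contributes
#' its magnitude to the slot matching its sign, so at most 3 slots are
#' nonzero and opposing slots are never both nonzero.
#'
#' @param v A unit 3-vector.
#' @return A named nonnegative 6-vector.
#' @export
direction_to_axis_weights <- function(v) {
  if (length(v) != 3L || !all(is.finite(v)))
    abort("`v` must be a finite 3-vector")
  if (abs(sqrt(sum(v^2)) - 1) > 1e-8)
    abort("`v` must have unit Euclidean norm")
  u <- c(max(v[1], 0), max(-v[1], 0),
         max(v[2], 0), max(-v[2], 0),
         max(v[3], 0), max(-v[3], 0))
  names(u) <- .dir_names
  u
}

.dir_names <- c("+x", "-x", "+y", "-y", "+z", "-z")

#' Direction distribution induced by a structure within sensing range
#'
#' Sums the axis-folded unit vectors toward every mask-true voxel within
#' Euclidean distance `d` of the cell (own voxel excluded), then
#' L1-normalizes into a probability distribution over the six directions.
#' If no structure voxel is in range the uniform distribution (1/6 each) is
#' returned, so the structure term degrades gracefully to isotropy.
#'
#' @param pos Cell voxel coordinate (1-based, length 3).
#' @param mask 3D logical array of structure voxels.
#' @param d Sensing radius in voxels (default 5, inclusive).
#' @return A named probability 6-vector summing to 1.
#' @export
structure_attraction <- function(pos, mask, d = 5) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, d >= 1)
  pos <- as.integer(round(pos))
  dims <- dim(mask)
  lo <- pmax(pos - floor(d), 1L)
  hi <- pmin(pos + floor(d), dims)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  idx <- which(sub, arr.ind = TRUE)
  u <- rep(0, 6)
  if (nrow(idx) > 0) {
    coords <- sweep(idx, 2, lo - 1L, "+")
    off <- sweep(coords, 2, pos)
    r2 <- rowSums(off^2)
    keep <- r2 > 0 & r2 <= d^2
    if (any(keep)) {
      off <- off[keep, , drop = FALSE]
      inv <- 1 / sqrt(r2[keep])
      u <- c(sum(pmax(off[, 1], 0) * inv), sum(pmax(-off[, 1], 0) * inv),
             sum(pmax(off[, 2], 0) * inv), sum(pmax(-off[, 2], 0) * inv),
             sum(pmax(off[, 3], 0) * inv), sum(pmax(-off[, 3], 0) * inv))
    }
  }
  s <- sum(u)
  p <- if (s > 0) u / s else rep(1 / 6, 6)
  names(p) <- .dir_names
  p
}

#' Mix isotropic, white-matter and vessel direction distributions
#'
#' The migration distribution is
#' `(1/6) (1 - w_wm - w_bv) + w_wm * P_wm + w_bv * P_bv`,
#' a convex combination of the isotropic distribution and the two structure
#' attraction distributions.
#'
#' @param P_wm,P_bv Probability 6-vectors from [structure_attraction()].
#' @param w_wm,w_bv Attraction weights with `w_wm + w_bv <= 1`.
#' @return A named probability 6-vector summing to 1.
#' @export
mixed_migration_distribution <- function(P_wm, P_bv, w_wm, w_bv) {
  if (w_wm < 0 || w_bv < 0 || w_wm + w_bv > 1 + 1e-12)
    abort("weights must be nonnegative with `w_wm + w_bv <= 1`")
  stopifnot(length(P_wm) == 6L, length(P_bv) == 6L)
  p <- (1 - w_wm - w_bv) / 6 + w_wm * P_wm + w_bv * P_bv
  names(p) <- .dir_names
  p
}

#' Precompute per-voxel attraction distributions for an atlas
#'
#' Because the anatomical masks do not change during a simulation, the
#' structure-attraction distribution of every voxel can be computed once and
#' reused by every cell at every step.  Pass the result to
#' [simulate_tumor()] when running many simulations on the same atlas.
#'
#' @param atlas An [anatomy_atlas()].
#' @param d Sensing radius in voxels (default 5).
#' @param structures Which fields to compute (default both).
#' @return An object of class `attraction_field` with per-voxel 6-column
#'   probability matrices `wm` and `bv`.
#' @export
attraction_field <- function(atlas, d = 5, structures = c("wm", "bv")) {
  stopifnot(inherits(atlas, "anatomy_atlas"))
  dims <- as.integer(atlas$dim)
  dom <- as.logical(atlas$brain)
  empty <- matrix(numeric(0), 0, 6)
  wm <- if ("wm" %in% structures)
    attraction_field_cpp(as.logical(atlas$wm), dims, d, dom) else empty
  bv <- if ("bv" %in% structures)
    attraction_field_cpp(as.logical(atlas$bv), dims, d, dom) else empty
  structure(list(wm = wm, bv = bv, d = d, dim = dims),
            class = "attraction_field")
}

.ensure_field <- function(field, atlas, params) {
  need <- c(if (params$w_wm > 0) "wm", if (params$w_bv > 0) "bv")
  if (length(need) == 0L)
    return(structure(list(wm = matrix(numeric(0), 0, 6),
                          bv = matrix(numeric(0), 0, 6),
                          d = params$d, dim = atlas$dim),
                     class = "attraction_field"))
  if (is.null(field)) return(attraction_field(atlas, d = params$d, structures = need))
  stopifnot(inherits(field, "attraction_field"))
  if (!isTRUE(all.equal(field$d, params$d)))
    abort("attraction field was computed with a different sensing radius")
  if ("wm" %in% need && nrow(field$wm) == 0) abort("field lacks the wm component")
  if ("bv" %in% need && nrow(field$bv) == 0) abort("field lacks the bv component")
  field
}

.run_core <- function(state, params, atlas, steps, seed = NULL, field = NULL,
                      q_mig = -1, treat_start = 0L) {
  stopifnot(inherits(state, "lattice_state"), inherits(params, "sim_params"),
            inherits(atlas, "anatomy_atlas"))
  if (!identical(dim(state$counts), atlas$dim))
    abort("state and atlas have different lattice shapes")
  field <- .ensure_field(field, atlas, params)
  run <- function() {
    run_abm_cpp(as.integer(state$counts), as.logical(atlas$brain),
                as.integer(atlas$dim), field$wm, field$bv,
                params$p_m, params$p_p, params$w_wm, params$w_bv,
                params$K, as.integer(steps), q_mig, as.integer(treat_start))
  }
  res <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  counts <- array(res$counts, atlas$dim)
  out <- .new_lattice_state(counts, t = state$t + steps)
  attr(out, "n_traj") <- res$n_traj
  attr(out, "births") <- res$births
  attr(out, "moves") <- res$moves
  attr(out, "moves_treatment") <- res$moves_treatment
  attr(out, "params") <- params
  out
}

#' Run the growth simulation
#'
#' Advances the lattice state by `steps` time steps (default `params$steps`).
#' Within a step, the cells alive at step start are processed in a uniformly
#' random permutation; each may first proliferate (if its voxel is below the
#' carrying capacity; offspring are inert until the next step) and then
#' attempt one von Neumann move drawn from the mixed migration distribution.
#' Moves into full voxels or off the brain mask are aborted.  Runs are
#' bit-reproducible under a fixed `seed`.
#'
#' @param params A [sim_params()].
#' @param atlas An [anatomy_atlas()].
#' @param init A `lattice_state` from [initialize_tumor()].
#' @param steps Number of steps (defaults to `params$steps`).
#' @param seed Optional integer seed for this simulation.
#' @param field Optional precomputed [attraction_field()].
#' @return The final `lattice_state`; attributes `n_traj` (total cell count
#'   after every step), `births`, `moves` carry run summaries.
#' @export
simulate_tumor <- function(params, atlas, init, steps = NULL, seed = NULL,
                           field = NULL) {
  .run_core(init, params, atlas, steps %||% params$steps, seed = seed,
            field = field)
}

#' Advance a lattice state by one step
#'
#' @inheritParams simulate_tumor
#' @param state The current `lattice_state`.
#' @return The `lattice_state` after one time step.
#' @export
step_tumor <- function(state, params, atlas, seed = NULL, field = NULL) {
  .run_core(state, params, atlas, 1L, seed = seed, field = field)
}

#' Occupied voxels as a tibble
#'
#' @param state A `lattice_state`.
#' @return A tibble with columns `x`, `y`, `z`, `count` for voxels holding at
#'   least one cell.
#' @export
occupied_voxels <- function(state) {
  stopifnot(inherits(state, "lattice_state"))
  idx <- which(state$counts > 0, arr.ind = TRUE)
  tibble::tibble(x = as.integer(idx[, 1]), y = as.integer(idx[, 2]),
                 z = as.integer(idx[, 3]),
                 count = as.integer(state$counts[idx]))
}
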