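# Benchmark orchestration and provenance.

#' The 16-corner ground-truth design
#'
#' Every combination of a low and a high value for each of the four model
#' parameters: `p_m` in {0.2, 1}, `p_p` in {0.0005, 0.005}, `w_wm` in
#' {0.1, 0.45}, `w_bv` in {0.1, 0.45}.
#'
#' @return A 16-row tibble with `case`, `p_m`, `p_p`, `w_wm`, `w_bv`.
#' @export
benchmark_truth_grid <- function() {
  g <- tidyr::expand_grid(p_m = c(0.2, 1), p_p = c(0.0005, 0.005),
                          w_wm = c(0.1, 0.45), w_bv = c(0.1, 0.45))
  dplyr::bind_cols(tibble::tibble(case = seq_len(nrow(g))), g)
}

#' Benchmark configuration
#'
#' Desk-scale defaults for the synthetic parameter-recovery study: a 64^3
#' synthetic atlas, 300 steps per simulation from a radius-4 seed sphere, a
#' shared prior pool of 400 simulations, and a 5% acceptance fraction.
#'
#' @param atlas_shape Grid dimensions of the synthetic atlas.
#' @param spacing_um Voxel spacing in micrometres.
#' @param n_sims Size of the prior simulation pool.
#' @param accept_frac Fraction of the pool accepted per case.
#' @param steps Time steps per simulation.
#' @param init_radius,cells_per_voxel Initial sphere radius and seeding
#'   density.
#' @param K,d Carrying capacity and sensing radius.
#' @param slice_axis,slice_index Slice compared between simulation and
#'   observation; `slice_index = NULL` means the mid-plane through the
#'   injection site.
#' @param seed Master seed; every other seed is derived from it.
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(atlas_shape = c(64, 64, 64), spacing_um = 43,
                             n_sims = 400, accept_frac = 0.05, steps = 300,
                             init_radius = 4, cells_per_voxel = 3, K = 3,
                             d = 5, slice_axis = 3, slice_index = NULL,
                             seed = 1) {
  if (n_sims * accept_frac < 1) abort("`n_sims * accept_frac` must be >= 1")
  structure(list(atlas_shape = atlas_shape, spacing_um = spacing_um,
                 n_sims = n_sims, accept_frac = accept_frac, steps = steps,
                 init_radius = init_radius, cells_per_voxel = cells_per_voxel,
                 K = K, d = d, slice_axis = slice_axis,
                 slice_index = slice_index, seed = seed),
            class = "benchmark_config")
}

#' Scaled-down parameter-recovery benchmark
#'
#' Replicates, at desk scale, the synthetic study comparing three fitting
#' methods: rejection ABC with the Jaccard distance, rejection ABC with the
#' geometric summary-statistic distance, and the geometric distance followed
#' by regression adjustment.  For each of the 16 ground-truth corners an
#' observed slice is simulated; a single shared prior pool (independent of
#' every observation) is fitted against each case under each method, and the
#' mean relative error E over the accepted (or adjusted) parameter sets is
#' reported.
#'
#' @param config A [benchmark_config()].
#' @param methods Which methods to run.
#' @param verbose Print progress.
#' @return A tibble with `case`, the true parameters, `method`, `E`, `delta`;
#'   attribute `config` carries the configuration.
#' @export
run_benchmark_study <- function(config = benchmark_config(),
                                methods = c("jaccard_direct",
                                            "geometric_direct",
                                            "geometric_regression"),
                                verbose = FALSE) {
  stopifnot(inherits(config, "benchmark_config"))
  methods <- match.arg(methods, several.ok = TRUE)
  seeds <- withr::with_seed(as.integer(config$seed),
                            sample.int(.Machine$integer.max - 1L, 18L))
  atlas_seed <- seeds[1]; pool_seed <- seeds[2]; obs_seeds <- seeds[3:18]

  atlas <- generate_synthetic_atlas(shape = config$atlas_shape,
                                    spacing_um = config$spacing_um,
                                    seed = atlas_seed)
  field <- attraction_field(atlas, d = config$d)
  init <- initialize_tumor(atlas, radius = config$init_radius,
                           cells_per_voxel = config$cells_per_voxel)
  slice_index <- config$slice_index %||%
    round(config$atlas_shape[config$slice_axis] / 2)
  truth <- benchmark_truth_grid()
  prior <- prior_spec()

  if (verbose) inform("simulating observed tumors for the 16 ground-truth cases")
  observed <- purrr::map(seq_len(nrow(truth)), function(i) {
    sp <- sim_params(truth$p_m[i], truth$p_p[i], truth$w_wm[i], truth$w_bv[i],
                     K = config$K, steps = config$steps, d = config$d)
    st <- simulate_tumor(sp, atlas, init, seed = obs_seeds[i], field = field)
    extract_slice(st, axis = config$slice_axis, index = slice_index,
                  spacing_um = config$spacing_um)
  })

  if (verbose) inform(paste0("simulating the shared prior pool (",
                             config$n_sims, " simulations)"))
  draws <- sample_prior(config$n_sims, prior, seed = pool_seed)
  pool <- simulate_pool(draws, atlas, init, steps = config$steps,
                        slice_axis = config$slice_axis,
                        slice_index = slice_index, K = config$K, d = config$d,
                        field = field, seed = pool_seed, keep_slices = TRUE)

  rows <- purrr::map(seq_len(nrow(truth)), function(i) {
    if (verbose) inform(paste0("fitting case ", i, "/16"))
    tru <- c(p_m = truth$p_m[i], p_p = truth$p_p[i], w_wm = truth$w_wm[i],
             w_bv = truth$w_bv[i])
    one <- function(method) {
      fit <- switch(method,
        jaccard_direct = abc_fit(pool, observed[[i]],
                                 accept_frac = config$accept_frac,
                                 prior = prior, adjust = FALSE,
                                 distance = "jaccard"),
        geometric_direct = abc_fit(pool, observed[[i]],
                                   accept_frac = config$accept_frac,
                                   prior = prior, adjust = FALSE,
                                   distance = "geometric"),
        geometric_regression = abc_fit(pool, observed[[i]],
                                       accept_frac = config$accept_frac,
                                       prior = prior, adjust = TRUE,
                                       distance = "geometric"))
      theta <- if (fit$was_adjusted) fit$adjusted else
        fit$accepted[, setdiff(names(fit$accepted), "distance")]
      err <- estimation_error(tru, theta)
      tibble::tibble(case = i, p_m = tru[["p_m"]], p_p = tru[["p_p"]],
                     w_wm = tru[["w_wm"]], w_bv = tru[["w_bv"]],
                     method = method, E = err$E, delta = fit$delta)
    }
    dplyr::bind_rows(purrr::map(methods, one))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  out
}

#' Provenance sidecar for a pipeline run
#'
#' Records everything needed to reproduce a run bit-for-bit: the master seed,
#' a hash of the configuration, the package version, and optional hashes of
#' the atlas and of the outputs.  [verify_provenance()] recomputes the hashes
#' and flags any mismatch (e.g. a tampered configuration).
#'
#' @param seed Master seed of the run.
#' @param config Configuration object (any R list).
#' @param atlas Optional [anatomy_atlas()] used by the run.
#' @param outputs Optional run outputs to fingerprint.
#' @return A `provenance_record` list.
#' @export
provenance_record <- function(seed, config, atlas = NULL, outputs = NULL) {
  rec <- list(package = "gliomalatt",
              version = as.character(packageVersion("gliomalatt")),
              seed = as.integer(seed),
              config_hash = rlang::hash(config),
              atlas_hash = if (!is.null(atlas)) rlang::hash(atlas),
              output_hash = if (!is.null(outputs)) rlang::hash(outputs))
  structure(rec[!vapply(rec, is.null, logical(1))],
            class = "provenance_record")
}

#' @rdname provenance_record
#' @param record A `provenance_record`.
#' @return `verify_provenance()` returns `TRUE` if every supplied component
#'   matches the record, otherwise `FALSE` with attribute `mismatches`.
#' @export
verify_provenance <- function(record, config = NULL, atlas = NULL,
                              outputs = NULL) {
  bad <- character()
  if (!is.null(config) && !identical(rlang::hash(config), record$config_hash))
    bad <- c(bad, "config")
  if (!is.null(atlas) && !identical(rlang::hash(atlas), record$atlas_hash))
    bad <- c(bad, "atlas")
  if (!is.null(outputs) && !identical(rlang::hash(outputs), record$output_hash))
    bad <- c(bad, "outputs")
  structure(length(bad) == 0L, mismatches = bad)
}

#' @rdname provenance_record
#' @param path JSON file path.
#' @export
write_provenance <- function(record, path) {
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname provenance_record
#' @export
read_provenance <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "provenance_record")
}
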