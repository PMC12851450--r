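# In-silico anti-migration / anti-proliferation drug-mix experiments.

#' Treatment schedule
#'
#' Tumors grow untreated for `pre_days`, are treated for `treat_days`, and
#' are compared to an untreated control grown for the full horizon
#' (`pre_days + treat_days`).  Days are mapped to lattice steps at a fixed
#' rate (default 20 steps/day, i.e. 1800 steps per 90 days).  The drug-mix
#' grid runs from pure anti-migration (1.0) to pure anti-proliferation (0.0).
#'
#' @param pre_days Untreated growth before treatment (default 30).
#' @param treat_days Treated growth (default 60).
#' @param steps_per_day Lattice steps per simulated day (default 20).
#' @param mix_step Grid spacing of the anti-migration fraction (default 0.1).
#' @return An object of class `treatment_schedule`.
#' @export
treatment_schedule <- function(pre_days = 30, treat_days = 60,
                               steps_per_day = 20, mix_step = 0.1) {
  if (pre_days < 0 || treat_days <= 0) abort("invalid schedule durations")
  structure(list(pre_days = pre_days, treat_days = treat_days,
                 control_days = pre_days + treat_days,
                 steps_per_day = steps_per_day,
                 pre_steps = as.integer(round(pre_days * steps_per_day)),
                 treat_steps = as.integer(round(treat_days * steps_per_day)),
                 mix_grid = seq(1, 0, by = -abs(mix_step))),
            class = "treatment_schedule")
}

#' Simulate growth with a treatment phase
#'
#' Identical dynamics to [simulate_tumor()] for the first `pre_steps` steps;
#' from then on each acting cell independently draws, every step, which
#' mechanism the drug mix blocks: with probability `q_mig` its migration
#' attempt is suppressed for that step, otherwise its proliferation attempt
#' is suppressed.
#'
#' @inheritParams simulate_tumor
#' @param q_mig Anti-migration fraction of the drug mix, in `[0, 1]`.
#' @param pre_steps,treat_steps Steps before and during treatment.
#' @return The final `lattice_state`; attribute `moves_treatment` counts
#'   migration events that occurred during the treatment phase.
#' @export
simulate_treated <- function(params, atlas, init, q_mig, pre_steps,
                             treat_steps, seed = NULL, field = NULL) {
  if (q_mig < 0 || q_mig > 1) abort("`q_mig` must be in [0, 1]")
  .run_core(init, params, atlas, steps = pre_steps + treat_steps, seed = seed,
            field = field, q_mig = q_mig, treat_start = pre_steps)
}

#' Volume of the convex hull of the tumor
#'
#' The convex hull of the occupied voxel centers, a proxy for the spatial
#' spread of the tumor that the raw cell count does not capture.  Degenerate
#' point sets (single voxel, colinear, coplanar) have volume 0.
#'
#' @param x A `lattice_state` or an integer matrix of voxel coordinates
#'   (rows = points).
#' @return Hull volume in voxel units cubed.
#' @export
convex_hull_volume <- function(x) {
  pts <- if (inherits(x, "lattice_state")) {
    as.matrix(occupied_voxels(x)[, c("x", "y", "z")])
  } else {
    as.matrix(x)
  }
  if (nrow(pts) == 0L) abort("empty tumor: the convex hull is undefined")
  if (ncol(pts) != 3L) abort("points must have 3 columns")
  storage.mode(pts) <- "integer"
  # reduce to per-column extremes along x: interior points cannot be hull
  # vertices
  key <- paste(pts[, 2], pts[, 3], sep = ",")
  keep <- unlist(lapply(split(seq_len(nrow(pts)), key), function(i) {
    i[c(which.min(pts[i, 1]), which.max(pts[i, 1]))]
  }), use.names = FALSE)
  convex_hull_volume_cpp(pts[unique(keep), , drop = FALSE])
}

#' Sweep drug-mix combinations and compare to untreated controls
#'
#' For every anti-migration fraction in the schedule's mix grid and every
#' seed, grows a tumor untreated for the pre-treatment phase and treated for
#' the treatment phase, and compares its final cell count and convex-hull
#' volume to an untreated control grown for the full horizon with the same
#' seed.
#'
#' @inheritParams simulate_tumor
#' @param schedule A [treatment_schedule()].
#' @param seeds Integer vector of replicate seeds.
#' @param include_sham Also run a sham arm (`mix = NA`): an untreated
#'   replicate on the control's seed stream, whose relative measures are
#'   exactly 1 by construction.
#' @return A tibble of class `treatment_sweep` with columns `mix`, `seed`,
#'   `cells_treated`, `cells_control`, `hull_treated`, `hull_control`,
#'   `rel_cells`, `rel_hull`.
#' @export
run_treatment_sweep <- function(params, atlas, init,
                                schedule = treatment_schedule(),
                                seeds = 1:5, field = NULL,
                                include_sham = FALSE) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  field <- .ensure_field(field, atlas, params)
  total_steps <- schedule$pre_steps + schedule$treat_steps
  ratio <- function(t, c) ifelse(c == 0 & t == 0, 1, t / c)
  rows <- purrr::map(seeds, function(sd) {
    control <- simulate_tumor(params, atlas, init, steps = total_steps,
                              seed = sd, field = field)
    cc <- control$n_cells
    hc <- convex_hull_volume(control)
    mixes <- c(if (include_sham) NA_real_, schedule$mix_grid)
    purrr::map(mixes, function(mx) {
      treated <- if (is.na(mx)) {
        simulate_tumor(params, atlas, init, steps = total_steps, seed = sd,
                       field = field)
      } else {
        simulate_treated(params, atlas, init, q_mig = mx,
                         pre_steps = schedule$pre_steps,
                         treat_steps = schedule$treat_steps, seed = sd,
                         field = field)
      }
      ct <- treated$n_cells
      ht <- convex_hull_volume(treated)
      tibble::tibble(mix = mx, seed = sd, cells_treated = ct,
                     cells_control = cc, hull_treated = ht, hull_control = hc,
                     rel_cells = ratio(ct, cc), rel_hull = ratio(ht, hc))
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  class(out) <- c("treatment_sweep", class(out))
  out
}

#' @rdname run_treatment_sweep
#' @param object A `treatment_sweep` tibble.
#' @param ... Unused.
#' @method autoplot treatment_sweep
#' @export
autoplot.treatment_sweep <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$mix))
  df <- dplyr::summarise(dplyr::group_by(df, .data$mix),
                         `relative cell count` = mean(.data$rel_cells),
                         `relative convex hull` = mean(.data$rel_hull),
                         .groups = "drop")
  df <- tidyr::pivot_longer(df, -"mix", names_to = "measure",
                            values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mix, y = .data$value,
                                   colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "anti-migration fraction of drug mix",
                  y = "treated / untreated", colour = NULL) +
    ggplot2::theme_minimal()
}
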