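# Rejection ABC with local-linear regression adjustment, point estimation,
# error metrics, model comparison, and physical-unit rescaling.

#' Uniform prior specification
#'
#' Independent uniform priors for the four model parameters, with the joint
#' simplex constraint `w_wm + w_bv <= 1` enforced at sampling time by
#' rejection resampling.
#'
#' @param p_m,p_p,w_wm,w_bv Numeric ranges `c(lower, upper)`.
#' @return An object of class `prior_spec` (named list of ranges).
#' @export
prior_spec <- function(p_m = c(0, 1), p_p = c(0, 0.015), w_wm = c(0, 1),
                       w_bv = c(0, 1)) {
  ranges <- list(p_m = p_m, p_p = p_p, w_wm = w_wm, w_bv = w_bv)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2])
      abort(paste0("prior range for `", nm, "` must satisfy lower < upper"))
  }
  structure(ranges, class = "prior_spec")
}

#' Sample parameter sets from the prior
#'
#' Draws uniformly within each range; `(w_wm, w_bv)` pairs violating the
#' simplex constraint are rejected and redrawn, so the joint density is
#' uniform on the admissible triangle.  The white-matter-only model variant
#' fixes `w_bv = 0`.
#'
#' @param n Number of parameter sets.
#' @param prior A [prior_spec()].
#' @param variant `"full"` or `"wm-only"`.
#' @param seed Optional integer seed.
#' @return A tibble with columns `p_m`, `p_p`, `w_wm`, `w_bv`.
#' @export
sample_prior <- function(n, prior = prior_spec(), variant = c("full", "wm-only"),
                         seed = NULL) {
  variant <- match.arg(variant)
  if (n < 1) abort("`n` must be >= 1")
  draw <- function() {
    ru <- function(r, m) runif(m, r[1], r[2])
    out <- tibble::tibble(p_m = ru(prior$p_m, n), p_p = ru(prior$p_p, n),
                          w_wm = ru(prior$w_wm, n),
                          w_bv = if (variant == "wm-only") 0 else ru(prior$w_bv, n))
    bad <- which(out$w_wm + out$w_bv > 1)
    while (length(bad) > 0) {
      out$w_wm[bad] <- ru(prior$w_wm, length(bad))
      out$w_bv[bad] <- ru(prior$w_bv, length(bad))
      bad <- bad[out$w_wm[bad] + out$w_bv[bad] > 1]
    }
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Simulate a pool of parameter sets and summarize their slices
#'
#' Runs one simulation per parameter set (the stochastic variability between
#' runs is absorbed into the posterior), extracts a fixed slice, and computes
#' the geometric summary statistics.  Per-simulation seeds are derived from
#' `seed` so the whole pool is reproducible.
#'
#' @param params A tibble with columns `p_m`, `p_p`, `w_wm`, `w_bv`.
#' @param atlas An [anatomy_atlas()].
#' @param init A `lattice_state` from [initialize_tumor()].
#' @param steps Time steps per simulation.
#' @param slice_axis,slice_index Slice specification (see [extract_slice()]);
#'   `slice_index` defaults to the mid-plane.
#' @param K,d Carrying capacity and sensing radius for every simulation.
#' @param field Optional precomputed [attraction_field()].
#' @param seed Integer seed for the pool.
#' @param keep_slices Keep the binary slices (needed for Jaccard-based
#'   fitting); default `TRUE`.
#' @return A tibble: the parameter columns, `sim_seed`, the 8 summary-statistic
#'   columns, `n_cells`, and (optionally) a `slice` list-column.
#' @export
simulate_pool <- function(params, atlas, init, steps = 1800, slice_axis = 3,
                          slice_index = NULL, K = 3, d = 5, field = NULL,
                          seed = NULL, keep_slices = TRUE) {
  stopifnot(is.data.frame(params),
            all(c("p_m", "p_p", "w_wm", "w_bv") %in% names(params)))
  n <- nrow(params)
  slice_index <- slice_index %||% round(atlas$dim[slice_axis] / 2)
  sim_seeds <- if (is.null(seed)) sample.int(.Machine$integer.max - 1L, n)
  else withr::with_seed(as.integer(seed),
                        sample.int(.Machine$integer.max - 1L, n))
  if (is.null(field)) field <- attraction_field(atlas, d = d)
  res <- purrr::map(seq_len(n), function(i) {
    sp <- sim_params(params$p_m[i], params$p_p[i], params$w_wm[i],
                     params$w_bv[i], K = K, steps = steps, d = d)
    st <- simulate_tumor(sp, atlas, init, seed = sim_seeds[i], field = field)
    sl <- extract_slice(st, axis = slice_axis, index = slice_index,
                        spacing_um = atlas$spacing_um)
    list(stats = summary_statistics(sl), n_cells = st$n_cells,
         slice = if (keep_slices) sl$pixels else NULL)
  })
  stats <- do.call(rbind, purrr::map(res, "stats"))
  out <- dplyr::bind_cols(
    tibble::as_tibble(params[, c("p_m", "p_p", "w_wm", "w_bv")]),
    tibble::tibble(sim_seed = sim_seeds),
    tibble::as_tibble(stats),
    tibble::tibble(n_cells = purrr::map_dbl(res, "n_cells")))
  if (keep_slices) out$slice <- purrr::map(res, "slice")
  out
}

#' Rejection step: keep the closest fraction of simulations
#'
#' Retains the `round(accept_frac * n)` simulations with the smallest
#' distances (ties broken by simulation index) and reports `delta`, the
#' largest accepted distance — the acceptance threshold, an inverse measure
#' of fit quality.
#'
#' @param distances Finite numeric vector of simulation-to-observation
#'   distances.
#' @param accept_frac Fraction to accept (default 0.01, the top 1% rule).
#' @return A list with `indices` (in increasing distance order), `delta`,
#'   and `n_accept`.
#' @export
abc_rejection <- function(distances, accept_frac = 0.01) {
  if (!all(is.finite(distances))) abort("`distances` must be finite")
  n <- length(distances)
  k <- as.integer(round(accept_frac * n))
  if (k < 1L) abort("`accept_frac * n` must be at least 1")
  ord <- order(distances)  # stable: ties keep index order
  idx <- ord[seq_len(k)]
  list(indices = idx, delta = distances[idx[k]], n_accept = k)
}

.logit_unit <- function(x, eps = 1e-12) qlogis(pmin(pmax(x, eps), 1 - eps))

#' Local-linear regression adjustment of accepted parameters
#'
#' Each accepted parameter is mapped to its prior range by a logit transform,
#' regressed on the (standardized) discrepancy between simulated and observed
#' summary statistics by weighted least squares with Epanechnikov weights
#' `1 - (distance / delta)^2`, and shifted to the regression value at the
#' observed statistics; back-transforming guarantees the adjusted samples lie
#' strictly inside the prior ranges.  Parameters that are constant over the
#' accepted set (e.g. `w_bv` in the white-matter-only variant) pass through
#' unchanged.  Adjusted `(w_wm, w_bv)` pairs that leave the simplex are
#' projected back onto it radially.
#'
#' @param theta Tibble of accepted parameters (columns among `p_m`, `p_p`,
#'   `w_wm`, `w_bv`).
#' @param stats Numeric matrix (accepted x components) of their summary
#'   statistics.
#' @param s_obs Observed summary statistics.
#' @param distances Accepted distances.
#' @param delta Acceptance threshold (regression kernel bandwidth).
#' @param prior A [prior_spec()].
#' @param scale Per-component scale used for the distances (default 1).
#' @return A tibble of adjusted parameters; attribute `n_projected` counts
#'   simplex projections, attribute `adjusted` records whether the regression
#'   was applied.
#' @export
abc_regression_adjust <- function(theta, stats, s_obs, distances, delta,
                                  prior = prior_spec(), scale = 1) {
  theta <- tibble::as_tibble(theta)
  stats <- as.matrix(stats)
  n <- nrow(theta)
  fallback <- function(msg) {
    if (!is.null(msg)) warn(msg)
    structure(theta, adjusted = FALSE, n_projected = 0L)
  }
  if (delta <= 0) return(fallback(NULL))  # all simulations match exactly
  if (n < ncol(stats) + 2L)
    return(fallback("too few accepted points for regression adjustment; returning unadjusted samples"))
  X <- sweep(stats, 2, s_obs)
  X <- sweep(X, 2, rep_len(scale, ncol(X)), "/")
  w <- pmax(1 - (distances / delta)^2, 0)
  if (sum(w > 0) < ncol(X) + 2L)
    return(fallback("regression weights are degenerate; returning unadjusted samples"))
  adj <- theta
  for (nm in names(theta)) {
    r <- prior[[nm]]
    x <- theta[[nm]]
    if (is.null(r) || .sd_pop(x) == 0) next  # constant: nothing to adjust
    z <- .logit_unit((x - r[1]) / (r[2] - r[1]))
    fit <- lm.wfit(cbind(1, X), z, w)
    b <- fit$coefficients[-1]
    b[is.na(b)] <- 0  # rank-deficient directions carry no adjustment
    z_adj <- z - drop(X %*% b)
    adj[[nm]] <- r[1] + (r[2] - r[1]) * plogis(z_adj)
  }
  n_proj <- 0L
  if (all(c("w_wm", "w_bv") %in% names(adj))) {
    s <- adj$w_wm + adj$w_bv
    viol <- which(s > 1)
    n_proj <- length(viol)
    if (n_proj > 0) {
      adj$w_wm[viol] <- adj$w_wm[viol] / s[viol]
      adj$w_bv[viol] <- adj$w_bv[viol] / s[viol]
      inform(paste0(n_proj, " adjusted sample(s) projected back onto the w-simplex"))
    }
  }
  structure(adj, adjusted = TRUE, n_projected = n_proj)
}

#' Posterior point estimate by bounded kernel density smoothing
#'
#' The sample is rescaled to `[0, 1]` by its prior range, smoothed with an
#' Epanechnikov kernel of bandwidth 1/10 (so the bandwidth means the same
#' thing for every parameter regardless of its natural scale), truncated and
#' renormalized to the unit interval, and summarized by the mean of the
#' resulting density; the 10% and 90% quantiles of the density are reported
#' alongside.
#'
#' @param x Numeric sample (inside the prior range).
#' @param range Prior range `c(lower, upper)`.
#' @param bandwidth Kernel bandwidth on the unit scale (default 1/10).
#' @param grid_n Quadrature grid size (default 2001).
#' @return A list with `estimate`, `q10`, `q90` in natural units.
#' @export
posterior_point_estimate <- function(x, range, bandwidth = 0.1,
                                     grid_n = 2001) {
  lo <- range[1]; hi <- range[2]
  if (any(x < lo - 1e-12) || any(x > hi + 1e-12))
    abort("samples must lie within the prior range")
  z <- (x - lo) / (hi - lo)
  g <- seq(0, 1, length.out = grid_n)
  u <- outer(g, z, "-") / bandwidth
  f <- rowSums(ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0))
  dx <- g[2] - g[1]
  # trapezoid quadrature on the truncated, renormalized density
  tw <- c(0.5, rep(1, grid_n - 2L), 0.5) * dx
  total <- sum(f * tw)
  if (total <= 0) abort("degenerate density")
  mean_z <- sum(g * f * tw) / total
  cdf <- cumsum(f * tw) / total
  qs <- approx(cdf, g, xout = c(0.1, 0.9), ties = "ordered", rule = 2)$y
  list(estimate = lo + (hi - lo) * mean_z,
       q10 = lo + (hi - lo) * qs[1],
       q90 = lo + (hi - lo) * qs[2])
}

.point_estimates <- function(theta, prior) {
  purrr::map_dfr(names(theta), function(nm) {
    r <- prior[[nm]]
    x <- theta[[nm]]
    if (is.null(r)) return(NULL)
    if (.sd_pop(x) == 0) {
      return(tibble::tibble(parameter = nm, estimate = x[1], q10 = x[1],
                            q90 = x[1], sample_q10 = x[1], sample_q90 = x[1]))
    }
    pe <- posterior_point_estimate(x, r)
    sq <- unname(stats::quantile(x, c(0.1, 0.9)))
    tibble::tibble(parameter = nm, estimate = pe$estimate, q10 = pe$q10,
                   q90 = pe$q90, sample_q10 = sq[1], sample_q90 = sq[2])
  })
}

#' Fit the growth model to an observed tumor slice by ABC
#'
#' Given a pool of simulated parameter sets with their summary statistics
#' (from [simulate_pool()]) and an observed binary slice, performs rejection
#' ABC — with either the standardized geometric summary-statistic distance or
#' one minus the Jaccard index as the distance — optionally followed by
#' local-linear regression adjustment, and computes kernel-density point
#' estimates with 10%/90% percentiles.
#'
#' @param pool Tibble from [simulate_pool()].
#' @param observed A `tumor_slice`, binary matrix, or (for
#'   `distance = "geometric"` only) a summary-statistic vector.
#' @param accept_frac Fraction of simulations to accept (default 0.01).
#' @param prior The [prior_spec()] the pool was drawn from.
#' @param adjust Apply regression adjustment (default `TRUE`; only available
#'   for the geometric distance).
#' @param distance `"geometric"` (standardized summary statistics) or
#'   `"jaccard"` (1 - overlap).
#' @return An object of class `abc_fit`.
#' @export
abc_fit <- function(pool, observed, accept_frac = 0.01, prior = prior_spec(),
                    adjust = TRUE, distance = c("geometric", "jaccard")) {
  distance <- match.arg(distance)
  par_names <- intersect(c("p_m", "p_p", "w_wm", "w_bv"), names(pool))
  stats <- as.matrix(pool[, .stat_names])
  scale <- stat_scale(stats)
  if (distance == "geometric") {
    s_obs <- if (is.numeric(observed) && !is.matrix(observed)) observed
    else summary_statistics(observed)
    d <- apply(stats, 1, summary_distance, s_obs = s_obs, scale = scale)
  } else {
    if (!"slice" %in% names(pool))
      abort("Jaccard fitting needs a pool built with `keep_slices = TRUE`")
    obs_px <- .slice_pixels(observed)
    d <- purrr::map_dbl(pool$slice, function(s) 1 - jaccard_index(s, obs_px))
    s_obs <- NULL
    if (adjust) {
      warn("regression adjustment is not defined for the Jaccard distance; fitting directly")
      adjust <- FALSE
    }
  }
  rej <- abc_rejection(d, accept_frac)
  accepted <- tibble::as_tibble(pool[rej$indices, par_names])
  accepted$distance <- d[rej$indices]
  theta <- accepted[, par_names]
  adjusted <- if (adjust) {
    abc_regression_adjust(theta, stats[rej$indices, , drop = FALSE], s_obs,
                          accepted$distance, rej$delta, prior, scale)
  } else {
    structure(theta, adjusted = FALSE, n_projected = 0L)
  }
  structure(
    list(accepted = accepted, adjusted = adjusted, delta = rej$delta,
         scale = scale, s_obs = s_obs, accept_frac = accept_frac,
         n_sims = nrow(pool), distance = distance,
         was_adjusted = isTRUE(attr(adjusted, "adjusted")),
         estimates = .point_estimates(adjusted, prior), prior = prior),
    class = "abc_fit")
}

#' @export
print.abc_fit <- function(x, ...) {
  cat("<abc_fit> ", x$n_sims, " simulations, ", nrow(x$accepted),
      " accepted (", x$distance, " distance), delta = ", signif(x$delta, 4),
      if (x$was_adjusted) ", regression-adjusted" else "", "\n", sep = "")
  print(x$estimates)
  invisible(x)
}

#' @rdname abc_fit
#' @param x An `abc_fit` object.
#' @param ... Unused.
#' @method tidy abc_fit
#' @export
tidy.abc_fit <- function(x, ...) x$estimates

#' @rdname abc_fit
#' @method glance abc_fit
#' @export
glance.abc_fit <- function(x, ...) {
  tibble::tibble(n_sims = x$n_sims, n_accepted = nrow(x$accepted),
                 accept_frac = x$accept_frac, delta = x$delta,
                 distance = x$distance, adjusted = x$was_adjusted)
}

#' Relative estimation error of accepted parameter sets
#'
#' For each accepted (or adjusted) parameter set, the absolute relative error
#' averaged over the model parameters; the method error `E` is the mean of
#' these per-set errors.  True parameter values must be nonzero.
#'
#' @param truth Named numeric vector of true parameter values.
#' @param theta Tibble of accepted/adjusted parameter sets.
#' @return A list with `E_i` (per-set errors) and `E` (their mean).
#' @export
estimation_error <- function(truth, theta) {
  nms <- intersect(names(truth), names(theta))
  if (length(nms) == 0L) abort("no common parameters between `truth` and `theta`")
  if (any(truth[nms] == 0))
    abort("relative error is undefined for a true parameter equal to 0")
  rel <- purrr::map(nms, function(nm) abs(theta[[nm]] - truth[[nm]]) / abs(truth[[nm]]))
  E_i <- Reduce(`+`, rel) / length(nms)
  list(E_i = E_i, E = mean(E_i))
}

#' Model support from a pooled simulation set
#'
#' Pools simulations from competing model variants, computes a common
#' standardized distance to the observed statistics, accepts the closest
#' fraction, and reports the fraction of accepted simulations contributed by
#' each model — the ABC analogue of posterior model probability.
#'
#' @param stats Numeric matrix of pooled summary statistics.
#' @param model Character/factor vector of model labels, one per row.
#' @param s_obs Observed summary statistics.
#' @param accept_frac Fraction to accept (default 0.01).
#' @return A tibble with `model`, `n_accepted`, `fraction` (fractions sum
#'   to 1).
#' @export
model_support <- function(stats, model, s_obs, accept_frac = 0.01) {
  stats <- as.matrix(stats)
  if (nrow(stats) == 0L) abort("empty simulation pool")
  if (length(model) != nrow(stats)) abort("`model` must label every row")
  scale <- stat_scale(stats)
  d <- apply(stats, 1, summary_distance, s_obs = s_obs, scale = scale)
  rej <- abc_rejection(d, accept_frac)
  lev <- if (is.factor(model)) levels(model) else unique(model)
  acc <- model[rej$indices]
  tibble::tibble(model = lev,
                 n_accepted = purrr::map_int(lev, ~ sum(acc == .x)),
                 fraction = purrr::map_int(lev, ~ sum(acc == .x)) / rej$n_accept)
}

#' Rescale lattice parameters to physical rates
#'
#' Converts the per-step probabilities into a migration rate in micrometres
#' per hour and a proliferation rate per day, given the real-time duration a
#' simulation of `steps` steps represents: `dt_hours = duration_days * 24 /
#' steps`, `P_m = p_m * spacing_um / dt_hours`, `P_p = p_p * 24 / dt_hours`.
#'
#' @param p_m,p_p Per-step probabilities (vectorized).
#' @param duration_days Real duration represented by the simulation.
#' @param spacing_um Voxel edge length in micrometres (default 43).
#' @param steps Number of simulation steps (default 1800).
#' @return A tibble with `P_m_um_per_h`, `P_p_per_day`, `dt_hours`,
#'   `duration_days`, `steps`.
#' @export
rescale_parameters <- function(p_m, p_p, duration_days, spacing_um = 43,
                               steps = 1800) {
  if (any(duration_days <= 0)) abort("`duration_days` must be positive")
  if (any(steps <= 0)) abort("`steps` must be positive")
  dt_hours <- duration_days * 24 / steps
  tibble::tibble(p_m = p_m, p_p = p_p,
                 P_m_um_per_h = p_m * spacing_um / dt_hours,
                 P_p_per_day = p_p * 24 / dt_hours,
                 dt_hours = dt_hours, duration_days = duration_days,
                 steps = steps)
}
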