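# ggplot2 views of atlases, lattices, and fits.

#' Plot one slice of an atlas
#'
#' Renders brain, white matter, and vessels of a single plane as a filled
#' raster, useful for eyeballing synthetic anatomy.
#'
#' @param atlas An [anatomy_atlas()].
#' @param axis Slice axis (1/2/3 or "x"/"y"/"z").
#' @param index Plane index; defaults to the mid-plane.
#' @return A ggplot object.
#' @export
plot_atlas_slice <- function(atlas, axis = 3, index = NULL) {
  stopifnot(inherits(atlas, "anatomy_atlas"))
  if (is.character(axis)) axis <- match(axis, c("x", "y", "z"))
  index <- index %||% round(atlas$dim[axis] / 2)
  take <- function(m) switch(axis, m[index, , ], m[, index, ], m[, , index])
  lab <- function(m, what) {
    idx <- which(take(m), arr.ind = TRUE)
    tibble::tibble(i = idx[, 1], j = idx[, 2], tissue = what)
  }
  df <- dplyr::bind_rows(lab(atlas$brain, "brain"), lab(atlas$wm, "white matter"),
                         lab(atlas$bv, "vessel"))
  df$tissue <- factor(df$tissue, levels = c("brain", "white matter", "vessel"))
  df <- df[order(df$tissue), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$tissue)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(brain = "grey85",
                                          `white matter` = "steelblue",
                                          vessel = "firebrick")) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = NULL)
}

#' @rdname simulate_tumor
#' @param object A `lattice_state`.
#' @param axis,index Slice to display (defaults to the mid axial plane).
#' @param ... Unused.
#' @method autoplot lattice_state
#' @export
autoplot.lattice_state <- function(object, axis = 3, index = NULL, ...) {
  if (is.character(axis)) axis <- match(axis, c("x", "y", "z"))
  index <- index %||% round(dim(object$counts)[axis] / 2)
  m <- switch(axis, object$counts[index, , ], object$counts[, index, ],
              object$counts[, , index])
  df <- tibble::as_tibble(expand.grid(i = seq_len(nrow(m)),
                                      j = seq_len(ncol(m))))
  df$count <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "cells/voxel")
}

#' @rdname abc_fit
#' @param object An `abc_fit`.
#' @method autoplot abc_fit
#' @export
autoplot.abc_fit <- function(object, ...) {
  theta <- tibble::as_tibble(object$adjusted)
  keep <- names(theta)[vapply(theta, function(x) .sd_pop(x) > 0, logical(1))]
  df <- tidyr::pivot_longer(theta[, keep], dplyr::everything(),
                            names_to = "parameter", values_to = "value")
  est <- object$estimates[object$estimates$parameter %in% keep, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(data = est,
                        ggplot2::aes(xintercept = .data$estimate),
                        linetype = 2) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "posterior density")
}
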