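# Shared fixtures, all built in code.

# full-grid brain with empty structures: a neutral arena for dynamics tests
arena_atlas <- function(n = 15, spacing_um = 43) {
  generate_synthetic_atlas(shape = rep(n, 3), spacing_um = spacing_um,
                           brain = "full", tract_specs = list(),
                           vessel_specs = list(), seed = 1)
}

# arena with a single white-matter structure given as voxel coordinates
structured_atlas <- function(n, wm_voxels = NULL, bv_voxels = NULL) {
  wm <- array(FALSE, rep(n, 3))
  bv <- array(FALSE, rep(n, 3))
  if (!is.null(wm_voxels)) wm[wm_voxels] <- TRUE
  if (!is.null(bv_voxels)) bv[bv_voxels] <- TRUE
  anatomy_atlas(array(TRUE, rep(n, 3)), wm, bv)
}

checkerboard <- function(n = 8) {
  outer(seq_len(n), seq_len(n), function(i, j) (i + j) %% 2 == 0)
}

# independent flood-fill component labeling oracle (breadth-first, pure R)
bfs_label_oracle <- function(img, connectivity = 8) {
  nr <- nrow(img); nc <- ncol(img)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  nxt <- 0L
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (!img[rr, cc] || lab[rr, cc] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(rr, cc))
    lab[rr, cc] <- nxt
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        r2 <- p[1] + nb[k, 1]; c2 <- p[2] + nb[k, 2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (img[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- nxt
          queue[[length(queue) + 1]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# canonical form for comparing labelings up to label permutation
canon_labels <- function(lab) {
  v <- as.vector(lab)
  match(v, unique(v[v > 0])) |> (\(x) ifelse(is.na(x), 0L, x))() |>
    matrix(nrow(lab), ncol(lab))
}
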