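test_that("sphere initialization reproduces the seeding cell counts", {
  atl <- arena_atlas(21)
  expect_identical(initialize_tumor(atl, radius = 8)$n_cells, 6327L)
  expect_identical(initialize_tumor(atl, radius = 0)$n_cells, 3L)
  # radius 1: enumerate integer offsets with ||v|| <= 1 -> 7 voxels
  n_off <- sum(rowSums(as.matrix(expand.grid(-1:1, -1:1, -1:1))^2) <= 1)
  expect_identical(initialize_tumor(atl, radius = 1)$n_cells, 3L * n_off)
  expect_error(initialize_tumor(atl, center = c(2, 2, 2), radius = 8),
               "exceeds the grid")
})

test_that("unit directions are normalized and guard the degenerate case", {
  expect_equal(unit_direction(c(0, 0, 0), c(1, 0, 0)), c(1, 0, 0))
  expect_equal(unit_direction(c(2, 3, 4), c(3, 4, 4)),
               c(1 / sqrt(2), 1 / sqrt(2), 0))
  expect_error(unit_direction(c(1, 1, 1), c(1, 1, 1)), "distinct")
})

test_that("axis-weight folding puts magnitudes in the matching sign slots", {
  expect_equal(unname(direction_to_axis_weights(c(1, 0, 0))),
               c(1, 0, 0, 0, 0, 0))
  expect_equal(unname(direction_to_axis_weights(c(-1, 0, 0))),
               c(0, 1, 0, 0, 0, 0))
  expect_equal(unname(direction_to_axis_weights(c(1, 1, 0) / sqrt(2))),
               c(1 / sqrt(2), 0, 1 / sqrt(2), 0, 0, 0))
  # at most 3 nonzero slots, opposing slots never both positive
  set.seed(8)
  for (i in 1:50) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    u <- direction_to_axis_weights(v)
    expect_lte(sum(u > 0), 3)
    expect_true(all(u[c(1, 3, 5)] * u[c(2, 4, 6)] == 0))
  }
})

test_that("structure attraction sums unit contributions and normalizes", {
  n <- 11; c0 <- c(6, 6, 6)
  # no structure in range -> uniform fallback
  empty <- array(FALSE, rep(n, 3))
  expect_equal(unname(structure_attraction(c0, empty, d = 5)), rep(1 / 6, 6))
  # single voxel at +x offset 2 -> all mass on +x
  one <- array(FALSE, rep(n, 3)); one[8, 6, 6] <- TRUE
  expect_equal(unname(structure_attraction(c0, one, d = 5)),
               c(1, 0, 0, 0, 0, 0))
  # symmetric pair -> half and half
  two <- array(FALSE, rep(n, 3)); two[8, 6, 6] <- TRUE; two[4, 6, 6] <- TRUE
  expect_equal(unname(structure_attraction(c0, two, d = 5)),
               c(0.5, 0.5, 0, 0, 0, 0))
  # own voxel is excluded from sensing
  self <- array(FALSE, rep(n, 3)); self[6, 6, 6] <- TRUE
  expect_equal(unname(structure_attraction(c0, self, d = 5)), rep(1 / 6, 6))
})

test_that("structure attraction agrees with a brute-force voxel loop", {
  set.seed(13)
  n <- 13; c0 <- c(7, 7, 7); d <- 5
  mask <- array(runif(n^3) < 0.1, rep(n, 3))
  u <- rep(0, 6)
  for (x in 1:n) for (y in 1:n) for (z in 1:n) {
    if (!mask[x, y, z]) next
    off <- c(x, y, z) - c0
    r <- sqrt(sum(off^2))
    if (r == 0 || r > d) next
    u <- u + c(max(off[1], 0), max(-off[1], 0), max(off[2], 0),
               max(-off[2], 0), max(off[3], 0), max(-off[3], 0)) / r
  }
  expect_equal(unname(structure_attraction(c0, mask, d)), u / sum(u),
               tolerance = 1e-12)
})

test_that("the precomputed attraction field matches the per-voxel function", {
  set.seed(21)
  n <- 9
  mask <- array(runif(n^3) < 0.15, rep(n, 3))
  atl <- structured_atlas(n, wm_voxels = which(mask, arr.ind = TRUE))
  fld <- attraction_field(atl, d = 3, structures = "wm")
  for (pos in list(c(1, 1, 1), c(5, 5, 5), c(2, 7, 4), c(9, 9, 9))) {
    v <- pos[1] + n * (pos[2] - 1) + n^2 * (pos[3] - 1)
    expect_equal(unname(fld$wm[v, ]),
                 unname(structure_attraction(pos, atl$wm, d = 3)),
                 tolerance = 1e-12)
  }
})

test_that("mixing the direction distributions is a convex combination", {
  Pw <- c(1, 0, 0, 0, 0, 0); Pb <- c(0, 1, 0, 0, 0, 0)
  expect_equal(unname(mixed_migration_distribution(Pw, Pb, 0, 0)), rep(1 / 6, 6))
  expect_equal(unname(mixed_migration_distribution(Pw, Pb, 1, 0)), Pw)
  expect_equal(unname(mixed_migration_distribution(Pw, Pb, 0.45, 0.45)),
               c(0.45 + 1 / 60, 0.45 + 1 / 60, 1 / 60, 1 / 60, 1 / 60, 1 / 60))
  expect_error(mixed_migration_distribution(Pw, Pb, 0.6, 0.6), "w_wm \\+ w_bv")
})

test_that("inert dynamics leave the state unchanged; p_p = 1 fills to capacity", {
  atl <- arena_atlas(9)
  init <- initialize_tumor(atl, radius = 0, cells_per_voxel = 1)
  p0 <- sim_params(p_m = 0, p_p = 0, K = 3, steps = 5)
  same <- simulate_tumor(p0, atl, init, seed = 1)
  expect_identical(same$counts, init$counts)

  # one cell, certain proliferation, no migration: 1 -> 2 -> 3 -> 3
  # (the newborn cannot act in its birth step, and K = 3 caps the voxel)
  p1 <- sim_params(p_m = 0, p_p = 1, K = 3, steps = 1)
  s <- init
  for (expected in c(2L, 3L, 3L)) {
    s <- step_tumor(s, p1, atl, seed = expected)
    expect_identical(s$n_cells, expected)
  }
  expect_true(all(s$counts <= 3L))
})

test_that("runs are bit-reproducible under a fixed seed", {
  atl <- generate_synthetic_atlas(shape = c(24, 24, 24), seed = 4)
  init <- initialize_tumor(atl, radius = 2)
  p <- sim_params(p_m = 0.7, p_p = 0.05, w_wm = 0.4, w_bv = 0.3, steps = 30)
  a <- simulate_tumor(p, atl, init, seed = 123)
  b <- simulate_tumor(p, atl, init, seed = 123)
  expect_identical(a$counts, b$counts)
  expect_identical(attr(a, "n_traj"), attr(b, "n_traj"))
})

test_that("unconstrained growth matches the branching-process expectation", {
  # with huge K and no boundary in reach, total count is a branching process
  # with offspring 1 + Bernoulli(p_p): E[N_T] = N_0 (1 + p_p)^T
  atl <- arena_atlas(41)
  init <- initialize_tumor(atl, radius = 0, cells_per_voxel = 3)
  p <- sim_params(p_m = 0.5, p_p = 0.1, K = 1000L, steps = 10)
  finals <- vapply(1:20, function(sd)
    as.numeric(simulate_tumor(p, atl, init, seed = sd)$n_cells), numeric(1))
  expected <- 3 * (1 + p$p_p)^10
  se <- stats::sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - expected), 3 * se + 1e-9)
  expect_true(all(finals <= 3 * (1 + 1)^10))
})

test_that("unbiased migration is a symmetric 6-neighbor random walk", {
  # single non-proliferating cell, one step, many replicates: displacement
  # counts must be uniform over the 6 von Neumann directions
  atl <- arena_atlas(7)
  init <- initialize_tumor(atl, center = c(4, 4, 4), radius = 0,
                           cells_per_voxel = 1)
  p <- sim_params(p_m = 1, p_p = 0, steps = 1)
  dirs <- vapply(1:10000, function(sd) {
    fin <- simulate_tumor(p, atl, init, seed = sd)
    idx <- which(fin$counts > 0, arr.ind = TRUE)[1, ] - c(4, 4, 4)
    paste(idx, collapse = ",")
  }, character(1))
  counts <- table(dirs)
  expect_identical(length(counts), 6L)
  expect_gt(stats::chisq.test(counts, p = rep(1 / 6, 6))$p.value, 1e-3)
})

test_that("full white-matter attraction pulls single-step moves toward the tract", {
  # plane of white matter at x = 9, cell at x = 6: +x moves must dominate -x
  n <- 11
  wm <- as.matrix(expand.grid(x = 9, y = 1:n, z = 1:n))
  atl <- structured_atlas(n, wm_voxels = wm)
  init <- initialize_tumor(atl, center = c(6, 6, 6), radius = 0,
                           cells_per_voxel = 1)
  p <- sim_params(p_m = 1, p_p = 0, w_wm = 1, steps = 1)
  fld <- attraction_field(atl, d = 5)
  dx <- vapply(1:2000, function(sd) {
    fin <- simulate_tumor(p, atl, init, seed = sd, field = fld)
    which(fin$counts > 0, arr.ind = TRUE)[1, 1] - 6L
  }, integer(1))
  expect_lt(stats::binom.test(sum(dx > 0), sum(dx != 0), p = 0.5,
                              alternative = "greater")$p.value, 1e-3)
  expect_gt(mean(dx), 0)
})

test_that("cells never leave the brain mask and capacity is respected", {
  set.seed(77)
  atl <- generate_synthetic_atlas(shape = c(16, 16, 16), seed = 5)
  init <- initialize_tumor(atl, radius = 1)
  for (i in 1:10) {
    p <- sim_params(p_m = runif(1), p_p = runif(1, 0, 0.2),
                    w_wm = runif(1, 0, 0.5), w_bv = runif(1, 0, 0.5),
                    K = 3, steps = 40)
    fin <- simulate_tumor(p, atl, init, seed = i)
    expect_true(all(fin$counts >= 0) && all(fin$counts <= 3))
    expect_false(any(fin$counts[!atl$brain] > 0))
    traj <- attr(fin, "n_traj")
    expect_true(all(diff(traj) >= 0))
    expect_true(all(diff(traj) <= traj[-length(traj)]))
  }
})
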