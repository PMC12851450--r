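test_that("slice extraction binarizes exactly at the cell threshold", {
  counts <- array(0L, c(5, 6, 7))
  expect_false(any(extract_slice(counts, 3, 4)$pixels))
  counts[2, 3, 4] <- 1L
  sl <- extract_slice(counts, 3, 4)
  expect_identical(sum(sl$pixels), 1L)
  expect_true(sl$pixels[2, 3])
  expect_error(extract_slice(counts, 3, 8), "out of range")

  set.seed(31)
  counts <- array(sample(0:3, 5 * 6 * 7, replace = TRUE), c(5, 6, 7))
  sl <- extract_slice(counts, 2, 5, threshold_cells = 2)
  oracle <- matrix(FALSE, 5, 7)
  for (i in 1:5) for (k in 1:7) oracle[i, k] <- counts[i, 5, k] >= 2
  expect_identical(sl$pixels, oracle)
})

test_that("component labeling matches a flood-fill oracle", {
  # diagonal touch: one component under 8-connectivity, two under 4
  diag2 <- matrix(FALSE, 3, 3); diag2[1, 1] <- TRUE; diag2[2, 2] <- TRUE
  expect_identical(max(label_components(diag2, 8)), 1L)
  expect_identical(max(label_components(diag2, 4)), 2L)
  expect_identical(max(label_components(matrix(FALSE, 4, 4))), 0L)

  set.seed(17)
  for (i in 1:5) {
    img <- matrix(runif(32 * 32) < 0.4, 32, 32)
    for (conn in c(8L, 4L)) {
      got <- label_components(img, conn)
      want <- bfs_label_oracle(img, conn)
      expect_identical(canon_labels(got), canon_labels(want))
    }
  }
})

test_that("region properties follow their geometric definitions", {
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  p <- region_properties(one)
  expect_equal(p$area, 1)
  expect_equal(p$filled_area, 1)
  expect_equal(p$eccentricity, 0)  # isotropic moments with the pixel term

  ring <- matrix(FALSE, 5, 5); ring[2:4, 2:4] <- TRUE; ring[3, 3] <- FALSE
  p <- region_properties(ring)
  expect_equal(p$area, 8)
  expect_equal(p$filled_area, 9)

  # 1 x 9 line: eccentricity from the closed-form discrete second moments
  line <- matrix(FALSE, 3, 11); line[2, 2:10] <- TRUE
  p <- region_properties(line)
  uxx <- mean((1:9 - 5)^2) + 1 / 12
  uyy <- 1 / 12
  expect_equal(p$eccentricity, sqrt(1 - uyy / uxx))
  expect_gt(p$eccentricity, 0.99)
})

test_that("the weighted perimeter estimator is bit-stable on frozen shapes", {
  sq2 <- matrix(FALSE, 4, 4); sq2[2:3, 2:3] <- TRUE
  expect_equal(region_properties(sq2)$perimeter, 4)
  sq3 <- matrix(FALSE, 5, 5); sq3[2:4, 2:4] <- TRUE
  expect_equal(region_properties(sq3)$perimeter, 8)
})

test_that("summary statistics assemble the 8-vector as specified", {
  expect_equal(unname(summary_statistics(matrix(FALSE, 6, 6))), rep(0, 8))

  sq <- matrix(FALSE, 6, 6); sq[2:3, 2:3] <- TRUE
  s <- summary_statistics(sq)
  expect_equal(unname(s["n_components"]), 1)
  expect_equal(unname(s["mean_area"]), 4)
  expect_equal(unname(s[c("sd_area", "sd_eccentricity", "sd_perimeter")]),
               c(0, 0, 0))
  expect_equal(unname(s["max_filled_area"]), 4)

  two <- matrix(FALSE, 8, 8); two[2:3, 2:3] <- TRUE; two[6:7, 6:7] <- TRUE
  s2 <- summary_statistics(two)
  expect_equal(unname(s2["n_components"]), 2)
  expect_equal(unname(s2["sd_area"]), 0)  # identical regions
  expect_equal(unname(s2["mean_area"]), 4)
})

test_that("summary statistics are invariant under translation and flips", {
  set.seed(23)
  base <- matrix(runif(20 * 20) < 0.3, 20, 20)
  img <- matrix(FALSE, 30, 30); img[4 + 1:20, 6 + 1:20] <- base
  shifted <- matrix(FALSE, 30, 30); shifted[8 + 1:20, 1 + 1:20] <- base
  expect_equal(summary_statistics(img), summary_statistics(shifted))
  expect_equal(summary_statistics(img),
               summary_statistics(img[nrow(img):1, ]))
  expect_equal(summary_statistics(img),
               summary_statistics(img[, ncol(img):1]))
})

test_that("Jaccard index measures overlap and handles the empty case", {
  cb <- checkerboard(8)
  expect_equal(jaccard_index(cb, !cb), 0)
  expect_equal(jaccard_index(cb, cb), 1)
  expect_equal(jaccard_index(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)), 1)
  expect_error(jaccard_index(cb, matrix(TRUE, 4, 4)), "same shape")

  set.seed(29)
  a <- matrix(runif(15 * 15) < 0.5, 15, 15)
  b <- matrix(runif(15 * 15) < 0.5, 15, 15)
  inter <- 0L; uni <- 0L
  for (i in 1:15) for (j in 1:15) {
    if (a[i, j] && b[i, j]) inter <- inter + 1L
    if (a[i, j] || b[i, j]) uni <- uni + 1L
  }
  expect_equal(jaccard_index(a, b), inter / uni)
  expect_equal(jaccard_index(a, b), jaccard_index(b, a))
})

test_that("summary distance is a scaled Euclidean norm", {
  s <- c(1, 2, 3)
  expect_equal(summary_distance(s, s), 0)
  expect_equal(summary_distance(c(1, 2), c(4, 6)), 5)
  set.seed(3)
  a <- rnorm(8); b <- rnorm(8); sc <- runif(8, 0.5, 2)
  expect_equal(summary_distance(a, b, sc), summary_distance(b, a, sc))
  expect_equal(summary_distance(a, b, sc), sqrt(sum(((a - b) / sc)^2)))
})
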