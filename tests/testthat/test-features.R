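abind_cols <- function(...) {
  parts <- list(...)
  out <- array(0L, dim = c(dim(parts[[1]])[1],
                           sum(vapply(parts, function(p) dim(p)[2], numeric(1))),
                           3))
  at <- 0
  for (p in parts) {
    out[, at + seq_len(dim(p)[2]), ] <- p
    at <- at + dim(p)[2]
  }
  out
}

test_that("slice boundaries follow the floor partition", {
  patch <- array(0L, dim = c(4, 20, 3))
  s <- split_roi(patch, 20)
  expect_length(s, 20)
  expect_true(all(vapply(s, function(x) dim(x)[2], numeric(1)) == 1))

  # Non-divisible width: widths in {2, 3}, disjoint cover of all columns.
  patch45 <- array(seq_len(4 * 45 * 3), dim = c(4, 45, 3))
  s45 <- split_roi(patch45, 20)
  widths <- vapply(s45, function(x) dim(x)[2], numeric(1))
  expect_identical(sum(widths), 45)
  expect_true(all(widths %in% c(2, 3)))
  expect_equal(widths, diff(floor((0:20) * 45 / 20)))
  # Concatenating the slices reconstructs the patch (disjoint + ordered).
  expect_identical(do.call(function(...) abind_cols(...), s45), patch45)

  expect_error(split_roi(array(0L, dim = c(4, 19, 3)), 20), "width")
})

test_that("green histogram counts occurrences per 8-bit level", {
  sl <- array(0L, dim = c(10, 10, 3))
  sl[, , 2] <- 200L
  h <- green_histogram(sl)
  expect_identical(h[201], 100L)
  expect_identical(sum(h), 100L)

  sl2 <- array(0L, dim = c(1, 4, 3))
  sl2[1, , 2] <- c(0L, 0L, 25L, 255L)
  h2 <- green_histogram(sl2)
  expect_identical(h2[c(1, 26, 256)], c(2L, 1L, 1L))
  expect_identical(sum(h2), 4L)

  g <- matrix(sample(0:255, 80, replace = TRUE), 8, 10)
  expect_identical(sum(green_histogram(g)), 80L)
})

test_that("histogram area equals the thresholded sum over bin widths", {
  expect_identical(histogram_area(rep(0L, 256)), 0)
  h <- rep(0L, 256); h[256] <- 100L
  expect_identical(histogram_area(h, histogram_spec(k = 25)), 100)

  set.seed(31)
  g <- matrix(sample(0:255, 80, replace = TRUE), 8, 10)
  a <- histogram_area(green_histogram(g), histogram_spec(k = 25))
  expect_identical(a, as.numeric(sum(g >= 25)))

  # Non-unit bins weight each level by its bin width.
  edges <- cumsum(c(0, rep(2, 256)))
  a2 <- histogram_area(green_histogram(g), histogram_spec(k = 0, edges))
  expect_identical(a2, 2 * 80)
})

test_that("feature vector composes slices, histograms and areas in order", {
  zero <- array(0L, dim = c(10, 40, 3))
  expect_identical(extract_features(zero), rep(0, 20))

  half <- array(0L, dim = c(10, 40, 3))
  half[, 1:20, 2] <- 200L
  f <- extract_features(half, histogram_spec(k = 25))
  expect_identical(f, c(rep(20, 10), rep(0, 10)))

  s <- generate_roi_patch(scene_params(seed = 2))
  expect_length(extract_features(s$patch), 20L)
})

test_that("features match the per-pixel brute-force oracle on random patches", {
  set.seed(17)
  for (i in 1:50) {
    w <- sample(20:90, 1); h <- sample(5:40, 1)
    patch <- array(sample(0:255, h * w * 3, replace = TRUE),
                   dim = c(h, w, 3))
    expect_identical(extract_features(patch, histogram_spec(k = 25)),
                     naive_features(patch, k = 25))
  }
})

test_that("with k = 0 the features conserve the total pixel count", {
  for (seed in 1:10) {
    s <- generate_roi_patch(scene_params(seed = seed))
    f <- extract_features(s$patch, histogram_spec(k = 0))
    expect_identical(sum(f), prod(dim(s$patch)[1:2]))
  }
})

test_that("features are non-increasing in the exclusion threshold k", {
  s <- generate_roi_patch(scene_params(seed = 8))
  ks <- c(0, 25, 100, 255)
  f <- lapply(ks, function(k) extract_features(s$patch, histogram_spec(k = k)))
  for (j in seq_len(length(ks) - 1)) {
    expect_true(all(f[[j + 1]] <= f[[j]]))
  }
})

test_that("features are local to their slice under pixel permutations", {
  set.seed(5)
  patch <- array(sample(0:255, 20 * 40 * 3, replace = TRUE),
                 dim = c(20, 40, 3))
  f0 <- extract_features(patch)
  # Permute pixels inside slice 3 (columns 5..6): vector unchanged.
  p2 <- patch
  block <- p2[, 5:6, 2]
  p2[, 5:6, 2] <- matrix(sample(block), nrow(block))
  expect_identical(extract_features(p2), f0)
  # Swap the contents of slices 1 and 20: exactly those entries swap.
  p3 <- patch
  p3[, 1:2, ] <- patch[, 39:40, ]
  p3[, 39:40, ] <- patch[, 1:2, ]
  f3 <- extract_features(p3)
  expect_identical(f3[c(20, 1)], f0[c(1, 20)])
  expect_identical(f3[2:19], f0[2:19])
})

test_that("normalized features are per-pixel fractions", {
  half <- array(0L, dim = c(10, 40, 3))
  half[, 1:20, 2] <- 200L
  f <- extract_features(half, normalize = TRUE)
  expect_identical(f, c(rep(1, 10), rep(0, 10)))
})

test_that("feature CSV round-trips and rejects malformed rows", {
  dir <- withr::local_tempdir()
  d <- generate_dataset(8, seed = 2)
  fm <- features_matrix(d)
  path <- write_features_csv(fm, file.path(dir, "f.csv"))
  back <- read_features_csv(path)
  expect_equal(back$X, fm$X, ignore_attr = TRUE)
  expect_identical(back$y, fm$y)

  writeLines(c("f1,f2,label", "1,2,1", "3,NA,0"), file.path(dir, "bad.csv"))
  expect_error(read_features_csv(file.path(dir, "bad.csv")), "row 2")
})
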