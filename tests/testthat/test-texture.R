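test_that("grayscale conversion applies luma weights and validates shape", {
  white <- array(1, dim = c(4, 4, 3))
  expect_true(all(to_grayscale(white)$pixels == 255L))

  red <- array(0, dim = c(4, 4, 3))
  red[, , 1] <- 255
  expect_true(all(to_grayscale(red)$pixels == 76L)) # round(0.299 * 255)

  k <- array(123 / 255, dim = c(3, 3, 3))
  expect_true(all(to_grayscale(k)$pixels == 123L))

  expect_error(to_grayscale(matrix(0, 4, 4)), "3-channel")
})

test_that("quantization is floor binning that preserves intensity order", {
  img <- gray_image(matrix(c(0, 64, 128, 192, 255, 0, 64, 128, 192, 255),
                           nrow = 2, byrow = TRUE), 256)
  q <- quantize(img, 4)
  expect_equal(q$pixels[1, ], c(0L, 1L, 2L, 3L, 3L))
  expect_equal(q$levels, 4L)

  const <- gray_image(matrix(200L, 3, 3), 256)
  expect_true(all(quantize(const, 8)$pixels == 6L))

  extremes <- gray_image(matrix(c(0L, 255L, 255L, 0L), 2), 256)
  expect_equal(sort(unique(as.vector(quantize(extremes, 2)$pixels))),
               c(0L, 1L))
  # non-divisor depths must stay in range too
  expect_lt(max(quantize(img, 3)$pixels), 3)
  expect_error(quantize(img, 1), ">= 2")
})

test_that("first-order statistics are population moments with NA degeneracy", {
  const <- gray_image(matrix(7L, 4, 4), 256)
  fo <- first_order_stats(const)
  expect_equal(fo[["mean"]], 7)
  expect_equal(fo[["sd"]], 0)
  expect_true(is.na(fo[["skewness"]]) && is.na(fo[["kurtosis"]]))

  two <- gray_image(matrix(c(0L, 2L, 0L, 2L), 2), 256)
  expect_equal(unname(first_order_stats(two)), c(1, 1, 0, 1))

  img <- random_gray(16, 16, 256, seed = 11)
  refl <- gray_image(255L - img$pixels, 256)
  a <- first_order_stats(img)
  b <- first_order_stats(refl)
  expect_equal(b[["skewness"]], -a[["skewness"]])
  expect_equal(b[["sd"]], a[["sd"]])
  expect_equal(b[["kurtosis"]], a[["kurtosis"]])
})

test_that("co-occurrence matrix counts, symmetrizes and normalizes", {
  cb <- gray_image(matrix(c(0L, 1L, 1L, 0L), 2), 2)
  p <- cooccurrence(cb, d = 1, angles = 0, symmetric = TRUE)
  expect_equal(unclass(p), matrix(c(0, 0.5, 0.5, 0), 2),
               ignore_attr = TRUE)

  const <- gray_image(matrix(3L, 4, 4), 8)
  pc <- cooccurrence(const, d = 1, angles = c(0, 45, 90, 135))
  expect_equal(pc[4, 4], 1)
  expect_equal(sum(pc), 1)

  img <- random_gray(20, 20, 8, seed = 3)
  pr <- cooccurrence(img, d = 1, angles = c(0, 45, 90, 135),
                     symmetric = TRUE)
  expect_equal(sum(pr), 1)
  expect_equal(unclass(pr), t(unclass(pr)))

  tiny <- gray_image(matrix(c(0L, 1L, 1L, 0L), 2), 2)
  expect_error(cooccurrence(tiny, d = 5, angles = 0), "no valid pixel pair")
})

test_that("co-occurrence features match closed forms on printed fixtures", {
  const <- gray_image(matrix(3L, 4, 4), 8)
  f <- haralick_features(cooccurrence(const, angles = 0))
  expect_equal(f[["ASM"]], 1)
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["entropy"]], 0)
  expect_equal(f[["IDM"]], 1)
  expect_true(is.na(f[["correlation"]]))
  expect_true(is.na(f[["IMC1"]]))

  chk <- haralick_features(matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(chk[["ASM"]], 0.5)
  expect_equal(chk[["contrast"]], 1)
  expect_equal(chk[["correlation"]], -1)
  expect_equal(chk[["sum_of_squares"]], 0.25)
  expect_equal(chk[["IDM"]], 0.5)
  expect_equal(chk[["entropy"]], 1)
  expect_equal(chk[["sum_average"]], 1)
  expect_equal(chk[["sum_entropy"]], 0)
  expect_equal(chk[["IMC1"]], -1)
  expect_equal(chk[["IMC2"]], sqrt(1 - exp(-2)))
})

test_that("co-occurrence features agree with the naive-loop oracle", {
  for (s in 1:20) {
    img <- random_gray(32, 32, 16, seed = 100 + s)
    p <- cooccurrence(img, d = 1, angles = c(0, 45, 90, 135),
                      symmetric = TRUE)
    expect_equal(haralick_features(p), naive_haralick(unclass(p)),
                 tolerance = 1e-8)
  }
})

test_that("GLCM and shared statistics agree with scikit-image", {
  img <- random_gray(24, 24, 8, seed = 77)
  ref <- skimage_glcm(img$pixels, 8)
  p <- cooccurrence(img, d = 1, angles = 0, symmetric = TRUE)
  expect_equal(unclass(p), ref$P, tolerance = 1e-10, ignore_attr = TRUE)
  f <- haralick_features(p)
  expect_equal(f[c("contrast", "ASM", "correlation", "IDM")], ref$props,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("run-length matrices scan maximal runs and conserve pixels", {
  const <- gray_image(matrix(3L, 4, 4), 8)
  r <- run_length(const, 0)
  expect_equal(r[4, 4], 4L)
  expect_equal(sum(r), 4L)

  rows <- gray_image(rbind(c(0L, 0L, 1L, 1L, 1L),
                           c(2L, 2L, 2L, 2L, 2L)), 3)
  rr <- run_length(rows, 0)
  expect_equal(rr[1, 2], 1L) # grey 0, length 2
  expect_equal(rr[2, 3], 1L) # grey 1, length 3
  expect_equal(rr[3, 5], 1L) # grey 2, length 5
  expect_equal(sum(rr), 3L)

  img <- random_gray(15, 11, 4, seed = 9)
  for (ang in c(0, 45, 90, 135)) {
    r <- run_length(img, ang)
    expect_equal(sum(r %*% seq_len(ncol(r))), 15 * 11)
  }
})

test_that("run-length features match hand-enumerated fixtures", {
  const <- gray_image(matrix(3L, 4, 4), 8)
  f <- rlm_features(run_length(const, 0))
  expect_equal(unname(f), c(1 / 16, 16, 4, 4, 0.25))

  cb <- gray_image((outer(1:6, 1:6, `+`) %% 2L), 2)
  fc <- rlm_features(run_length(cb, 0)) # every horizontal run has length 1
  expect_equal(fc[["SRE"]], 1)
  expect_equal(fc[["LRE"]], 1)
  expect_equal(fc[["RP"]], 1)

  # single grey level: GLNU equals the total run count
  r <- run_length(const, 90)
  expect_equal(rlm_features(r)[["GLNU"]], sum(r))
})

test_that("texture vector flags degeneracy and respects symmetries", {
  const <- gray_image(matrix(100L, 16, 16), 256)
  v <- texture_features(const)
  expect_equal(v[["ASM"]], 1)
  expect_equal(v[["IDM"]], 1)
  expect_true(all(is.na(v[c("skewness", "kurtosis", "correlation",
                            "IMC1", "IMC2")])))
  expect_false(anyNA(v[c("SRE", "LRE", "GLNU", "RLNU", "RP")]))

  img <- random_gray(24, 24, 256, seed = 21)
  rot <- gray_image(rot90(img$pixels), 256)
  expect_equal(texture_features(img), texture_features(rot),
               tolerance = 1e-12)

  # first-order statistics ignore pixel arrangement entirely
  perm <- with(img, gray_image(matrix(sample(pixels), nrow(pixels)), levels))
  expect_equal(first_order_stats(img), first_order_stats(perm))
})

test_that("noise drives ASM down and entropy up monotonically", {
  base <- matrix(100L, 48, 48)
  set.seed(5)
  noise_at <- function(frac) {
    m <- base
    idx <- sample(length(m), round(frac * length(m)))
    m[idx] <- sample(0:255, length(idx), replace = TRUE)
    texture_features(gray_image(m, 256))
  }
  v <- lapply(c(0.1, 0.4, 0.8), noise_at)
  asm <- vapply(v, `[[`, numeric(1), "ASM")
  ent <- vapply(v, `[[`, numeric(1), "entropy")
  expect_true(all(diff(asm) < 0))
  expect_true(all(diff(ent) > 0))
})

test_that("PNG round trip preserves the grey image", {
  img <- gen_image("pork_boiled", size = 64, seed = 4)
  path <- tempfile(fileext = ".png")
  png::writePNG(img, path)
  gr <- read_image_gray(path)
  # PNG stores channels at 8 bits, so luma can shift by at most one level
  expect_lte(max(abs(gr$pixels - to_grayscale(img)$pixels)), 1L)
})
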