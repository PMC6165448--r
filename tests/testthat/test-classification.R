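test_that("pooled z-normalization centers, scales and drops degenerate features", {
  set.seed(1)
  x <- matrix(rnorm(60, 5, 3), 20, 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  nz <- normalize_features(x)
  expect_equal(unname(colMeans(nz$x)), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(sqrt(colMeans(nz$x^2))), rep(1, 3), tolerance = 1e-10)

  x2 <- cbind(x, flat = 7)
  expect_warning(nz2 <- normalize_features(x2), "zero-variance")
  expect_equal(nz2$dropped, "flat")
  expect_equal(ncol(nz2$x), 3)

  v <- c(1, 2, -3)
  pair <- rbind(v, -v)
  expect_equal(unname(normalize_features(pair)$x),
               rbind(c(1, 1, -1), c(-1, -1, 1)))
})

test_that("PNN scores equal hand-computed Gaussian kernel sums", {
  x <- rbind(c(0, 0), c(1, 1), c(3, 0), c(0, 3))
  y <- c("A", "A", "B", "C")
  m <- pnn_fit(x, y, sigma = 1)
  s <- pnn_score(m, c(1, 0))
  expect_equal(s[["A"]], (exp(-1 / 2) + exp(-1 / 2)) / 2, tolerance = 1e-12)
  expect_equal(s[["B"]], exp(-4 / 2), tolerance = 1e-12)
  expect_equal(s[["C"]], exp(-10 / 2), tolerance = 1e-12)
  expect_equal(pnn_classify(m, c(1, 0)), "A")
  expect_error(pnn_score(m, c(NA, 0)), "missing")
})

test_that("exact midpoint ties resolve to the first registered class", {
  m <- pnn_fit(rbind(c(0, 0), c(2, 0)), c("left", "right"), sigma = 0.7)
  s <- pnn_score(m, c(1, 0))
  expect_equal(s[["left"]], s[["right"]])
  expect_equal(pnn_classify(m, c(1, 0)), "left")
})

test_that("the PNN collapses to 1-nearest-neighbour as sigma shrinks", {
  set.seed(8)
  tr <- matrix(rnorm(24), 12, 2)
  ytr <- rep(c("A", "B"), each = 6)
  qs <- matrix(rnorm(20), 10, 2)
  m <- pnn_fit(tr, ytr, sigma = 1e-4)
  got <- vapply(seq_len(10), function(i) pnn_classify(m, qs[i, ]),
                character(1))
  expect_equal(got, naive_1nn(tr, ytr, qs))
})

test_that("leave-one-out evaluation matches a literal per-fold rebuild", {
  set.seed(12)
  x <- matrix(rnorm(72), 18, 4)
  colnames(x) <- paste0("f", 1:4)
  y <- rep(c("A", "B", "C"), each = 6)
  for (norm in c("fold", "pooled")) {
    for (sub in list(1L, c(2L, 3L), c(1L, 2L, 4L))) {
      for (sg in c(0.3, 1)) {
        tt <- loo_evaluate(x, y, subset = sub, sigma = sg, norm = norm)
        expect_equal(
          tt$accuracy,
          naive_loo_accuracy(x[, sub, drop = FALSE], y, sg, norm),
          info = sprintf("norm=%s size=%d sigma=%g", norm, length(sub), sg)
        )
        expect_equal(unname(rowSums(tt$confusion)), rep(6L, 3),
                     ignore_attr = TRUE)
      }
    }
  }
})

test_that("well-separated classes classify perfectly, symmetric labels at chance", {
  set.seed(3)
  x <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40, 10), 20, 2))
  y <- rep(c("near", "far"), each = 20)
  expect_equal(loo_evaluate(x, y, sigma = "auto")$accuracy, 1)

  # two classes drawn iid from one distribution: expected accuracy 1/2.
  # A fixed kernel width is required here: the auto grid maximizes LOO
  # accuracy and its selection bias lifts chance-level data above the
  # binomial band.
  set.seed(4)
  xs <- matrix(rnorm(180), 60, 3)
  ys <- rep(c("u", "v"), 30)
  acc <- loo_evaluate(xs, ys, sigma = sqrt(3))$accuracy
  bounds <- qbinom(c(0.005, 0.995), 60, 0.5) / 60
  expect_gte(acc, bounds[1])
  expect_lte(acc, bounds[2])
})

test_that("LOO accuracy is invariant to per-feature affine rescaling", {
  set.seed(6)
  x <- matrix(rnorm(80), 20, 4)
  y <- rep(c("A", "B"), each = 10)
  scale <- c(3, -2, 0.5, 10)
  shift <- c(-1, 4, 0, 100)
  x2 <- sweep(sweep(x, 2, scale, "*"), 2, shift, "+")
  for (norm in c("fold", "pooled")) {
    a1 <- loo_evaluate(x, y, sigma = 0.8, norm = norm)
    a2 <- loo_evaluate(x2, y, sigma = 0.8, norm = norm)
    expect_equal(a1$confusion, a2$confusion)
  }
})

test_that("patterns with missing retained features are rejected with a warning", {
  set.seed(2)
  x <- matrix(rnorm(40), 10, 4)
  x[3, 2] <- NA
  y <- rep(c("A", "B"), each = 5)
  expect_warning(tt <- loo_evaluate(x, y, subset = c(2L, 3L), sigma = 1),
                 "rejected")
  expect_equal(sum(tt$confusion), 9)
})

test_that("subset search finds planted discriminants and honours tie-breaks", {
  set.seed(10)
  n <- 40
  y <- rep(c("A", "B"), each = n / 2)
  x <- matrix(rnorm(n * 5), n, 5)
  colnames(x) <- paste0("f", 1:5)
  x[, 3] <- ifelse(y == "A", 0, 10) + rnorm(n, 0, 0.5)
  res <- subset_search(x, y, max_size = 2, sigma = "auto")
  expect_equal(res$best_subset, "f3")
  expect_equal(res$accuracy, 1)

  # two redundant perfect features: the single-feature subset wins, and
  # the lexicographically first of the two is kept
  x2 <- x
  x2[, 5] <- x2[, 3] + rnorm(n, 0, 0.01)
  res2 <- subset_search(x2, y, max_size = 2, sigma = "auto")
  expect_equal(res2$best_subset, "f3")

  wide <- cbind(x, matrix(rnorm(n * 4), n, 4,
                          dimnames = list(NULL, paste0("g", 1:4))))
  expect_error(subset_search(wide, y, max_size = 7), "force")
})

test_that("size-1 search equals an independent best-single-feature scan", {
  set.seed(14)
  x <- matrix(rnorm(120), 30, 4)
  colnames(x) <- paste0("f", 1:4)
  x[, 2] <- x[, 2] + ifelse(rep(c(TRUE, FALSE), 15), 0, 2)
  y <- rep(c("A", "B"), 15)
  res <- subset_search(x, y, max_size = 1, sigma = 0.5)
  scan <- vapply(1:4, function(j) {
    loo_evaluate(x, y, subset = j, sigma = 0.5)$accuracy
  }, numeric(1))
  expect_equal(res$accuracy, max(scan))
  expect_equal(res$best_subset, colnames(x)[which.max(scan)])
})

test_that("LOO order-invariance: permuting patterns leaves accuracy unchanged", {
  set.seed(19)
  x <- matrix(rnorm(60), 20, 3)
  y <- rep(c("A", "B"), each = 10)
  perm <- sample(20)
  a1 <- loo_evaluate(x, y, sigma = 0.6)
  a2 <- loo_evaluate(x[perm, ], y[perm], sigma = 0.6)
  expect_equal(a1$accuracy, a2$accuracy)
  expect_equal(a1$confusion[c("A", "B"), c("A", "B")],
               a2$confusion[c("A", "B"), c("A", "B")])
})
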