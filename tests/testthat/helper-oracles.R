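# Independent reference implementations used as oracles. These are kept
# deliberately naive (explicit loops straight from the textbook
# definitions) and share no code with the package's vectorized paths.

# The thirteen co-occurrence statistics from their definitions, on a
# normalized G x G matrix, base-2 logs, 0-based grey levels.
naive_haralick <- function(p) {
  g <- nrow(p)
  px <- rowSums(p)
  py <- colSums(p)
  mux <- 0; muy <- 0
  for (i in 1:g) {
    mux <- mux + (i - 1) * px[i]
    muy <- muy + (i - 1) * py[i]
  }
  sx <- 0; sy <- 0
  for (i in 1:g) {
    sx <- sx + (i - 1 - mux)^2 * px[i]
    sy <- sy + (i - 1 - muy)^2 * py[i]
  }
  sx <- sqrt(sx); sy <- sqrt(sy)

  asm <- 0; idm <- 0; ent <- 0; ssq <- 0; cnum <- 0
  psum <- numeric(2 * g - 1) # index k+1 for k = 0..2g-2
  pdif <- numeric(g)         # index k+1 for k = 0..g-1
  for (i in 1:g) {
    for (j in 1:g) {
      v <- p[i, j]
      asm <- asm + v^2
      idm <- idm + v / (1 + (i - j)^2)
      if (v > 0) ent <- ent - v * log2(v)
      ssq <- ssq + (i - 1 - mux)^2 * v
      cnum <- cnum + (i - 1) * (j - 1) * v
      psum[i + j - 1] <- psum[i + j - 1] + v
      pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + v
    }
  }
  contrast <- 0; savg <- 0; sent <- 0
  for (k in 0:(2 * g - 2)) {
    savg <- savg + k * psum[k + 1]
    if (psum[k + 1] > 0) sent <- sent - psum[k + 1] * log2(psum[k + 1])
  }
  svar <- 0
  for (k in 0:(2 * g - 2)) svar <- svar + (k - savg)^2 * psum[k + 1]
  dmean <- 0; dent <- 0
  for (k in 0:(g - 1)) {
    contrast <- contrast + k^2 * pdif[k + 1]
    dmean <- dmean + k * pdif[k + 1]
    if (pdif[k + 1] > 0) dent <- dent - pdif[k + 1] * log2(pdif[k + 1])
  }
  dvar <- 0
  for (k in 0:(g - 1)) dvar <- dvar + (k - dmean)^2 * pdif[k + 1]

  hx <- 0; hy <- 0
  for (i in 1:g) {
    if (px[i] > 0) hx <- hx - px[i] * log2(px[i])
    if (py[i] > 0) hy <- hy - py[i] * log2(py[i])
  }
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:g) {
    for (j in 1:g) {
      q <- px[i] * py[j]
      if (q > 0) {
        if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * log2(q)
        hxy2 <- hxy2 - q * log2(q)
      }
    }
  }
  corr <- if (sx == 0 || sy == 0) NA_real_ else (cnum - mux * muy) / (sx * sy)
  imc1 <- if (max(hx, hy) == 0) NA_real_ else (ent - hxy1) / max(hx, hy)
  imc2 <- if (max(hx, hy) == 0) NA_real_ else {
    sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  }
  c(ASM = asm, contrast = contrast, correlation = corr,
    sum_of_squares = ssq, IDM = idm, entropy = ent, sum_entropy = sent,
    sum_average = savg, sum_variance = svar, difference_variance = dvar,
    difference_entropy = dent, IMC1 = imc1, IMC2 = imc2)
}

# Literal leave-one-out PNN: rebuild normalization and classifier for
# every fold with explicit loops.
naive_loo_accuracy <- function(x, y, sigma, norm = "fold") {
  x <- as.matrix(x)
  y <- factor(y, levels = unique(y))
  n <- nrow(x)
  popsd <- function(v) sqrt(mean((v - mean(v))^2))
  if (norm == "pooled") {
    mu <- colMeans(x)
    s <- apply(x, 2, popsd)
  }
  pred <- character(n)
  for (i in seq_len(n)) {
    tr <- x[-i, , drop = FALSE]
    ytr <- y[-i]
    if (norm == "fold") {
      mu <- colMeans(tr)
      s <- apply(tr, 2, popsd)
    }
    s <- pmax(s, sqrt(.Machine$double.eps))
    trn <- sweep(sweep(tr, 2, mu), 2, s, "/")
    q <- (x[i, ] - mu) / s
    scores <- vapply(levels(y), function(cl) {
      xs <- trn[ytr == cl, , drop = FALSE]
      mean(exp(-rowSums(sweep(xs, 2, q)^2) / (2 * sigma^2)))
    }, numeric(1))
    pred[i] <- levels(y)[which.max(scores)]
  }
  mean(pred == as.character(y))
}

# 1-nearest-neighbour labels, computed directly.
naive_1nn <- function(train_x, train_y, queries) {
  apply(queries, 1, function(q) {
    train_y[which.min(rowSums(sweep(train_x, 2, q)^2))]
  })
}

# Cross-check GLCM construction and the shared subset of its statistics
# against scikit-image (pre-installed Python stack).
skimage_glcm <- function(mat, levels) {
  f_in <- tempfile(fileext = ".csv")
  f_out <- tempfile(fileext = ".csv")
  f_py <- tempfile(fileext = ".py")
  utils::write.table(mat, f_in, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  writeLines(sprintf("
import numpy as np
from skimage.feature import graycomatrix, graycoprops
img = np.loadtxt(r'%s', delimiter=',').astype(np.uint8)
G = %d
P = graycomatrix(img, distances=[1], angles=[0], levels=G,
                 symmetric=True, normed=True)
props = [graycoprops(P, p)[0, 0]
         for p in ('contrast', 'ASM', 'correlation', 'homogeneity')]
out = np.vstack([P[:, :, 0, 0], np.array(props + [0.0] * (G - 4))[None, :]])
np.savetxt(r'%s', out, delimiter=',')
", f_in, levels, f_out), f_py)
  status <- system2("python", f_py, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("scikit-image cross-check script failed")
  raw <- as.matrix(utils::read.csv(f_out, header = FALSE))
  list(
    P = unname(raw[seq_len(levels), , drop = FALSE]),
    props = c(contrast = raw[levels + 1, 1], ASM = raw[levels + 1, 2],
              correlation = raw[levels + 1, 3], IDM = raw[levels + 1, 4])
  )
}

# Random test image helper.
random_gray <- function(h, w, levels, seed) {
  with_seed <- get("with_seed", envir = asNamespace("hamqa"))
  with_seed(seed, gray_image(matrix(sample.int(levels, h * w, replace = TRUE) - 1L, h, w),
                             levels = levels))
}

rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
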