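#' Grey-level image container
#'
#' A `gray_image` is an integer matrix of pixel intensities in
#' `[0, levels - 1]` together with its quantization depth. It is the
#' substrate of all texture computations: first-order statistics are
#' taken on the full-depth (256-level) image, while co-occurrence and
#' run-length matrices are built on a coarser quantization.
#'
#' @param pixels integer matrix, values in `[0, levels - 1]`, at least 2x2.
#' @param levels quantization depth G (>= 2).
#' @return an object of class `gray_image`.
#' @export
gray_image <- function(pixels, levels = 256L) {
  pixels <- as.matrix(pixels)
  levels <- as.integer(levels)
  if (levels < 2L) stop("`levels` must be >= 2", call. = FALSE)
  if (nrow(pixels) < 2L || ncol(pixels) < 2L) {
    stop("image must be at least 2x2", call. = FALSE)
  }
  if (anyNA(pixels)) stop("image contains missing pixels", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) >= levels) {
    stop("pixel values must lie in [0, levels - 1]", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, levels = levels), class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image %d x %d, %d levels>\n",
    nrow(x$pixels), ncol(x$pixels), x$levels
  ))
  invisible(x)
}

#' Convert an RGB image to 8-bit grayscale
#'
#' Uses the standard luma weighting 0.299 R + 0.587 G + 0.114 B and
#' rounds to the nearest integer; the result has 256 grey levels.
#' Channel values may be on the `[0, 1]` scale (as returned by
#' [png::readPNG()]) or already 8-bit `[0, 255]`.
#'
#' @param rgb numeric array `height x width x 3`.
#' @return a [gray_image] with 256 levels.
#' @export
to_grayscale <- function(rgb) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) {
    stop("expected a 3-channel (height x width x 3) RGB array", call. = FALSE)
  }
  if (max(rgb) <= 1) rgb <- rgb * 255
  g <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  gray_image(pmin(pmax(round(g), 0), 255), levels = 256L)
}

#' Requantize a grey-level image
#'
#' Uniform binning `floor(pixel * levels / G)`; intensity ordering is
#' preserved. Used to bring 256-level images down to the depth at which
#' co-occurrence and run-length matrices are statistically filled.
#'
#' @param img a [gray_image].
#' @param levels target depth (>= 2, <= current depth).
#' @return a [gray_image] with `levels` levels.
#' @export
quantize <- function(img, levels) {
  stopifnot(inherits(img, "gray_image"))
  levels <- as.integer(levels)
  if (levels < 2L) stop("`levels` must be >= 2", call. = FALSE)
  if (levels > img$levels) {
    stop("cannot quantize upwards: `levels` exceeds current depth", call. = FALSE)
  }
  gray_image((img$pixels * levels) %/% img$levels, levels = levels)
}

#' Central rectangular region of interest
#'
#' Keeps the central `frac` of each dimension, excluding background
#' around a photographed slice.
#'
#' @param img a [gray_image].
#' @param frac fraction of each dimension to keep (default 0.6).
#' @return a [gray_image].
#' @export
crop_center <- function(img, frac = 0.6) {
  stopifnot(inherits(img, "gray_image"), frac > 0, frac <= 1)
  h <- nrow(img$pixels)
  w <- ncol(img$pixels)
  kh <- max(2L, floor(h * frac))
  kw <- max(2L, floor(w * frac))
  r0 <- floor((h - kh) / 2) + 1L
  c0 <- floor((w - kw) / 2) + 1L
  gray_image(img$pixels[r0:(r0 + kh - 1L), c0:(c0 + kw - 1L)], img$levels)
}

#' First-order histogram statistics
#'
#' Population moments of the pixel-intensity distribution: mean,
#' standard deviation, skewness (m3 / sd^3) and kurtosis (m4 / sd^4,
#' raw, so a normal histogram gives 3). On a constant image the sd is 0
#' and skewness/kurtosis are undefined; they propagate as `NA`.
#'
#' @param img a [gray_image].
#' @return named numeric vector `mean`, `sd`, `skewness`, `kurtosis`.
#' @export
first_order_stats <- function(img) {
  stopifnot(inherits(img, "gray_image"))
  x <- as.numeric(img$pixels)
  m <- mean(x)
  v <- mean((x - m)^2)
  s <- sqrt(v)
  if (s == 0) {
    return(c(mean = m, sd = 0, skewness = NA_real_, kurtosis = NA_real_))
  }
  c(
    mean = m, sd = s,
    skewness = mean((x - m)^3) / s^3,
    kurtosis = mean((x - m)^4) / s^4
  )
}

# Row/column offsets of the four standard directions. Angles follow the
# usual image convention: 0 = horizontal, 90 = vertical, 45/135 the two
# diagonals. Row offsets are negative because row indices grow downwards.
.dir_offset <- function(angle) {
  switch(as.character(angle),
    "0"   = c(0L, 1L),
    "45"  = c(-1L, 1L),
    "90"  = c(-1L, 0L),
    "135" = c(-1L, -1L),
    stop("direction must be one of 0, 45, 90, 135 degrees", call. = FALSE)
  )
}

#' Grey-level co-occurrence matrix
#'
#' Counts pairs of intensities at pixel offset `d` along the requested
#' directions, accumulated over directions, optionally symmetrized
#' (counting each pair in both orders), and normalized to sum 1.
#'
#' @param img a [gray_image] (typically already quantized).
#' @param d offset distance in pixels (default 1).
#' @param angles directions in degrees, subset of `c(0, 45, 90, 135)`.
#' @param symmetric logical; count ordered pairs both ways (default TRUE).
#' @return a `G x G` matrix summing to 1, with attributes `d`, `angles`,
#'   `symmetric`.
#' @export
cooccurrence <- function(img, d = 1L, angles = c(0, 45, 90, 135),
                         symmetric = TRUE) {
  stopifnot(inherits(img, "gray_image"), d >= 1)
  d <- as.integer(d)
  g <- img$levels
  px <- img$pixels
  h <- nrow(px)
  w <- ncol(px)
  counts <- numeric(g * g)
  for (ang in angles) {
    off <- .dir_offset(ang) * d
    rows <- seq_len(h)[(seq_len(h) + off[1]) >= 1 & (seq_len(h) + off[1]) <= h]
    cols <- seq_len(w)[(seq_len(w) + off[2]) >= 1 & (seq_len(w) + off[2]) <= w]
    if (length(rows) == 0 || length(cols) == 0) next
    a <- px[rows, cols, drop = FALSE]
    b <- px[rows + off[1], cols + off[2], drop = FALSE]
    counts <- counts + tabulate(as.integer(a) * g + as.integer(b) + 1L,
                                nbins = g * g)
    if (symmetric) {
      counts <- counts + tabulate(as.integer(b) * g + as.integer(a) + 1L,
                                  nbins = g * g)
    }
  }
  total <- sum(counts)
  if (total == 0) {
    stop("no valid pixel pair at offset d in the requested directions",
         call. = FALSE)
  }
  p <- matrix(counts / total, g, g, byrow = TRUE) # row = first level
  structure(p, d = d, angles = angles, symmetric = symmetric)
}

#' The thirteen co-occurrence (Haralick) features
#'
#' Computed from a normalized co-occurrence matrix, in the fixed order
#' ASM, contrast, correlation, sum of squares, IDM, entropy, sum
#' entropy, sum average, sum variance, difference variance, difference
#' entropy, IMC1, IMC2. Entropies use log base 2. Grey levels enter the
#' moment-type features as their 0-based values. Sum variance is taken
#' about the sum average. On a matrix with zero marginal variance
#' (constant image) correlation, IMC1 and IMC2 are undefined and
#' returned as `NA`.
#'
#' @param p normalized `G x G` co-occurrence matrix (sums to 1).
#' @return named numeric vector of length 13.
#' @export
haralick_features <- function(p) {
  p <- unclass(as.matrix(p))
  g <- nrow(p)
  stopifnot(ncol(p) == g, abs(sum(p) - 1) < 1e-8)
  lev <- 0:(g - 1)

  px <- rowSums(p)
  py <- colSums(p)
  mux <- sum(lev * px)
  muy <- sum(lev * py)
  sx <- sqrt(sum((lev - mux)^2 * px))
  sy <- sqrt(sum((lev - muy)^2 * py))

  asm <- sum(p^2)
  idm <- sum(p / (1 + outer(lev, lev, function(i, j) (i - j)^2)))
  entropy <- -sum(xlog2(p))

  # p_{x+y}(k), k = 0..2G-2 and p_{x-y}(k), k = 0..G-1 on 0-based levels
  isum <- outer(lev, lev, `+`)
  idiff <- abs(outer(lev, lev, `-`))
  pxy_sum <- vapply(0:(2 * g - 2), function(k) sum(p[isum == k]), numeric(1))
  pxy_dif <- vapply(0:(g - 1), function(k) sum(p[idiff == k]), numeric(1))

  ks <- 0:(2 * g - 2)
  kd <- 0:(g - 1)
  contrast <- sum(kd^2 * pxy_dif)
  sum_average <- sum(ks * pxy_sum)
  sum_variance <- sum((ks - sum_average)^2 * pxy_sum)
  sum_entropy <- -sum(xlog2(pxy_sum))
  dif_mean <- sum(kd * pxy_dif)
  difference_variance <- sum((kd - dif_mean)^2 * pxy_dif)
  difference_entropy <- -sum(xlog2(pxy_dif))
  sum_of_squares <- sum(outer((lev - mux)^2, rep(1, g)) * p)

  correlation <- if (sx == 0 || sy == 0) NA_real_ else {
    (sum(outer(lev, lev) * p) - mux * muy) / (sx * sy)
  }

  hx <- -sum(xlog2(px))
  hy <- -sum(xlog2(py))
  pxpy <- outer(px, py)
  hxy1 <- -sum(p[pxpy > 0] * log2(pxpy[pxpy > 0]))
  hxy2 <- -sum(xlog2(pxpy))
  imc1 <- if (max(hx, hy) == 0) NA_real_ else (entropy - hxy1) / max(hx, hy)
  imc2 <- if (max(hx, hy) == 0) NA_real_ else {
    sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  }

  c(
    ASM = asm, contrast = contrast, correlation = correlation,
    sum_of_squares = sum_of_squares, IDM = idm, entropy = entropy,
    sum_entropy = sum_entropy, sum_average = sum_average,
    sum_variance = sum_variance, difference_variance = difference_variance,
    difference_entropy = difference_entropy, IMC1 = imc1, IMC2 = imc2
  )
}

# Decompose the image into the scan lines of one direction.
.scan_lines <- function(px, angle) {
  h <- nrow(px)
  w <- ncol(px)
  switch(as.character(angle),
    "0"   = lapply(seq_len(h), function(r) px[r, ]),
    "90"  = lapply(seq_len(w), function(c) px[, c]),
    # 45 degrees: anti-diagonals (constant row + col)
    "45"  = split(px, row(px) + col(px)),
    # 135 degrees: main diagonals (constant col - row)
    "135" = split(px, col(px) - row(px)),
    stop("direction must be one of 0, 45, 90, 135 degrees", call. = FALSE)
  )
}

#' Grey-level run-length matrix
#'
#' `R[g, l]` counts the maximal collinear runs of grey level `g`
#' (0-based, row `g + 1`) with length `l` along one direction. Every
#' pixel belongs to exactly one run, so `sum(R * length)` equals the
#' pixel count.
#'
#' @param img a [gray_image] (typically quantized).
#' @param angle scan direction: 0, 45, 90 or 135 degrees.
#' @return integer matrix `G x Lmax` with attribute `num_pixels`.
#' @export
run_length <- function(img, angle = 0) {
  stopifnot(inherits(img, "gray_image"))
  g <- img$levels
  lines <- .scan_lines(img$pixels, angle)
  runs <- lapply(lines, function(v) rle(as.integer(v)))
  vals <- unlist(lapply(runs, `[[`, "values"), use.names = FALSE)
  lens <- unlist(lapply(runs, `[[`, "lengths"), use.names = FALSE)
  lmax <- max(nrow(img$pixels), ncol(img$pixels))
  r <- matrix(
    tabulate((lens - 1L) * g + vals + 1L, nbins = g * lmax),
    nrow = g, ncol = lmax
  )
  structure(r, num_pixels = length(img$pixels), angle = angle)
}

#' Run-length matrix features
#'
#' Short-run emphasis, long-run emphasis, grey-level nonuniformity,
#' run-length nonuniformity and run percentage, with `N` the total
#' number of runs:
#' \deqn{SRE = \frac{1}{N}\sum R_{gl}/l^2,\quad
#'       LRE = \frac{1}{N}\sum R_{gl} l^2,\quad
#'       GLNU = \frac{1}{N}\sum_g (\sum_l R_{gl})^2,}
#' \deqn{RLNU = \frac{1}{N}\sum_l (\sum_g R_{gl})^2,\quad
#'       RP = N / \mathrm{pixels}.}
#'
#' @param r run-length matrix from [run_length()].
#' @param num_pixels pixels scanned; defaults to the matrix attribute.
#' @return named numeric vector `SRE`, `LRE`, `GLNU`, `RLNU`, `RP`.
#' @export
rlm_features <- function(r, num_pixels = attr(r, "num_pixels")) {
  r <- unclass(as.matrix(r))
  n <- sum(r)
  if (n == 0) stop("run-length matrix contains no runs", call. = FALSE)
  l <- seq_len(ncol(r))
  rl <- colSums(r) # runs per length
  rg <- rowSums(r) # runs per grey level
  c(
    SRE = sum(rl / l^2) / n,
    LRE = sum(rl * l^2) / n,
    GLNU = sum(rg^2) / n,
    RLNU = sum(rl^2) / n,
    RP = n / num_pixels
  )
}

#' Texture extraction configuration
#'
#' @param levels quantization depth for co-occurrence and run-length
#'   matrices (first-order statistics always use the full 256 levels).
#' @param d co-occurrence offset distance in pixels.
#' @param angles directions averaged over, degrees.
#' @param roi_frac central-crop fraction applied before any computation;
#'   `NULL` disables cropping (synthetic images have no background).
#' @return a list of class `texture_config`.
#' @export
texture_config <- function(levels = 32L, d = 1L, angles = c(0, 45, 90, 135),
                           roi_frac = NULL) {
  structure(
    list(levels = as.integer(levels), d = as.integer(d),
         angles = angles, roi_frac = roi_frac),
    class = "texture_config"
  )
}

#' The 22-slot texture feature vector
#'
#' First-order statistics are computed on the unquantized 256-level
#' image; the 13 co-occurrence features on the quantized image with
#' counts accumulated over the configured directions; the 5 run-length
#' features per direction and then averaged. Undefined features on
#' degenerate (e.g. constant) images propagate as `NA`.
#'
#' @param img a [gray_image] with 256 levels, or an RGB array.
#' @param cfg a [texture_config].
#' @return named numeric vector of length 22 in the order of
#'   [texture_feature_names()].
#' @export
texture_features <- function(img, cfg = texture_config()) {
  if (is.array(img) && length(dim(img)) == 3L) img <- to_grayscale(img)
  stopifnot(inherits(img, "gray_image"), inherits(cfg, "texture_config"))
  if (!is.null(cfg$roi_frac)) img <- crop_center(img, cfg$roi_frac)

  fo <- first_order_stats(img)
  q <- quantize(img, cfg$levels)
  har <- haralick_features(cooccurrence(q, d = cfg$d, angles = cfg$angles,
                                        symmetric = TRUE))
  rlm <- rowMeans(vapply(
    cfg$angles,
    function(ang) rlm_features(run_length(q, ang)),
    numeric(5)
  ))
  out <- c(fo, har, rlm)
  names(out) <- texture_feature_names()
  out
}

#' Read a PNG image as a grey-level image
#'
#' 8-bit RGB images are converted with [to_grayscale()]; single-channel
#' images are rescaled to 256 levels directly. An alpha channel, if
#' present, is dropped.
#'
#' @param path path to a PNG file.
#' @return a [gray_image] with 256 levels.
#' @export
read_image_gray <- function(path) {
  x <- png::readPNG(path)
  if (is.matrix(x)) {
    return(gray_image(round(x * 255), levels = 256L))
  }
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  to_grayscale(x)
}
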