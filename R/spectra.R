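#' FT-IR spectrum container
#'
#' A wavenumber/absorbance series. Wavenumbers must be strictly
#' monotone (instruments scan 4000 -> 500 cm-1; ascending storage is
#' accepted and handled identically).
#'
#' @param wavenumber numeric vector, cm-1, strictly monotone.
#' @param absorbance numeric vector of the same length.
#' @return an object of class `spectrum`.
#' @export
spectrum <- function(wavenumber, absorbance) {
  stopifnot(length(wavenumber) == length(absorbance), length(wavenumber) >= 2)
  d <- diff(wavenumber)
  if (!(all(d > 0) || all(d < 0))) {
    stop("wavenumbers must be strictly monotone", call. = FALSE)
  }
  structure(list(wavenumber = as.numeric(wavenumber),
                 absorbance = as.numeric(absorbance)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %d points, %.0f-%.0f cm-1>\n",
              length(x$wavenumber), max(x$wavenumber), min(x$wavenumber)))
  invisible(x)
}

#' Read a two-column wavenumber/absorbance CSV
#'
#' @param path CSV with columns `wavenumber`, `absorbance` (or any two
#'   columns in that order).
#' @return a [spectrum].
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  spectrum(df[[1]], df[[2]])
}

#' Diagnostic mid-infrared band registry
#'
#' The fifteen absorbance regions used throughout the analysis, plus two
#' auxiliary diagnostics: the 717 cm-1 unsaturation marker and the
#' 1083 cm-1 symmetric P=O band. Single-wavenumber regions are expanded
#' to `center +/- half_window` (default 8 cm-1, twice the nominal 4 cm-1
#' resolution). The registry ships as a plain CSV and can be replaced.
#'
#' @param include_aux include the auxiliary 717/1083 rows (default FALSE).
#' @param half_window expansion for single-wavenumber regions, cm-1.
#' @param path registry file; defaults to the CSV shipped with the package.
#' @return data.frame with columns `band`, `low`, `high`, `assignment`.
#' @export
ftir_bands <- function(include_aux = FALSE, half_window = 8,
                       path = system.file("extdata", "ftir_bands.csv",
                                          package = "hamqa")) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  pointlike <- reg$low == reg$high
  reg$low[pointlike] <- reg$low[pointlike] - half_window
  reg$high[pointlike] <- reg$high[pointlike] + half_window
  if (!include_aux) reg <- reg[!reg$aux, , drop = FALSE]
  rownames(reg) <- NULL
  reg[, c("band", "low", "high", "assignment")]
}

#' Linear baseline correction anchored at two quiet wavenumbers
#'
#' Subtracts the straight line through the absorbances at the sample
#' points nearest to the two anchors (defaults 3800 and 520 cm-1, both
#' outside every diagnostic band).
#'
#' @param s a [spectrum].
#' @param anchors two anchor wavenumbers, cm-1.
#' @return a baseline-corrected [spectrum].
#' @export
baseline_correct <- function(s, anchors = c(3800, 520)) {
  stopifnot(inherits(s, "spectrum"), length(anchors) == 2)
  i1 <- which.min(abs(s$wavenumber - anchors[1]))
  i2 <- which.min(abs(s$wavenumber - anchors[2]))
  if (i1 == i2) stop("baseline anchors coincide on this grid", call. = FALSE)
  x1 <- s$wavenumber[i1]; y1 <- s$absorbance[i1]
  x2 <- s$wavenumber[i2]; y2 <- s$absorbance[i2]
  slope <- (y2 - y1) / (x2 - x1)
  spectrum(s$wavenumber, s$absorbance - (y1 + slope * (s$wavenumber - x1)))
}

#' Band intensity: maximum absorbance inside a wavenumber window
#'
#' Table-style band intensities are peak absorbances, so the intensity
#' of a region is the maximum of the (optionally baseline-corrected)
#' absorbance over the window.
#'
#' @param s a [spectrum].
#' @param low,high window bounds in cm-1 (`high` defaults to `low`,
#'   i.e. a point region already expanded by the registry).
#' @param baseline apply [baseline_correct()] first (default FALSE;
#'   enable for instrument spectra with offset baselines).
#' @return peak absorbance within the window.
#' @export
band_intensity <- function(s, low, high = low, baseline = FALSE) {
  stopifnot(inherits(s, "spectrum"), low <= high)
  if (baseline) s <- baseline_correct(s)
  inside <- s$wavenumber >= low & s$wavenumber <= high
  if (!any(inside)) {
    stop(sprintf("band [%g, %g] cm-1 contains no sample point", low, high),
         call. = FALSE)
  }
  max(s$absorbance[inside])
}

#' Band-intensity table for one or more spectra
#'
#' @param spectra a [spectrum] or a (optionally named) list of them.
#' @param bands band registry as from [ftir_bands()].
#' @param baseline passed to [band_intensity()].
#' @return data.frame, one row per spectrum with a `sample_id` column
#'   and one column per band (band names preserved verbatim).
#' @export
band_table <- function(spectra, bands = ftir_bands(), baseline = FALSE) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  ids <- names(spectra)
  if (is.null(ids)) ids <- as.character(seq_along(spectra))
  rows <- lapply(spectra, function(s) {
    vapply(seq_len(nrow(bands)), function(i) {
      tryCatch(
        band_intensity(s, bands$low[i], bands$high[i], baseline = baseline),
        error = function(e) NA_real_
      )
    }, numeric(1))
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- bands$band
  cbind(data.frame(sample_id = ids, stringsAsFactors = FALSE), out)
}

#' Carbonyl-to-phosphate band ratio and its attribution
#'
#' Ratio of the ester C=O intensity near 1744 cm-1 to the asymmetric
#' P=O intensity at 1240 cm-1. Ratios between 1.9 and 2.3 attribute the
#' P=O band to phospholipids; ratios outside that interval attribute it
#' to nucleic acids.
#'
#' @param i1744,i1240 band intensities (vectorized).
#' @return data.frame with columns `ratio` and `attribution`.
#' @export
co_po_ratio <- function(i1744, i1240) {
  if (any(i1240 <= 0)) {
    stop("P=O (1240 cm-1) intensity must be positive", call. = FALSE)
  }
  ratio <- i1744 / i1240
  data.frame(
    ratio = ratio,
    attribution = ifelse(ratio >= 1.9 & ratio <= 2.3,
                         "phospholipid", "nucleic_acid"),
    stringsAsFactors = FALSE
  )
}

#' Is a band present at a given position?
#'
#' A band is called present when a local maximum inside
#' `center +/- half_window` has prominence greater than `k` times the
#' spectrum's noise scale (median absolute successive difference).
#' Prominence is the peak height above the higher of the two minima
#' separating the peak from taller terrain on either side (search capped
#' at `reach` samples).
#'
#' @param s a [spectrum].
#' @param center band position, cm-1.
#' @param half_window search half-width, cm-1 (default 8).
#' @param k prominence threshold in noise-scale units (default 5).
#' @param reach maximum samples to walk when measuring prominence.
#' @return logical.
#' @export
band_presence <- function(s, center, half_window = 8, k = 5, reach = 40L) {
  stopifnot(inherits(s, "spectrum"))
  a <- s$absorbance
  wn <- s$wavenumber
  inside <- which(wn >= center - half_window & wn <= center + half_window)
  if (length(inside) == 0) {
    stop("band center outside the spectrum range", call. = FALSE)
  }
  noise <- stats::median(abs(diff(a)))
  im <- inside[which.max(a[inside])]
  n <- length(a)
  if (im == 1L || im == n) return(FALSE)

  side_min <- function(step) {
    j <- im + step
    lo <- a[im]
    seen <- FALSE
    steps <- 0L
    while (j >= 1L && j <= n && steps < reach) {
      if (a[j] > a[im]) return(if (seen) lo else a[im])
      lo <- min(lo, a[j])
      seen <- TRUE
      j <- j + step
      steps <- steps + 1L
    }
    lo
  }
  prominence <- a[im] - max(side_min(-1L), side_min(1L))
  is.finite(prominence) && prominence > k * noise
}

#' Pearson correlations between colour parameters and band intensities
#'
#' @param colors data.frame of colour features with a `sample_id` column.
#' @param bands band-intensity table with a `sample_id` column.
#' @param pairs data.frame with columns `color` and `band` naming the
#'   requested pairs.
#' @return data.frame with columns `color`, `band`, `n`, `r`, `p`.
#'   Pairs with zero variance in either variable get `NA` with a warning.
#' @export
color_band_correlation <- function(colors, bands, pairs) {
  stopifnot("sample_id" %in% names(colors), "sample_id" %in% names(bands))
  merged <- merge(colors, bands, by = "sample_id")
  if (nrow(merged) < 3) stop("need at least 3 matched samples", call. = FALSE)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- merged[[pairs$color[i]]]
    y <- merged[[pairs$band[i]]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning(sprintf("correlation undefined for (%s, %s)",
                      pairs$color[i], pairs$band[i]), call. = FALSE)
      return(data.frame(color = pairs$color[i], band = pairs$band[i],
                        n = length(x), r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(color = pairs$color[i], band = pairs$band[i],
               n = length(x), r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, out)
}
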