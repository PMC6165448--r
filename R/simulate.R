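#' Synthetic colorimeter readings for a ham class
#'
#' L*, a*, b* are drawn independently from normal distributions with the
#' class means and standard deviations; chroma, hue and colour
#' difference are always derived downstream, never sampled.
#'
#' @param class ham class name (see [ham_class_names()]) or a spec from
#'   [ham_classes()].
#' @param n number of replicates.
#' @param seed integer seed.
#' @return data.frame `sample_id`, `class`, `L`, `a`, `b`.
#' @export
gen_color <- function(class, n = 30, seed = 1L) {
  spec <- if (is.character(class)) ham_classes(class) else class
  stopifnot(n >= 1)
  with_seed(seed, {
    data.frame(
      sample_id = sprintf("%s_%03d", spec$class, seq_len(n)),
      class = spec$class,
      L = stats::rnorm(n, spec$color_mean[["L"]], spec$color_sd[["L"]]),
      a = stats::rnorm(n, spec$color_mean[["a"]], spec$color_sd[["a"]]),
      b = stats::rnorm(n, spec$color_mean[["b"]], spec$color_sd[["b"]]),
      stringsAsFactors = FALSE
    )
  })
}

# Band centers used by the spectrum generator: midpoint of the raw
# registry region, snapped to the 4 cm-1 acquisition grid so a peak
# maximum coincides with a sample point.
.band_centers <- function(bands) {
  raw <- utils::read.csv(system.file("extdata", "ftir_bands.csv",
                                     package = "hamqa"))
  centers <- (raw$low + raw$high) / 2
  names(centers) <- raw$band
  4 * round(centers[bands] / 4)
}

.drift_ramp <- function(day) {
  ifelse(day <= 10, 0, (day - 10) / 10)
}

#' Synthetic FT-IR spectrum for a ham class
#'
#' Sum of Gaussian bands (FWHM 15 cm-1) at the registry band centers on
#' a 4 cm-1 grid from 4000 down to 500 cm-1. Amplitudes are the class
#' band means scaled by the storage drift (zero before day 10, linear to
#' the signed day-20 fraction thereafter) plus normal amplitude noise
#' with the class band spreads, and white noise is added to the whole
#' trace. Turkey classes additionally carry the 717 cm-1 unsaturation
#' marker band; pork classes do not.
#'
#' @param class ham class name or spec.
#' @param day storage day (default 0).
#' @param seed integer seed.
#' @param band_noise draw amplitude noise (default TRUE).
#' @param white_noise_sd white-noise standard deviation on the trace
#'   (default 0.001; set 0 for noise-free spectra).
#' @param width_fwhm band full width at half maximum, cm-1.
#' @return a [spectrum].
#' @export
gen_spectrum <- function(class, day = 0, seed = 1L, band_noise = TRUE,
                         white_noise_sd = 0.001, width_fwhm = 15) {
  spec <- if (is.character(class)) ham_classes(class) else class
  stopifnot(day >= 0)
  wn <- seq(4000, 500, by = -4)
  width_sd <- width_fwhm / (2 * sqrt(2 * log(2)))
  centers <- .band_centers(spec$bands$band)
  ramp <- .drift_ramp(day)
  with_seed(seed, {
    amp <- spec$bands$mean * (1 + spec$bands$drift * ramp)
    if (band_noise) amp <- amp + stats::rnorm(length(amp), 0, spec$bands$sd)
    amp <- pmax(amp, 0)
    a <- numeric(length(wn))
    for (i in seq_along(amp)) {
      a <- a + amp[i] * exp(-(wn - centers[i])^2 / (2 * width_sd^2))
    }
    if (!is.null(spec$marker_717)) {
      m <- spec$marker_717[["mean"]]
      if (band_noise) m <- m + stats::rnorm(1, 0, spec$marker_717[["sd"]])
      a <- a + max(m, 0) * exp(-(wn - 716)^2 / (2 * width_sd^2))
    }
    if (white_noise_sd > 0) {
      a <- a + stats::rnorm(length(wn), 0, white_noise_sd)
    }
    spectrum(wn, a)
  })
}

# Separable Gaussian smoothing with circular boundary, used to give the
# blob field its correlation length.
.smooth2d <- function(z, scale) {
  if (scale <= 0) return(z)
  kern <- function(len) {
    half <- min(max(1L, ceiling(3 * scale)), (len - 1L) %/% 2L)
    k <- exp(-((-half):half)^2 / (2 * scale^2))
    k / sum(k)
  }
  sm <- stats::filter(z, kern(nrow(z)), method = "convolution", sides = 2,
                      circular = TRUE)
  sm <- stats::filter(t(sm), kern(ncol(z)), method = "convolution",
                      sides = 2, circular = TRUE)
  t(matrix(as.numeric(sm), nrow = ncol(z)))
}

#' Synthetic slice image for a ham class
#'
#' Luminance field = class base level (from its mean CIELAB colour) +
#' smoothed Gaussian blob field + elongated horizontal streak plateaus +
#' i.i.d. pixel noise, clipped to 8 bits and tinted with the class mean
#' colour (Lab -> sRGB, D65). The per-class texture parameters are
#' preset so that the documented class orderings of ASM, LRE, intensity
#' SD and GLNU hold across the default specs.
#'
#' @param class ham class name or spec.
#' @param size image side(s) in pixels, scalar or `c(height, width)`,
#'   minimum 64.
#' @param seed integer seed.
#' @return numeric array `height x width x 3` on `[0, 1]`.
#' @export
gen_image <- function(class, size = 128L, seed = 1L) {
  spec <- if (is.character(class)) ham_classes(class) else class
  if (length(size) == 1) size <- c(size, size)
  stopifnot(all(size >= 64))
  h <- as.integer(size[1]); w <- as.integer(size[2])
  tx <- spec$texture

  lab <- spec$color_mean
  rgb <- as.numeric(grDevices::convertColor(
    matrix(c(lab[["L"]], lab[["a"]], lab[["b"]]), 1),
    from = "Lab", to = "sRGB", to.ref.white = "D65", clip = TRUE
  ))
  luma <- sum(c(0.299, 0.587, 0.114) * rgb)
  base <- luma * 255

  with_seed(seed, {
    field <- matrix(0, h, w)
    if (tx$blob_amp > 0) {
      z <- .smooth2d(matrix(stats::rnorm(h * w), h, w), tx$blob_scale)
      field <- field + tx$blob_amp * z / stats::sd(z)
    }
    if (tx$streak_density > 0) {
      n_streaks <- round(tx$streak_density * h)
      rows <- sample.int(h, n_streaks, replace = TRUE)
      starts <- sample.int(max(1L, w - tx$streak_len), n_streaks,
                           replace = TRUE)
      signs <- sample(c(-1, 1), n_streaks, replace = TRUE)
      for (s in seq_len(n_streaks)) {
        cols <- starts[s]:min(w, starts[s] + tx$streak_len - 1L)
        field[rows[s], cols] <- field[rows[s], cols] + signs[s] * tx$streak_amp
      }
    }
    if (tx$noise_sd > 0) {
      field <- field + matrix(stats::rnorm(h * w, 0, tx$noise_sd), h, w)
    }
    y <- pmin(pmax(base + field, 0), 255) / 255
    out <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      out[, , ch] <- pmin(pmax(y * rgb[ch] / luma, 0), 1)
    }
    out
  })
}

#' Simulation design for a synthetic storage study
#'
#' @param classes ham classes included (default all five).
#' @param n replicates per class and day (>= 2).
#' @param days sampling days; the default is a 3-day interval over three
#'   weeks of refrigerated storage.
#' @param seed root seed; every generated artefact derives from it.
#' @param image_size side of the generated images in pixels.
#' @return list of class `study_design`.
#' @export
study_design <- function(classes = ham_class_names(), n = 30,
                         days = seq(0, 21, by = 3), seed = 1L,
                         image_size = 128L) {
  stopifnot(n >= 2, all(classes %in% ham_class_names()))
  structure(
    list(classes = classes, n = as.integer(n), days = days,
         seed = as.integer(seed), image_size = as.integer(image_size)),
    class = "study_design"
  )
}

#' Feature table of the synthetic discrimination experiment
#'
#' Generates `n` slice images and colorimeter readings per class (one
#' time point), extracts the 22 texture features from each image, and
#' binds the 6 derived colour features: the 28-column pattern table on
#' which the classifiers operate.
#'
#' @param classes ham classes (default all five).
#' @param n replicates per class.
#' @param seed integer seed.
#' @param image_size image side in pixels.
#' @param cfg texture configuration ([texture_config()]); synthetic
#'   images carry no background, so no ROI crop is applied by default.
#' @param ref colour-difference reference.
#' @return data.frame: `sample_id`, `class`, then the 28 feature columns
#'   in the order of [ham_feature_names()].
#' @export
gen_feature_table <- function(classes = ham_class_names(), n = 30,
                              seed = 1L, image_size = 128L,
                              cfg = texture_config(),
                              ref = white_reference()) {
  seeds <- with_seed(seed, {
    matrix(sample.int(.Machine$integer.max - 1L, length(classes) * n),
           nrow = n)
  })
  out <- lapply(seq_along(classes), function(ci) {
    cl <- classes[ci]
    colors <- gen_color(cl, n = n, seed = seeds[1, ci])
    tex <- t(vapply(seq_len(n), function(i) {
      texture_features(gen_image(cl, size = image_size,
                                 seed = seeds[i, ci]), cfg)
    }, numeric(22)))
    cbind(
      colors[, c("sample_id", "class")],
      as.data.frame(tex),
      color_features(colors$L, colors$a, colors$b, ref)
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Band-intensity series across storage days
#'
#' Generates spectra for every class x day x replicate cell of the
#' design and extracts their band table, round-tripping through the
#' spectra module.
#'
#' @param design a [study_design()].
#' @param band_noise,white_noise_sd passed to [gen_spectrum()].
#' @return data.frame: `sample_id`, `class`, `day`, then one column per
#'   registry band.
#' @export
gen_band_series <- function(design = study_design(),
                            band_noise = TRUE, white_noise_sd = 0.001) {
  cells <- expand.grid(rep = seq_len(design$n), day = design$days,
                       class = design$classes, stringsAsFactors = FALSE)
  seeds <- with_seed(design$seed,
                     sample.int(.Machine$integer.max - 1L, nrow(cells)))
  bands <- ftir_bands()
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    s <- gen_spectrum(cells$class[i], day = cells$day[i], seed = seeds[i],
                      band_noise = band_noise,
                      white_noise_sd = white_noise_sd)
    bt <- band_table(s, bands)
    bt$sample_id <- sprintf("%s_d%02d_%03d", cells$class[i], cells$day[i],
                            cells$rep[i])
    cbind(bt[, "sample_id", drop = FALSE],
          data.frame(class = cells$class[i], day = cells$day[i]),
          bt[, -1, drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a full synthetic study bundle on disk
#'
#' Writes the complete cross of classes x days x replicates: PNG images
#' under `images/<class>/`, colorimeter readings in `colors.csv`,
#' two-column spectra under `spectra/`, and a `manifest.json` recording
#' the design, seed and package version.
#'
#' @param design a [study_design()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest as a list.
#' @export
gen_study <- function(design = study_design(), out_dir) {
  stopifnot(inherits(design, "study_design"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "spectra"), showWarnings = FALSE)
  cells <- expand.grid(rep = seq_len(design$n), day = design$days,
                       class = design$classes, stringsAsFactors = FALSE)
  seeds <- with_seed(design$seed, {
    list(
      color = sample.int(.Machine$integer.max - 1L,
                         length(design$classes) * length(design$days)),
      cell = sample.int(.Machine$integer.max - 1L, nrow(cells))
    )
  })

  colors <- list()
  idx <- 0L
  for (cl in design$classes) {
    dir.create(file.path(out_dir, "images", cl), recursive = TRUE,
               showWarnings = FALSE)
    for (d in design$days) {
      idx <- idx + 1L
      cc <- gen_color(cl, n = design$n, seed = seeds$color[idx])
      cc$day <- d
      cc$sample_id <- sprintf("%s_d%02d_%03d", cl, d, seq_len(design$n))
      colors[[idx]] <- cc
    }
  }
  colors <- do.call(rbind, colors)
  utils::write.csv(colors[, c("sample_id", "class", "day", "L", "a", "b")],
                   file.path(out_dir, "colors.csv"), row.names = FALSE)

  for (i in seq_len(nrow(cells))) {
    cl <- cells$class[i]; d <- cells$day[i]; r <- cells$rep[i]
    stem <- sprintf("%s_d%02d_%03d", cl, d, r)
    img <- gen_image(cl, size = design$image_size, seed = seeds$cell[i])
    png::writePNG(img, file.path(out_dir, "images", cl,
                                 paste0(stem, ".png")))
    s <- gen_spectrum(cl, day = d, seed = seeds$cell[i])
    utils::write.csv(
      data.frame(wavenumber = s$wavenumber, absorbance = s$absorbance),
      file.path(out_dir, "spectra", paste0(stem, ".csv")),
      row.names = FALSE
    )
  }

  manifest <- list(
    design = list(classes = design$classes, n = design$n,
                  days = design$days, seed = design$seed,
                  image_size = design$image_size),
    package = as.character(utils::packageVersion("hamqa")),
    layout = list(images = "images/<class>/<class>_d<day>_<rep>.png",
                  spectra = "spectra/<class>_d<day>_<rep>.csv",
                  colors = "colors.csv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
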