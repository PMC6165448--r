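#' Class specifications for the five ham types
#'
#' The statistical parameters that condition every synthetic generator:
#' CIELAB colour means and standard deviations per class, the fifteen
#' mid-infrared band amplitudes (absorbance units) with their spreads,
#' per-band fractional storage drifts (signed change reached by day 20,
#' zero before day 10), the 717 cm-1 unsaturation marker (present in
#' turkey classes only), and the image-texture parameters that plant the
#' documented class orderings (ASM highest for boiled pork; LRE highest
#' for smoked pork; intensity SD higher for boiled than smoked turkey;
#' GLNU higher for smoked turkey).
#'
#' Texture parameters are on the 0-255 luminance scale: `noise_sd` is
#' i.i.d. per-pixel noise, `blob_amp`/`blob_scale` the amplitude and
#' correlation length of a smoothed Gaussian random field, and
#' `streak_*` the density (fraction of rows), length and amplitude of
#' elongated horizontal plateaus.
#'
#' @param class optional class name; one of
#'   `r paste0('\x60', paste(ham_class_names(), collapse = '\x60, \x60'), '\x60')`.
#' @return with `class`, a single spec (list); otherwise a named list of
#'   all five specs.
#' @export
ham_classes <- function(class = NULL) {
  specs <- .ham_specs()
  if (is.null(class)) return(specs)
  if (!class %in% names(specs)) {
    stop("unknown ham class: ", class, call. = FALSE)
  }
  specs[[class]]
}

#' @rdname ham_classes
#' @export
ham_class_names <- function() {
  c("turkey_boiled", "turkey_smoked", "pork_boiled", "pork_smoked",
    "pork_roasted")
}

# Colour statistics per class (CIELAB, colorimeter replicates, n = 30).
.color_params <- function() {
  data.frame(
    class = ham_class_names(),
    L_mean = c(66.76, 62.99, 54.41, 56.51, 58.20),
    L_sd   = c(3.36, 3.24, 3.31, 4.48, 1.33),
    a_mean = c(6.33, 4.77, 12.08, 11.98, 14.11),
    a_sd   = c(0.48, 0.82, 0.89, 0.85, 0.44),
    b_mean = c(11.12, 10.91, 7.74, 8.33, 10.19),
    b_sd   = c(1.16, 0.94, 0.42, 1.08, 0.58),
    stringsAsFactors = FALSE
  )
}

# Band-intensity statistics per class (absorbance units). Row order
# matches the band registry; columns are mean/sd per class.
.band_params <- function() {
  bands <- c("3500-3200", "3100-3020", "2950-2920", "2852", "1744",
             "1627", "1541", "1450", "1395", "1240", "1170-1154",
             "1117", "1040-1020", "966", "870")
  mean <- cbind(
    turkey_boiled = c(0.094, 0.036, 0.066, 0.080, 0.082, 0.064, 0.068,
                      0.077, 0.078, 0.056, 0.067, 0.066, 0.082, 0.012, 0.032),
    turkey_smoked = c(0.087, 0.028, 0.054, 0.068, 0.067, 0.051, 0.057,
                      0.064, 0.069, 0.051, 0.060, 0.064, 0.080, 0.015, 0.031),
    pork_boiled   = c(0.107, 0.022, 0.113, 0.122, 0.152, 0.078, 0.084,
                      0.098, 0.094, 0.096, 0.092, 0.087, 0.068, 0.009, 0.048),
    pork_smoked   = c(0.110, 0.019, 0.103, 0.108, 0.130, 0.083, 0.088,
                      0.099, 0.096, 0.092, 0.092, 0.087, 0.065, 0.013, 0.049),
    pork_roasted  = c(0.105, 0.020, 0.101, 0.105, 0.125, 0.082, 0.085,
                      0.097, 0.096, 0.091, 0.090, 0.086, 0.066, 0.009, 0.049)
  )
  sd <- cbind(
    turkey_boiled = c(0.002, 0.002, 0.002, 0.002, 0.003, 0.002, 0.003,
                      0.004, 0.001, 0.002, 0.002, 0.003, 0.001, 0.001, 0.002),
    turkey_smoked = c(0.003, 0.003, 0.001, 0.001, 0.003, 0.002, 0.001,
                      0.002, 0.003, 0.002, 0.002, 0.001, 0.001, 0.001, 0.001),
    pork_boiled   = c(0.002, 0.002, 0.004, 0.002, 0.004, 0.003, 0.004,
                      0.005, 0.003, 0.003, 0.003, 0.002, 0.001, 0.001, 0.002),
    pork_smoked   = c(0.004, 0.002, 0.002, 0.003, 0.003, 0.002, 0.002,
                      0.002, 0.003, 0.004, 0.001, 0.004, 0.003, 0.001, 0.001),
    pork_roasted  = c(0.003, 0.002, 0.002, 0.001, 0.002, 0.003, 0.005,
                      0.002, 0.002, 0.004, 0.004, 0.002, 0.003, 0.001, 0.002)
  )
  rownames(mean) <- rownames(sd) <- bands
  list(bands = bands, mean = mean, sd = sd)
}

# Signed fractional band drift reached by day 20 of refrigerated
# storage (zero before day 10): triglyceride ester and C-O bands and the
# protein amide bands decay; methyl/methylene, fatty-acid C-H and the
# trans-olefin marker grow; the olefinic C-H band decays. Bands not
# listed do not drift.
.band_drift <- function() {
  c("1744" = -0.10, "1170-1154" = -0.10, "1627" = -0.10, "1541" = -0.10,
    "3100-3020" = -0.10,
    "2950-2920" = 0.10, "2852" = 0.10, "1117" = 0.10, "966" = 0.10)
}

# Image-texture parameters per class (luminance scale 0-255).
.texture_params <- function() {
  list(
    turkey_boiled = list(noise_sd = 10, blob_amp = 28, blob_scale = 8,
                         streak_density = 0, streak_len = 0, streak_amp = 0),
    turkey_smoked = list(noise_sd = 4, blob_amp = 8, blob_scale = 8,
                         streak_density = 0, streak_len = 0, streak_amp = 0),
    pork_boiled   = list(noise_sd = 4, blob_amp = 4, blob_scale = 6,
                         streak_density = 0, streak_len = 0, streak_amp = 0),
    pork_smoked   = list(noise_sd = 1, blob_amp = 24, blob_scale = 18,
                         streak_density = 0.3, streak_len = 40,
                         streak_amp = 15),
    pork_roasted  = list(noise_sd = 16, blob_amp = 6, blob_scale = 2,
                         streak_density = 0, streak_len = 0, streak_amp = 0)
  )
}

.ham_specs <- function() {
  cp <- .color_params()
  bp <- .band_params()
  drift <- .band_drift()
  tx <- .texture_params()
  out <- lapply(ham_class_names(), function(cl) {
    i <- match(cl, cp$class)
    d <- stats::setNames(numeric(length(bp$bands)), bp$bands)
    d[names(drift)] <- drift
    list(
      class = cl,
      meat = if (startsWith(cl, "turkey")) "turkey" else "pork",
      color_mean = c(L = cp$L_mean[i], a = cp$a_mean[i], b = cp$b_mean[i]),
      color_sd = c(L = cp$L_sd[i], a = cp$a_sd[i], b = cp$b_sd[i]),
      bands = data.frame(
        band = bp$bands,
        mean = bp$mean[, cl],
        sd = bp$sd[, cl],
        drift = unname(d),
        row.names = NULL,
        stringsAsFactors = FALSE
      ),
      marker_717 = if (startsWith(cl, "turkey")) {
        c(mean = 0.010, sd = 0.001)
      } else {
        NULL
      },
      texture = tx[[cl]]
    )
  })
  stats::setNames(out, ham_class_names())
}
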