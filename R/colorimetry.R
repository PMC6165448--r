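#' White calibration standard used as the default colour-difference anchor
#'
#' @return named numeric vector `L`, `a`, `b`.
#' @export
white_reference <- function() {
  c(L = 97.83, a = -0.45, b = 1.88)
}

#' CIELAB chroma
#'
#' `C* = sqrt(a*^2 + b*^2)`, the radial colourfulness coordinate.
#'
#' @param a,b CIELAB a* and b* (vectorized).
#' @return numeric vector of chroma values (>= 0).
#' @export
lab_chroma <- function(a, b) {
  sqrt(a^2 + b^2)
}

#' CIELAB hue angle in degrees
#'
#' `h = atan2(b*, a*)` wrapped to `[0, 360)`. Undefined at the neutral
#' axis (`a* = b* = 0`).
#'
#' @param a,b CIELAB a* and b* (vectorized).
#' @return numeric vector of hue angles in degrees.
#' @export
lab_hue <- function(a, b) {
  if (any(a == 0 & b == 0)) {
    stop("hue angle undefined at a* = b* = 0", call. = FALSE)
  }
  (atan2(b, a) * 180 / pi) %% 360
}

#' CIE76 colour difference to a reference colour
#'
#' Euclidean distance in CIELAB space,
#' `sqrt((dL*)^2 + (da*)^2 + (db*)^2)`, against a configurable
#' reference (the white calibration standard by default).
#'
#' @param L,a,b CIELAB coordinates (vectorized).
#' @param ref reference colour, named vector with `L`, `a`, `b`.
#' @return numeric vector of colour differences (>= 0).
#' @export
delta_e <- function(L, a, b, ref = white_reference()) {
  sqrt((L - ref[["L"]])^2 + (a - ref[["a"]])^2 + (b - ref[["b"]])^2)
}

#' Assemble the six colour features
#'
#' Appends chroma, hue angle and CIE76 colour difference to raw CIELAB
#' readings, in the fixed order `L, a, b, C, h, dE`.
#'
#' @param L,a,b CIELAB coordinates (vectorized).
#' @param ref reference colour for the colour difference.
#' @return data.frame with columns [color_feature_names()].
#' @export
color_features <- function(L, a, b, ref = white_reference()) {
  data.frame(
    L = L, a = a, b = b,
    C = lab_chroma(a, b),
    h = lab_hue(a, b),
    dE = delta_e(L, a, b, ref)
  )
}

#' Augment a colorimeter replicate table with derived colour features
#'
#' @param df data.frame with columns `L`, `a`, `b` (other columns such as
#'   `sample_id`, `class`, `day` are carried through).
#' @param ref reference colour for the colour difference.
#' @return `df` with columns `C`, `h`, `dE` appended.
#' @export
augment_color_table <- function(df, ref = white_reference()) {
  stopifnot(all(c("L", "a", "b") %in% names(df)))
  df$C <- lab_chroma(df$a, df$b)
  df$h <- lab_hue(df$a, df$b)
  df$dE <- delta_e(df$L, df$a, df$b, ref)
  df
}
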