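#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` (Mersenne-Twister,
#' inversion normals) and restores the previous RNG state afterwards, so
#' generators are reproducible without clobbering the caller's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# log2 with 0 * log(0) = 0 convention used by all entropy-type features
xlog2 <- function(p) {
  out <- numeric(length(p))
  nz <- p > 0
  out[nz] <- p[nz] * log2(p[nz])
  out
}

#' Names of the 28 features in their fixed order
#'
#' Four first-order statistics, thirteen co-occurrence (Haralick)
#' features, five run-length features, and six colour parameters.
#' All feature tables in the package use exactly this order.
#'
#' @return character vector of length 28.
#' @export
ham_feature_names <- function() {
  c(texture_feature_names(), color_feature_names())
}

#' @rdname ham_feature_names
#' @export
texture_feature_names <- function() {
  c(
    "mean", "sd", "skewness", "kurtosis",
    "ASM", "contrast", "correlation", "sum_of_squares", "IDM",
    "entropy", "sum_entropy", "sum_average", "sum_variance",
    "difference_variance", "difference_entropy", "IMC1", "IMC2",
    "SRE", "LRE", "GLNU", "RLNU", "RP"
  )
}

#' @rdname ham_feature_names
#' @export
color_feature_names <- function() {
  c("L", "a", "b", "C", "h", "dE")
}
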