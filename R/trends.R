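#' Spearman rank correlation
#'
#' Midrank-tied rank correlation, the goodness-of-fit statistic used for
#' the storage-time trend fits.
#'
#' @param x,y numeric vectors, length >= 3.
#' @return correlation in `[-1, 1]`, or `NA` if either variable has zero
#'   rank variance.
#' @export
spearman_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Quadratic storage-time trend fit
#'
#' Least-squares fit of `value = c0 + c1 day + c2 day^2`. Goodness of
#' fit is the Spearman correlation between observed and fitted values
#' (optionally between value and day directly); the trend is accepted
#' when `|r|` exceeds the threshold. Constant series have an undefined
#' rank correlation and are never accepted.
#'
#' @param days,values numeric vectors; at least 4 points on at least 3
#'   distinct days.
#' @param threshold acceptance threshold on `|r|` (default 0.2).
#' @param rank_against `"fitted"` (default) correlates observed with
#'   fitted values; `"day"` correlates values with storage day.
#' @return list of class `trend_fit`: `coefficients` (`c0`, `c1`, `c2`),
#'   `spearman_r`, `accepted`, `fitted`, `threshold`.
#' @export
fit_trend <- function(days, values, threshold = 0.2,
                      rank_against = c("fitted", "day")) {
  rank_against <- match.arg(rank_against)
  stopifnot(length(days) == length(values))
  if (length(days) < 4 || length(unique(days)) < 3) {
    stop("trend fit needs >= 4 points on >= 3 distinct days", call. = FALSE)
  }
  fit <- stats::lm(values ~ days + I(days^2))
  cf <- unname(stats::coef(fit))
  fitted <- unname(stats::fitted(fit))
  r <- if (rank_against == "fitted") {
    suppressWarnings(spearman_r(values, fitted))
  } else {
    suppressWarnings(spearman_r(values, days))
  }
  structure(
    list(coefficients = c(c0 = cf[1], c1 = cf[2], c2 = cf[3]),
         spearman_r = r,
         accepted = isTRUE(!is.na(r) && abs(r) > threshold),
         fitted = fitted, threshold = threshold),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "quadratic trend: %.4g %+.4g d %+.4g d^2 | spearman r = %s | %s\n",
    x$coefficients[1], x$coefficients[2], x$coefficients[3],
    ifelse(is.na(x$spearman_r), "NA", sprintf("%.3f", x$spearman_r)),
    if (x$accepted) "accepted" else "not accepted"
  ))
  invisible(x)
}

# Compact letter display from a pairwise significance matrix, for groups
# already sorted by mean. Sweeps maximal runs of mutually non-significant
# groups (insert) and drops runs contained in another (absorb); with equal
# group sizes Tukey significance is monotone in the mean difference, so
# sharing a letter is then exactly the complement of significance.
.letter_display <- function(sig) {
  k <- nrow(sig)
  runs <- vector("list", k)
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig[i:(j + 1), i:(j + 1)])) j <- j + 1
    runs[[i]] <- i:j
  }
  keep <- !vapply(seq_len(k), function(m) {
    any(vapply(seq_len(k)[-m], function(o) {
      all(runs[[m]] %in% runs[[o]])
    }, logical(1)))
  }, logical(1))
  runs <- unique(runs[keep])
  letters_out <- character(k)
  for (m in seq_along(runs)) {
    letters_out[runs[[m]]] <- paste0(letters_out[runs[[m]]], letters[m])
  }
  letters_out
}

#' Group-mean comparison with a compact letter display
#'
#' One-way ANOVA followed by Tukey's HSD at level `alpha`; groups that
#' do not differ significantly share a letter, assembled greedily over
#' groups sorted by decreasing mean (so the highest mean carries "a").
#' When every group has zero internal variance the letters fall back to
#' exact-equality grouping.
#'
#' @param values numeric vector of observations.
#' @param groups group labels (>= 2 groups, each with >= 2 values).
#' @param alpha significance level (default 0.05).
#' @return data.frame (`group`, `n`, `mean`, `sd`, `letters`), sorted by
#'   decreasing mean, with attributes `anova_p` and `tukey` (the pairwise
#'   table).
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  }
  agg <- data.frame(
    group = names(tab),
    n = as.integer(tab),
    mean = as.numeric(tapply(values, groups, mean)),
    sd = as.numeric(tapply(values, groups, stats::sd))
  )
  agg <- agg[order(-agg$mean), ]
  rownames(agg) <- NULL
  k <- nrow(agg)

  if (all(agg$sd == 0)) {
    # degenerate: identical values within groups; equality grouping
    u <- match(agg$mean, unique(agg$mean))
    agg$letters <- letters[u]
    attr(agg, "anova_p") <- NA_real_
    attr(agg, "tukey") <- NULL
    return(agg)
  }

  # safe internal codes: Tukey rownames are "g1-g2" and would be ambiguous
  # for group labels that themselves contain a dash
  codes <- paste0("g", seq_along(levels(groups)))
  gsafe <- factor(codes[as.integer(groups)], levels = codes)
  fit <- stats::aov(values ~ gsafe)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$gsafe
  agg_codes <- codes[match(agg$group, levels(groups))]
  sig <- matrix(FALSE, k, k, dimnames = list(agg_codes, agg_codes))
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  for (r in seq_len(nrow(tk))) {
    g1 <- pairs[r, 1]; g2 <- pairs[r, 2]
    s <- tk[r, "p adj"] < alpha
    sig[g1, g2] <- s
    sig[g2, g1] <- s
  }
  rownames(tk) <- vapply(strsplit(rownames(tk), "-", fixed = TRUE),
                         function(pr) paste(levels(groups)[match(pr, codes)],
                                            collapse = " vs "),
                         character(1))
  agg$letters <- .letter_display(sig)
  attr(agg, "anova_p") <- anova_p
  attr(agg, "tukey") <- tk
  agg
}

#' Scan variables for storage-day effects
#'
#' For each variable, compares the per-day groups ([compare_groups()]
#' machinery via one-way ANOVA) and reports whether the day effect is
#' significant at `alpha` together with the direction of change between
#' the first and the last sampling day.
#'
#' @param df data.frame with a `day` column and the variables to scan.
#' @param variables variable (column) names; default all but `day`.
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns `variable`, `p`, `significant`,
#'   `direction` (`"increase"`, `"decrease"` or `"none"`),
#'   `first_day_mean`, `last_day_mean`.
#' @export
day_effect_scan <- function(df, variables = NULL, alpha = 0.05) {
  stopifnot("day" %in% names(df))
  if (is.null(variables)) variables <- setdiff(names(df), "day")
  days <- sort(unique(df$day))
  if (length(days) < 2) stop("need >= 2 sampling days", call. = FALSE)
  if (any(table(df$day) < 2)) {
    stop("need >= 2 replicates per sampling day", call. = FALSE)
  }
  rows <- lapply(variables, function(v) {
    x <- df[[v]]
    fit <- stats::aov(x ~ factor(df$day))
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    m_first <- mean(x[df$day == days[1]])
    m_last <- mean(x[df$day == days[length(days)]])
    sig <- !is.na(p) && p < alpha
    data.frame(
      variable = v, p = p, significant = sig,
      direction = if (!sig || m_last == m_first) "none"
                  else if (m_last > m_first) "increase" else "decrease",
      first_day_mean = m_first, last_day_mean = m_last,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
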