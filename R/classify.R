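#' Pooled z-normalization of a feature table
#'
#' Each feature is replaced by `(f - mu) / sigma` with `mu`, `sigma`
#' the mean and population standard deviation pooled over all patterns
#' of the classes involved (so the two-pattern set `{x, -x}` maps to
#' `{+1, -1}` exactly). Features with zero pooled variance carry no
#' information and are dropped with a warning.
#'
#' @param x numeric matrix or data.frame, patterns in rows.
#' @return list with `x` (normalized matrix), `mu`, `sigma`, and
#'   `dropped` (names of zero-variance features).
#' @export
normalize_features <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sigma <- sqrt(colMeans(sweep(x, 2, mu)^2))
  dropped <- colnames(x)[sigma == 0]
  if (length(dropped)) {
    warning("dropping zero-variance feature(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  keep <- sigma > 0
  list(
    x = sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sigma[keep], "/"),
    mu = mu[keep], sigma = sigma[keep], dropped = dropped
  )
}

#' Fit a Gaussian-kernel probabilistic neural network
#'
#' A PNN simply stores the training patterns per class; classification
#' evaluates a Gaussian kernel of width `sigma` at every stored pattern
#' and assigns the class with the highest average kernel value (equal
#' class priors).
#'
#' @param x numeric matrix of training patterns (rows), already on a
#'   common scale (see [normalize_features()]).
#' @param y class labels; registration order (used for tie-breaking) is
#'   the factor level order, or order of first appearance.
#' @param sigma kernel width (> 0).
#' @return object of class `pnn`.
#' @export
pnn_fit <- function(x, y, sigma) {
  x <- as.matrix(x)
  stopifnot(sigma > 0, nrow(x) == length(y))
  y <- if (is.factor(y)) droplevels(y) else factor(y, levels = unique(y))
  if (any(table(y) < 1)) stop("every class needs >= 1 pattern", call. = FALSE)
  structure(list(x = x, y = y, sigma = sigma, classes = levels(y)),
            class = "pnn")
}

#' Raw PNN class scores for a query pattern
#'
#' `score_c = (1/n_c) * sum_i exp(-||q - x_ci||^2 / (2 sigma^2))`.
#' Scores underflow for very small `sigma`; [pnn_classify()] uses a
#' numerically stable log-domain version, so prefer it for decisions.
#'
#' @param model a [pnn_fit()] model.
#' @param query numeric vector with the model's feature count.
#' @return named numeric vector of per-class scores.
#' @export
pnn_score <- function(model, query) {
  stopifnot(inherits(model, "pnn"), length(query) == ncol(model$x))
  if (anyNA(query)) stop("query has missing features; pattern rejected",
                         call. = FALSE)
  d2 <- rowSums(sweep(model$x, 2, as.numeric(query))^2)
  k <- exp(-d2 / (2 * model$sigma^2))
  tapply(k, model$y, mean)[model$classes]
}

#' Classify a query pattern with a PNN
#'
#' Argmax of the class scores, computed in the log domain (log-sum-exp
#' with a global shift) so that the small-`sigma` limit degrades
#' gracefully to 1-nearest-neighbour assignment. Ties are broken by the
#' lowest class index in registration order.
#'
#' @param model a [pnn_fit()] model.
#' @param query numeric vector.
#' @return class label (character).
#' @export
pnn_classify <- function(model, query) {
  stopifnot(inherits(model, "pnn"))
  if (anyNA(query)) stop("query has missing features; pattern rejected",
                         call. = FALSE)
  d2 <- rowSums(sweep(model$x, 2, as.numeric(query))^2)
  e <- -d2 / (2 * model$sigma^2)
  shift <- max(e)
  k <- exp(e - shift)
  s <- tapply(k, model$y, function(v) log(mean(v)))[model$classes]
  model$classes[which.max(s)] # which.max takes the first (lowest index) tie
}

# Precomputed quantities shared by every LOO evaluation on a dataset:
# per-feature squared-difference matrices and per-fold feature variances.
# Under z-normalization the fold means cancel in pattern differences, so
# fold-wise renormalization only rescales each feature by the fold's
# standard deviation; LOO distances can therefore be assembled from the
# raw squared differences and leave-one-out variances without rebuilding
# the design matrix in every fold.
.loo_engine <- function(x, y, norm = c("fold", "pooled")) {
  norm <- match.arg(norm)
  x <- as.matrix(x)
  n <- nrow(x)
  y <- if (is.factor(y)) droplevels(y) else factor(y, levels = unique(y))
  stopifnot(n == length(y), n >= 3)
  if (any(table(y) < 2)) {
    stop("leave-one-out needs >= 2 patterns per class", call. = FALSE)
  }
  p <- ncol(x)
  dk <- vector("list", p)
  for (k in seq_len(p)) dk[[k]] <- outer(x[, k], x[, k], `-`)^2

  if (norm == "pooled") {
    v <- colMeans(sweep(x, 2, colMeans(x))^2) # population variance
    s2 <- matrix(rep(pmax(v, .Machine$double.eps), each = n), n, p)
  } else {
    # leave-one-out population variance of each feature, closed form
    m <- colMeans(x)
    ss <- colSums(sweep(x, 2, m)^2)
    s2 <- matrix(0, n, p)
    for (k in seq_len(p)) {
      ssk <- ss[k] - (x[, k] - m[k])^2 * n / (n - 1)
      s2[, k] <- pmax(ssk / (n - 1), .Machine$double.eps)
    }
  }
  ymat <- stats::model.matrix(~ y - 1)
  colnames(ymat) <- levels(y)
  list(x = x, y = y, n = n, dk = dk, s2 = s2, ymat = ymat,
       counts = as.numeric(table(y)), classes = levels(y), norm = norm)
}

# One LOO pass for a feature subset at a fixed kernel width. Row i of
# the kernel matrix is shifted by its own maximum before exponentiation:
# the shift is common to all classes, so the argmax (and the confusion
# matrix) is exact even for widths far into underflow territory.
.loo_eval <- function(eng, subset, sigma) {
  n <- eng$n
  d <- matrix(0, n, n)
  for (k in subset) d <- d + eng$dk[[k]] * (1 / eng$s2[, k])
  e <- -d / (2 * sigma^2)
  diag(e) <- -Inf
  e <- e - apply(e, 1, max)
  kmat <- exp(e)
  scores <- kmat %*% eng$ymat
  denom <- matrix(rep(eng$counts, each = n), n) - eng$ymat # exclude self
  scores <- scores / denom
  pred <- max.col(scores, ties.method = "first")
  conf <- table(
    true = eng$y,
    assigned = factor(eng$classes[pred], levels = eng$classes)
  )
  structure(
    list(confusion = unclass(conf),
         accuracy = sum(diag(conf)) / n,
         per_class_recall = diag(conf) / rowSums(conf),
         sigma = sigma, norm = eng$norm, subset = subset),
    class = "truth_table"
  )
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("Leave-one-out truth table (accuracy %.1f%%, sigma %.4g)\n",
              100 * x$accuracy, x$sigma))
  print(x$confusion)
  invisible(x)
}

.sigma_grid <- function(p) c(0.05, 0.1, 0.2, 0.5, 1, 2) * sqrt(p)

# Grid search for the kernel width: LOO accuracy at each candidate,
# smallest width on ties (deterministic).
.pick_sigma <- function(eng, subset) {
  grid <- .sigma_grid(length(subset))
  acc <- vapply(grid, function(s) .loo_eval(eng, subset, s)$accuracy,
                numeric(1))
  grid[which.max(acc)]
}

#' Exact leave-one-out evaluation of a PNN on a feature subset
#'
#' For every pattern the classifier is designed from the remaining
#' `n - 1` patterns and the held-out pattern is assigned; counts are
#' accumulated into a confusion (truth) table. With
#' `norm = "fold"` (default) the z-normalization parameters are those of
#' the `n - 1` retained patterns, so no information about the held-out
#' pattern leaks into the design; `norm = "pooled"` normalizes once over
#' all patterns, the literal textbook procedure.
#'
#' @param x numeric matrix or data.frame of raw (unnormalized) features.
#' @param y class labels (>= 2 patterns per class).
#' @param subset feature columns to use (indices or names); default all.
#' @param sigma kernel width, or `"auto"` to pick from the grid
#'   `c(0.05, 0.1, 0.2, 0.5, 1, 2) * sqrt(p)` by LOO accuracy.
#' @param norm `"fold"` or `"pooled"` normalization mode.
#' @return a `truth_table`: confusion matrix, overall accuracy,
#'   per-class recall, the width used, and the subset evaluated.
#' @export
loo_evaluate <- function(x, y, subset = NULL, sigma = "auto",
                         norm = c("fold", "pooled")) {
  x <- as.matrix(x)
  if (is.null(subset)) subset <- seq_len(ncol(x))
  if (is.character(subset)) subset <- match(subset, colnames(x))
  if (anyNA(subset)) stop("unknown feature in `subset`", call. = FALSE)
  ok <- stats::complete.cases(x[, subset, drop = FALSE])
  if (!all(ok)) {
    warning(sum(!ok), " pattern(s) with missing features rejected",
            call. = FALSE)
    x <- x[ok, , drop = FALSE]
    y <- y[ok]
  }
  eng <- .loo_engine(x[, subset, drop = FALSE], y, match.arg(norm))
  sub <- seq_along(subset)
  s <- if (identical(sigma, "auto")) .pick_sigma(eng, sub) else sigma
  out <- .loo_eval(eng, sub, s)
  out$subset <- if (!is.null(colnames(x))) colnames(x)[subset] else subset
  out
}

#' Exhaustive feature-subset search under leave-one-out evaluation
#'
#' Evaluates every feature combination of size 1 up to `max_size` and
#' returns the one with the highest LOO accuracy; ties prefer fewer
#' features, then the lexicographically earliest subset in column
#' order. Sizes above 6 explode combinatorially and require
#' `force = TRUE`.
#'
#' @param x numeric matrix or data.frame of raw features.
#' @param y class labels.
#' @param max_size largest subset size to scan (default 3).
#' @param sigma kernel width or `"auto"` (per-subset grid search).
#' @param norm normalization mode, see [loo_evaluate()].
#' @param force allow `max_size > 6`.
#' @param top how many ranked subsets to keep in the report.
#' @return list with `best_subset` (feature names), `truth_table`,
#'   `sigma`, `accuracy`, `ranked` (top subsets as a data.frame) and
#'   `n_evaluated`.
#' @export
subset_search <- function(x, y, max_size = 3, sigma = "auto",
                          norm = c("fold", "pooled"),
                          force = FALSE, top = 20) {
  x <- as.matrix(x)
  p <- ncol(x)
  stopifnot(max_size >= 1, max_size <= p)
  if (max_size > 6 && !force) {
    stop("max_size > 6 scans >10^5 subsets; set force = TRUE if intended",
         call. = FALSE)
  }
  nms <- colnames(x)
  if (is.null(nms)) nms <- paste0("f", seq_len(p))
  ok <- stats::complete.cases(x)
  if (!all(ok)) {
    warning(sum(!ok), " pattern(s) with missing features rejected",
            call. = FALSE)
    x <- x[ok, , drop = FALSE]
    y <- y[ok]
  }
  norm <- match.arg(norm)
  eng <- .loo_engine(x, y, norm)

  best <- NULL
  records <- vector("list", sum(choose(p, seq_len(max_size))))
  i <- 0L
  for (size in seq_len(max_size)) {
    combos <- utils::combn(p, size)
    for (j in seq_len(ncol(combos))) {
      sub <- combos[, j]
      s <- if (identical(sigma, "auto")) .pick_sigma(eng, sub) else sigma
      tt <- .loo_eval(eng, sub, s)
      i <- i + 1L
      records[[i]] <- data.frame(
        subset = paste(nms[sub], collapse = "+"),
        size = size, sigma = s, accuracy = tt$accuracy
      )
      # strict improvement only: earlier (smaller, lexicographically
      # first) subsets win ties
      if (is.null(best) || tt$accuracy > best$accuracy) {
        best <- tt
        best$subset <- nms[sub]
      }
    }
  }
  ranked <- do.call(rbind, records[seq_len(i)])
  ord <- order(-ranked$accuracy, ranked$size, seq_len(nrow(ranked)))
  ranked <- ranked[ord[seq_len(min(top, nrow(ranked)))], ]
  rownames(ranked) <- NULL
  list(
    best_subset = best$subset,
    truth_table = best,
    sigma = best$sigma,
    accuracy = best$accuracy,
    ranked = ranked,
    n_evaluated = i
  )
}
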