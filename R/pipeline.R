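#' Extract the 28-column feature table from a study bundle on disk
#'
#' Reads the bundle written by [gen_study()] (or any directory with the
#' same layout): computes the 22 texture features from each PNG and
#' merges the 6 colour features derived from `colors.csv`.
#'
#' @param dir bundle directory containing `manifest.json`.
#' @param cfg texture configuration.
#' @param ref colour-difference reference.
#' @return data.frame `sample_id`, `class`, `day`, plus the 28 features.
#' @export
extract_study <- function(dir, cfg = texture_config(),
                          ref = white_reference()) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  colors <- utils::read.csv(file.path(dir, "colors.csv"),
                            stringsAsFactors = FALSE)
  colors <- cbind(colors[, c("sample_id", "class", "day")],
                  color_features(colors$L, colors$a, colors$b, ref))
  imgs <- list.files(file.path(dir, "images"), pattern = "\\.png$",
                     recursive = TRUE, full.names = TRUE)
  if (length(imgs) == 0) stop("no images found under ", dir, call. = FALSE)
  tex <- t(vapply(imgs, function(p) {
    texture_features(read_image_gray(p), cfg)
  }, numeric(22)))
  tex <- data.frame(sample_id = sub("\\.png$", "", basename(imgs)),
                    as.data.frame(tex), row.names = NULL)
  out <- merge(colors, tex, by = "sample_id")
  out[, c("sample_id", "class", "day", ham_feature_names())]
}

#' Band-intensity table of a study bundle's spectra
#'
#' @param dir bundle directory written by [gen_study()].
#' @param bands band registry.
#' @param baseline passed to [band_intensity()].
#' @return data.frame `sample_id`, `class`, `day`, plus one column per band.
#' @export
extract_study_bands <- function(dir, bands = ftir_bands(),
                                baseline = FALSE) {
  files <- list.files(file.path(dir, "spectra"), pattern = "\\.csv$",
                      full.names = TRUE)
  if (length(files) == 0) stop("no spectra found under ", dir, call. = FALSE)
  spectra <- lapply(files, read_spectrum_csv)
  names(spectra) <- sub("\\.csv$", "", basename(files))
  bt <- band_table(spectra, bands, baseline = baseline)
  meta <- regmatches(bt$sample_id,
                     regexec("^(.*)_d([0-9]+)_([0-9]+)$", bt$sample_id))
  bt$class <- vapply(meta, `[`, character(1), 2)
  bt$day <- as.integer(vapply(meta, `[`, character(1), 3))
  bt[, c("sample_id", "class", "day",
         setdiff(names(bt), c("sample_id", "class", "day")))]
}

#' Discriminate ham classes by exhaustive feature-subset search
#'
#' Restricts the feature table to the named classes, runs
#' [subset_search()] over the 28 features, and assembles a
#' self-describing report.
#'
#' @param features feature table from [gen_feature_table()] or
#'   [extract_study()].
#' @param classes two or three class names to discriminate.
#' @param max_size largest subset size (default 3).
#' @param sigma kernel width or `"auto"`.
#' @param norm normalization mode, see [loo_evaluate()].
#' @param top ranked subsets to keep.
#' @return list of class `discrimination_report`: `comparison`, `config`,
#'   `best_subset`, `sigma`, `accuracy`, `per_class_recall`, `confusion`,
#'   `ranked`.
#' @export
discriminate <- function(features, classes, max_size = 3, sigma = "auto",
                         norm = "fold", top = 20) {
  stopifnot(length(classes) >= 2, all(classes %in% features$class))
  sel <- features$class %in% classes
  x <- as.matrix(features[sel, ham_feature_names()])
  y <- factor(features$class[sel], levels = classes)
  res <- subset_search(x, y, max_size = max_size, sigma = sigma,
                       norm = norm, top = top)
  structure(
    list(
      comparison = classes,
      config = list(max_size = max_size, sigma_policy = sigma, norm = norm,
                    features = ham_feature_names(), n = sum(sel)),
      best_subset = res$best_subset,
      sigma = res$sigma,
      accuracy = res$accuracy,
      per_class_recall = res$truth_table$per_class_recall,
      confusion = res$truth_table$confusion,
      ranked = res$ranked,
      n_evaluated = res$n_evaluated
    ),
    class = "discrimination_report"
  )
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf(
    "%s: best subset {%s}, LOO accuracy %.1f%% (sigma %.3g, %d subsets)\n",
    paste(x$comparison, collapse = " vs "),
    paste(x$best_subset, collapse = ", "),
    100 * x$accuracy, x$sigma, x$n_evaluated
  ))
  print(x$confusion)
  invisible(x)
}

#' Write a discrimination report as JSON
#'
#' @param report a `discrimination_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$confusion <- as.data.frame.matrix(out$confusion)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Shelf-life analysis: storage-time trends and day effects
#'
#' For every class and variable, fits the quadratic storage-time trend
#' ([fit_trend()]) on the per-day means and scans for significant day
#' effects ([day_effect_scan()]).
#'
#' @param df data.frame with `class`, `day` and variable columns.
#' @param variables variables to analyse; default every column after
#'   `sample_id`/`class`/`day`.
#' @param threshold Spearman acceptance threshold for trends.
#' @param alpha significance level for the day scan.
#' @return list with `trends` (class, variable, c0, c1, c2, spearman_r,
#'   accepted) and `scan` (class, variable, p, significant, direction).
#' @export
shelflife <- function(df, variables = NULL, threshold = 0.2, alpha = 0.05) {
  stopifnot(all(c("class", "day") %in% names(df)))
  if (is.null(variables)) {
    variables <- setdiff(names(df), c("sample_id", "class", "day"))
  }
  trends <- list()
  scans <- list()
  for (cl in unique(df$class)) {
    sub <- df[df$class == cl, ]
    for (v in variables) {
      ft <- fit_trend(sub$day, sub[[v]], threshold = threshold)
      trends[[length(trends) + 1L]] <- data.frame(
        class = cl, variable = v,
        c0 = ft$coefficients[["c0"]], c1 = ft$coefficients[["c1"]],
        c2 = ft$coefficients[["c2"]], spearman_r = ft$spearman_r,
        accepted = ft$accepted, stringsAsFactors = FALSE
      )
    }
    sc <- day_effect_scan(sub[, c("day", variables)], variables, alpha)
    sc <- cbind(class = cl, sc)
    scans[[length(scans) + 1L]] <- sc
  }
  list(trends = do.call(rbind, trends), scan = do.call(rbind, scans))
}
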