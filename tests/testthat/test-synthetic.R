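test_that("generators are bit-reproducible under the seeding contract", {
  expect_identical(gen_color("pork_smoked", 5, seed = 3),
                   gen_color("pork_smoked", 5, seed = 3))
  expect_false(identical(gen_color("pork_smoked", 5, seed = 3)$L,
                         gen_color("pork_smoked", 5, seed = 4)$L))

  s1 <- gen_spectrum("turkey_boiled", day = 12, seed = 9)
  s2 <- gen_spectrum("turkey_boiled", day = 12, seed = 9)
  expect_identical(s1$absorbance, s2$absorbance)

  i1 <- gen_image("pork_roasted", 64, seed = 5)
  expect_identical(i1, gen_image("pork_roasted", 64, seed = 5))
  expect_false(identical(i1, gen_image("pork_roasted", 64, seed = 6)))

  expect_error(ham_classes("goose_roasted"), "unknown")
})

test_that("zero-spread colour generation returns the class means exactly", {
  spec <- ham_classes("turkey_smoked")
  spec$color_sd[] <- 0
  cc <- gen_color(spec, n = 4, seed = 1)
  expect_true(all(cc$L == spec$color_mean[["L"]]))
  expect_true(all(cc$a == spec$color_mean[["a"]]))
  expect_true(all(cc$b == spec$color_mean[["b"]]))
})

test_that("noise-free day-0 spectra return the class band means", {
  for (cl in ham_class_names()) {
    s <- gen_spectrum(cl, day = 0, seed = 1, band_noise = FALSE,
                      white_noise_sd = 0)
    got <- unlist(band_table(s)[1, -1])
    expect_equal(unname(got), ham_classes(cl)$bands$mean, tolerance = 1e-3)
  }
})

test_that("storage drift scales band amplitudes as specified", {
  s0 <- gen_spectrum("pork_boiled", day = 0, seed = 1, band_noise = FALSE,
                     white_noise_sd = 0)
  s20 <- gen_spectrum("pork_boiled", day = 20, seed = 1, band_noise = FALSE,
                      white_noise_sd = 0)
  b0 <- band_table(s0)
  b20 <- band_table(s20)
  expect_equal(b20[["1744"]] / b0[["1744"]], 0.9, tolerance = 1e-3)
  expect_equal(b20[["966"]] / b0[["966"]], 1.1, tolerance = 1e-3)
  # un-drifted band unchanged
  expect_equal(b20[["870"]] / b0[["870"]], 1, tolerance = 1e-3)
  # day 10 is the drift onset: no change before it
  s10 <- gen_spectrum("pork_boiled", day = 9, seed = 1, band_noise = FALSE,
                      white_noise_sd = 0)
  expect_equal(band_table(s10)[["1744"]], b0[["1744"]], tolerance = 1e-6)
})

test_that("colour moments converge to the class parameters", {
  spec <- ham_classes("turkey_boiled")
  cc <- gen_color("turkey_boiled", n = 1e4, seed = 2)
  se_a <- spec$color_sd[["a"]] / sqrt(1e4)
  expect_lt(abs(mean(cc$a) - spec$color_mean[["a"]]), 3 * se_a)
})

test_that("planted texture orderings hold across paired seeds", {
  n_seeds <- 30
  feats <- c("ASM", "LRE", "sd", "GLNU")
  vals <- array(NA_real_, c(n_seeds, 5, length(feats)),
                dimnames = list(NULL, ham_class_names(), feats))
  for (s in seq_len(n_seeds)) {
    for (cl in ham_class_names()) {
      vals[s, cl, ] <- texture_features(
        gen_image(cl, 128, seed = 900 + s)
      )[feats]
    }
  }
  # pairwise, per-seed comparisons of the documented orderings
  expect_gte(sum(vals[, "pork_boiled", "ASM"] > vals[, "pork_smoked", "ASM"]),
             0.9 * n_seeds)
  expect_gte(sum(vals[, "pork_boiled", "ASM"] > vals[, "pork_roasted", "ASM"]),
             0.9 * n_seeds)
  expect_gte(sum(vals[, "pork_smoked", "LRE"] > vals[, "pork_boiled", "LRE"]),
             0.9 * n_seeds)
  expect_gte(sum(vals[, "pork_smoked", "LRE"] > vals[, "pork_roasted", "LRE"]),
             0.9 * n_seeds)
  expect_gte(sum(vals[, "turkey_boiled", "sd"] > vals[, "turkey_smoked", "sd"]),
             0.9 * n_seeds)
  expect_gte(sum(vals[, "turkey_smoked", "GLNU"] >
                 vals[, "turkey_boiled", "GLNU"]),
             0.9 * n_seeds)
})

test_that("a minimal study bundle writes, reads back and round-trips", {
  dir <- file.path(tempdir(), "mini_bundle")
  on.exit(unlink(dir, recursive = TRUE))
  d <- study_design(classes = c("turkey_boiled", "pork_smoked"), n = 2,
                    days = c(0, 12), seed = 77, image_size = 64)
  gen_study(d, dir)

  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_equal(length(list.files(file.path(dir, "images"),
                                 recursive = TRUE)), 8)
  expect_equal(length(list.files(file.path(dir, "spectra"))), 8)

  feats <- extract_study(dir)
  expect_equal(nrow(feats), 8)
  expect_equal(names(feats),
               c("sample_id", "class", "day", ham_feature_names()))
  expect_false(anyNA(feats[, ham_feature_names()]))

  bands <- extract_study_bands(dir)
  expect_equal(nrow(bands), 8)
  expect_true(all(ftir_bands()$band %in% names(bands)))

  # identical design and seed reproduce the bundle byte for byte
  dir2 <- file.path(tempdir(), "mini_bundle2")
  on.exit(unlink(dir2, recursive = TRUE), add = TRUE)
  gen_study(d, dir2)
  f1 <- file.path(dir, "colors.csv")
  f2 <- file.path(dir2, "colors.csv")
  expect_identical(readLines(f1), readLines(f2))
  p1 <- list.files(file.path(dir, "images"), recursive = TRUE,
                   full.names = TRUE)[1]
  p2 <- list.files(file.path(dir2, "images"), recursive = TRUE,
                   full.names = TRUE)[1]
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  expect_error(study_design(classes = "goose"), "classes")
})

test_that("feature tables carry 28 ordered features per replicate", {
  ft <- gen_feature_table(classes = c("turkey_boiled", "turkey_smoked"),
                          n = 3, seed = 5, image_size = 64)
  expect_equal(nrow(ft), 6)
  expect_equal(names(ft), c("sample_id", "class", ham_feature_names()))
  expect_identical(ft, gen_feature_table(
    classes = c("turkey_boiled", "turkey_smoked"), n = 3, seed = 5,
    image_size = 64
  ))
})
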