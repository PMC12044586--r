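# ppm-window matching of feature lists against the candidate index.

test_that("window bounds are symmetric multiplicative ppm intervals", {
  expect_equal(window_bounds(100, 2), c(99.9998, 100.0002))
  w <- window_bounds(927.3694, 2)
  expect_equal(w, 927.3694 * c(1 - 2e-6, 1 + 2e-6))
  expect_equal(window_bounds(500, 0), c(500, 500))
  expect_error(window_bounds(500, -1), "non-negative")
})

test_that("bisection equals a brute-force linear scan", {
  expect_identical(bisect_range(c(100, 200, 300), 199.9996, 200.0004),
                   c(2L, 3L))
  expect_identical(bisect_range(c(100, 200, 300), 400, 401), c(4L, 4L))
  expect_identical(bisect_range(numeric(), 1, 2), c(1L, 1L))

  set.seed(11)
  for (i in 1:50) {
    x <- sort(stats::runif(1000, 50, 1500))
    centre <- stats::runif(1, 40, 1600)
    width <- stats::runif(1, 0, 50)
    lo <- centre - width; hi <- centre + width
    r <- bisect_range(x, lo, hi)
    idx <- which(x >= lo & x <= hi)
    if (length(idx)) {
      expect_identical(r, c(idx[1], idx[length(idx)] + 1L))
    } else {
      expect_identical(r[1], r[2])
    }
  }
})

test_that("isomer discrimination follows derivatization-target structure", {
  db <- fig3_db()
  res <- annotate_features(c(927.3694, 421.1911, 268.5), db,
                           matrix = "FMP-10", tol = 2)
  m <- res$matches
  # the triple-tag peak belongs to dopamine alone
  m1 <- m[m$feature == 1, ]
  expect_identical(m1$metabolite_id, "iso1")
  expect_identical(m1$form, "3AA")
  # the single-tag peak annotates all three derivatizable isomers
  m2 <- m[m$feature == 2, ]
  expect_identical(sort(m2$name),
                   sort(c("dopamine", "p-octopamine", "norfenefrine")))
  expect_true(all(m2$form == "1A"))
  # enbucrilate never appears; the off-candidate feature has no match
  expect_false("iso4" %in% m$metabolite_id)
  expect_false(3 %in% m$feature)
  expect_identical(res$n_annotated, 2L)
})

test_that("matches respect tolerance monotonicity and input order", {
  db <- fig3_db()
  feats <- c(421.19095, 927.36955, 674.28025)
  tols <- c(0, 0.2, 0.5, 1, 2)
  n_prev <- -1L
  for (tol in tols) {
    res <- annotate_features(feats, db, matrix = "FMP-10", tol = tol)
    expect_gte(nrow(res$matches), n_prev)
    n_prev <- nrow(res$matches)
    expect_true(all(abs(res$matches$delta_ppm) <= tol + 1e-12))
    # reported feature order is the input order
    expect_false(is.unsorted(res$matches$feature))
  }
  # tol = 0 keeps only exact equalities
  res0 <- annotate_features(c(421.1911, db$candidates$mz[1]), db,
                            matrix = "FMP-10", tol = 0)
  expect_true(all(res0$matches$delta_ppm == 0))
})

test_that("matrix-peak exclusion suppresses reagent features", {
  db <- fig3_db()
  reagent <- tag_shift(fmp10())
  # make a candidate-coincident feature and exclude it
  res <- annotate_features(c(421.1911, reagent), db, matrix = "FMP-10",
                           tol = 2, exclude = reagent)
  expect_identical(unique(res$matches$feature), 1L)
})

test_that("feature lists parse from txt and sniffed csv variants", {
  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("421.1911", "927.3694"), txt)
  f1 <- read_feature_list(txt)
  expect_equal(f1$mz, c(421.1911, 927.3694))

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("m/z,Area,Intensity", "421.1911,10,100.5",
               "927.3694,20,200.5"), csv)
  f2 <- read_feature_list(csv)
  expect_equal(f2$mz, c(421.1911, 927.3694))
  expect_equal(f2$Intensity, c(100.5, 200.5))  # extras carried through

  semi <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("row;mz;area", "a;421.1911;1", "b;927.3694;2"), semi)
  expect_equal(read_feature_list(semi)$mz, c(421.1911, 927.3694))

  # no m/z-named header: first numeric column wins
  anon <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,value", "x,421.1911"), anon)
  expect_equal(read_feature_list(anon)$mz, 421.1911)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("421.19", "-1"), bad)
  expect_error(read_feature_list(bad), "non-positive")
})

test_that("annotation tables export in both modes and re-import", {
  db <- fig3_db()
  res <- annotate_features(c(927.3694, 421.1911, 268.5), db,
                           matrix = "FMP-10", tol = 2)
  only <- withr::local_tempfile(fileext = ".csv")
  export_annotations(res, only, mode = "annotated-only")
  t1 <- utils::read.csv(only)
  expect_identical(nrow(t1), 4L)  # 1 + 3 matches, unannotated dropped

  full <- withr::local_tempfile(fileext = ".csv")
  export_annotations(res, full, mode = "full-table")
  t2 <- utils::read.csv(full)
  expect_identical(nrow(t2), 5L)  # plus the unannotated feature
  expect_true(any(is.na(t2$theoretical_mz)))
  # a multi-match feature explodes into one row per match, same query m/z
  expect_identical(sum(t2$query_mz == 421.1911), 3L)

  none <- annotate_features(268.5, db, matrix = "FMP-10", tol = 2)
  expect_error(export_annotations(none, only, mode = "annotated-only"),
               "full-table")
  expect_warning(annotate_features(numeric(), db, matrix = "FMP-10"),
                 "empty")
})
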