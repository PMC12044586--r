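# MS2 spectra: mzML round-trips, binning, cosine scoring, library search,
# mirror export, and diagnostic product ions.

test_that("mzML files round-trip through write and read", {
  s1 <- ms2_spectrum(c(100.1, 200.2, 300.3), c(10, 20, 30),
                     precursor_mz = 421.19, collision_energy = 30,
                     isolation_window = 1)
  s2 <- ms2_spectrum(c(150.5, 286.122641), c(5, 50),
                     precursor_mz = 674.28, collision_energy = 40,
                     isolation_window = 2)
  tmp <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(list(s1, s2), tmp)
  back <- read_mzml(tmp)
  expect_length(back, 2L)
  for (i in 1:2) {
    orig <- list(s1, s2)[[i]]
    expect_equal(back[[i]]$mz, orig$mz)
    expect_equal(back[[i]]$intensity, orig$intensity)
    expect_equal(back[[i]]$precursor_mz, orig$precursor_mz,
                 tolerance = 1e-6)
    expect_equal(back[[i]]$collision_energy, orig$collision_energy)
    expect_equal(back[[i]]$isolation_window, orig$isolation_window,
                 tolerance = 1e-4)
  }
})

test_that("non-MS2 and profile-mode files are handled explicitly", {
  s <- ms2_spectrum(c(100, 200), c(1, 2), precursor_mz = 300)
  tmp <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(s, tmp)
  doc <- readLines(tmp)

  ms1 <- withr::local_tempfile(fileext = ".mzML")
  writeLines(gsub('name="ms level" value="2"', 'name="ms level" value="1"',
                  doc, fixed = TRUE), ms1)
  expect_warning(out <- read_mzml(ms1), "no MS2")
  expect_length(out, 0L)

  prof <- withr::local_tempfile(fileext = ".mzML")
  writeLines(gsub('accession="MS:1000127" name="centroid spectrum"',
                  'accession="MS:1000128" name="profile spectrum"',
                  doc, fixed = TRUE), prof)
  expect_error(read_mzml(prof), "centroid")
  expect_error(read_mzml("does/not/exist.mzML"), "no such file")
})

test_that("spectrum construction sorts peaks and validates them", {
  s <- ms2_spectrum(c(300, 100, 200), c(3, 1, 2))
  expect_equal(s$mz, c(100, 200, 300))
  expect_equal(s$intensity, c(1, 2, 3))
  expect_error(ms2_spectrum(numeric(), numeric()), "length")
  expect_error(ms2_spectrum(c(100, 200), c(-1, 2)), "non-negative")
})

test_that("binning sums shared bins, cuts at max m/z, conserves intensity", {
  s <- ms2_spectrum(c(100.004, 100.006), c(5, 3))
  coarse <- bin_spectrum(s, 0.01)
  expect_identical(length(coarse$index), 1L)
  expect_equal(coarse$intensity, 8)
  fine <- bin_spectrum(s, 0.001)
  expect_identical(length(fine$index), 2L)
  expect_equal(sort(fine$intensity), c(3, 5))

  cut <- bin_spectrum(ms2_spectrum(c(100, 430), c(1, 9)), 0.01,
                      max_mz = 422)
  expect_equal(sum(cut$intensity), 1)
  expect_error(bin_spectrum(s, 0), "positive")

  # conservation without a cutoff, on a seeded random spectrum
  set.seed(5)
  r <- ms2_spectrum(stats::runif(200, 50, 450), stats::rexp(200))
  for (bs in c(1, 0.01, 0.001))
    expect_equal(sum(bin_spectrum(r, bs)$intensity), sum(r$intensity))
})

test_that("cosine similarity has the geometry of a normalized dot product", {
  s1 <- ms2_spectrum(c(100, 200), c(1, 1))
  s2 <- ms2_spectrum(c(100, 300), c(1, 1))
  s3 <- ms2_spectrum(c(150, 250), c(2, 7))
  expect_equal(cosine_similarity(s1, s1), 1.0)
  expect_equal(cosine_similarity(s1, s3), 0.0)   # disjoint bins
  expect_equal(cosine_similarity(s1, s2), 0.5)   # dot 1 over sqrt2*sqrt2
  # symmetry and scale invariance
  scaled <- ms2_spectrum(s2$mz, s2$intensity * 137)
  expect_equal(cosine_similarity(s1, scaled), cosine_similarity(s2, s1))
  # seeded random pairs stay inside [0, 1]
  set.seed(9)
  for (i in 1:20) {
    a <- ms2_spectrum(stats::runif(30, 50, 450), stats::rexp(30))
    b <- ms2_spectrum(stats::runif(30, 50, 450), stats::rexp(30))
    sc <- cosine_similarity(a, b)
    expect_gte(sc, 0); expect_lte(sc, 1)
  }
  zero <- ms2_spectrum(c(100, 200), c(0, 0))
  expect_error(cosine_similarity(s1, zero), "all-zero")
  expect_error(cosine_similarity(bin_spectrum(s1, 0.01),
                                 bin_spectrum(s2, 0.02)),
               "bin size")
})

test_that("library search ranks self-matches first, deterministically", {
  lib <- make_ms2_library(10, seed = 31, noise = 0.05)
  # noiseless self-query: rank 1, score 1
  hits <- search_library(lib$references[[4]], lib$references,
                         bin_size = 0.01)
  expect_identical(hits$id[1], "ref004")
  expect_equal(hits$score[1], 1.0)
  expect_identical(hits$rank, 1:10)
  # 5%-intensity-noise query still ranks its source first
  for (k in c(1, 4, 9)) {
    h <- search_library(lib$queries[[k]], lib$references, bin_size = 0.01)
    expect_identical(h$id[1], sprintf("ref%03d", k))
    expect_gt(h$score[1], 0.95)
  }
  # identical inputs give identical orderings across runs
  expect_identical(search_library(lib$queries[[2]], lib$references),
                   search_library(lib$queries[[2]], lib$references))
  expect_error(search_library(lib$queries[[1]], list()), "empty")
})

test_that("coarser bins never score mass-shifted copies lower", {
  set.seed(17)
  for (i in 1:5) {
    mz <- sort(stats::runif(25, 50, 400))
    inten <- stats::rexp(25, 1 / 50)
    ref <- ms2_spectrum(mz, inten)
    shifted <- ms2_spectrum(mz + 0.3, inten)  # mass-shifted copy
    coarse <- cosine_similarity(ref, shifted, bin_size = 1)
    fine <- cosine_similarity(ref, shifted, bin_size = 0.01)
    expect_gte(coarse, fine)
  }
})

test_that("mirror csv export re-imports both spectra exactly", {
  q <- ms2_spectrum(c(110.05, 220.1), c(40, 60))
  r <- ms2_spectrum(c(110.05, 220.1, 330.15), c(35, 65, 20))
  tmp <- withr::local_tempfile(fileext = ".csv")
  export_mirror(q, r, tmp)
  tab <- utils::read.csv(tmp)
  expect_identical(nrow(tab), 5L)
  expect_true(all(tab$intensity[tab$source == "reference"] < 0))
  back <- read_mirror(tmp)
  expect_equal(back$query$mz, q$mz)
  expect_equal(back$query$intensity, q$intensity)
  expect_equal(back$reference$intensity, r$intensity)
  expect_error(ms2_spectrum(numeric(), numeric()), "length")
})

test_that("diagnostic product ions flag functional classes", {
  ions <- diagnostic_ions(fmp10())
  expect_equal(round(ions[["phenolic_hydroxyl"]], 6), 286.122641)
  expect_equal(round(ions[["primary_amine"]], 6), 285.138625)

  both <- ms2_spectrum(c(150, 285.138625, 286.122641), c(5, 60, 80))
  flags <- flag_diagnostic_ions(both, fmp10())
  expect_true(all(flags))
  amine_only <- ms2_spectrum(c(150, 285.138625), c(5, 60))
  f2 <- flag_diagnostic_ions(amine_only, fmp10())
  expect_true(f2[["primary_amine"]])
  expect_false(f2[["phenolic_hydroxyl"]])
  neither <- ms2_spectrum(c(150, 200), c(5, 60))
  expect_false(any(flag_diagnostic_ions(neither, fmp10())))
  expect_error(diagnostic_ions(ampp()), "diagnostic")
})
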