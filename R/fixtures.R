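# Deterministic generators of synthetic test inputs: the isomer panel, a
# 36-compound standards panel, feature lists with injected mass-error
# curves plus decoys, and synthetic MS2 libraries.  Every generator is a
# pure function of its arguments (and seed), so downstream metrics are
# exactly computable from the returned truth tables.

#' Four-isomer discrimination panel
#'
#' Dopamine, p-octopamine, norfenefrine, and enbucrilate: all share the
#' formula C8H11NO2 (neutral monoisotopic mass 153.07898) but carry 3, 2,
#' 2, and 0 FMP-10 derivatization targets respectively, so structure-aware
#' annotation separates them where plain mass matching cannot.
#'
#' @return Metabolite data frame of 4 records.
#' @export
fig_isomer_panel <- function() {
  rbind(
    metabolite_record("iso1", "dopamine", "C8H11NO2",
                      "NCCc1ccc(O)c(O)c1", "endogenous", "brain"),
    metabolite_record("iso2", "p-octopamine", "C8H11NO2",
                      "NCC(O)c1ccc(O)cc1", "endogenous", "brain"),
    metabolite_record("iso3", "norfenefrine", "C8H11NO2",
                      "NCC(O)c1cccc(O)c1", "unspecified", character()),
    metabolite_record("iso4", "enbucrilate", "C8H11NO2",
                      "CCCCOC(=O)C(=C)C#N", "exogenous", character())
  )
}

.STANDARDS <- list(
  # name, formula, smiles, endogeneity, tissues
  list("dopamine", "C8H11NO2", "NCCc1ccc(O)c(O)c1", "endogenous", "brain"),
  list("serotonin", "C10H12N2O", "NCCc1c[nH]c2ccc(O)cc12", "endogenous",
       "brain;blood"),
  list("GABA", "C4H9NO2", "NCCCC(=O)O", "endogenous", "brain"),
  list("taurine", "C2H7NO3S", "NCCS(=O)(=O)O", "endogenous", "brain;liver"),
  list("histidine", "C6H9N3O2", "NC(Cc1c[nH]cn1)C(=O)O", "endogenous",
       "blood"),
  list("norepinephrine", "C8H11NO3", "NCC(O)c1ccc(O)c(O)c1", "endogenous",
       "brain"),
  list("DOPAC", "C8H8O4", "OC(=O)Cc1ccc(O)c(O)c1", "endogenous", "brain"),
  list("alpha-tocopherol", "C29H50O2",
       "CC1=C(O)C(C)=C2CCC(C)(CCCC(C)CCCC(C)CCCC(C)C)Oc2c1C", "endogenous",
       "blood;liver"),
  list("glycine", "C2H5NO2", "NCC(=O)O", "endogenous", "blood"),
  list("alanine", "C3H7NO2", "CC(N)C(=O)O", "endogenous", "blood"),
  list("serine", "C3H7NO3", "OCC(N)C(=O)O", "endogenous", "blood"),
  list("valine", "C5H11NO2", "CC(C)C(N)C(=O)O", "endogenous", "blood"),
  list("leucine", "C6H13NO2", "CC(C)CC(N)C(=O)O", "endogenous", "blood"),
  list("isoleucine", "C6H13NO2", "CCC(C)C(N)C(=O)O", "endogenous", "blood"),
  list("proline", "C5H9NO2", "OC(=O)C1CCCN1", "endogenous", "blood"),
  list("threonine", "C4H9NO3", "CC(O)C(N)C(=O)O", "endogenous", "blood"),
  list("cysteine", "C3H7NO2S", "NC(CS)C(=O)O", "endogenous", "blood"),
  list("methionine", "C5H11NO2S", "CSCCC(N)C(=O)O", "endogenous", "blood"),
  list("phenylalanine", "C9H11NO2", "NC(Cc1ccccc1)C(=O)O", "endogenous",
       "blood;brain"),
  list("tyrosine", "C9H11NO3", "NC(Cc1ccc(O)cc1)C(=O)O", "endogenous",
       "blood;brain"),
  list("tryptophan", "C11H12N2O2", "NC(Cc1c[nH]c2ccccc12)C(=O)O",
       "endogenous", "blood;brain"),
  list("aspartic acid", "C4H7NO4", "NC(CC(=O)O)C(=O)O", "endogenous",
       "blood"),
  list("glutamic acid", "C5H9NO4", "NC(CCC(=O)O)C(=O)O", "endogenous",
       "brain;blood"),
  list("asparagine", "C4H8N2O3", "NC(=O)CC(N)C(=O)O", "endogenous",
       "blood"),
  list("glutamine", "C5H10N2O3", "NC(=O)CCC(N)C(=O)O", "endogenous",
       "brain;blood"),
  list("lysine", "C6H14N2O2", "NCCCCC(N)C(=O)O", "endogenous", "blood"),
  list("arginine", "C6H14N4O2", "NC(CCCNC(=N)N)C(=O)O", "endogenous",
       "blood"),
  list("tyramine", "C8H11NO", "NCCc1ccc(O)cc1", "endogenous", "brain"),
  list("hordenine", "C10H15NO", "CN(C)CCc1ccc(O)cc1", "exogenous",
       character()),
  list("enbucrilate", "C8H11NO2", "CCCCOC(=O)C(=C)C#N", "exogenous",
       character()),
  list("caffeine", "C8H10N4O2", "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "exogenous",
       "blood"),
  list("nicotine", "C10H14N2", "CN1CCCC1c1cccnc1", "exogenous", "blood"),
  list("salbutamol", "C13H21NO3", "CC(C)(C)NCC(O)c1ccc(O)c(CO)c1",
       "exogenous", character()),
  list("amphetamine", "C9H13N", "CC(N)Cc1ccccc1", "exogenous", character()),
  list("p-octopamine", "C8H11NO2", "NCC(O)c1ccc(O)cc1", "unspecified",
       "brain"),
  list("norfenefrine", "C8H11NO2", "NCC(O)c1cccc(O)c1", "unspecified",
       character())
)

#' 36-compound standards panel
#'
#' A fixed roster of 36 chemical standards (catecholamines, amino acids and
#' related compounds) of which exactly 28 are flagged endogenous; the
#' remainder are exogenous or unspecified.  Deterministic across runs.
#'
#' @return Metabolite data frame of 36 records with ids `std01..std36`.
#' @export
standards_panel <- function() {
  rows <- lapply(seq_along(.STANDARDS), function(i) {
    s <- .STANDARDS[[i]]
    metabolite_record(sprintf("std%02d", i), s[[1]], s[[2]], s[[3]],
                      s[[4]], s[[5]])
  })
  do.call(rbind, rows)
}

#' Define a synthetic mass-error model
#'
#' Generated feature m/z values are
#' `true + a*true^2 + b*true + c + N(0, sd_ppm * true * 1e-6)`,
#' emulating the deviation pattern where errors grow with distance from
#' the lock mass along the m/z axis.
#'
#' @param a,b,c Quadratic error-truth coefficients.
#' @param sd_ppm Gaussian noise level in ppm (default 0).
#' @return An object of class `synthetic_error_model`.
#' @export
synthetic_error_model <- function(a = 0, b = 0, c = 0, sd_ppm = 0) {
  structure(list(a = a, b = b, c = c, sd_ppm = sd_ppm),
            class = "synthetic_error_model")
}

.perturb <- function(true_mz, model) {
  true_mz + model$a * true_mz^2 + model$b * true_mz + model$c +
    stats::rnorm(length(true_mz), 0, model$sd_ppm * true_mz * 1e-6)
}

#' Generate a synthetic feature list with ground truth
#'
#' One feature per candidate derivative m/z in the database (for the given
#' matrix), perturbed by the error model, plus uniform-random decoy peaks
#' drawn over the candidate m/z range.  The returned truth table maps every
#' feature to its generating candidate (`NA` for decoys).
#'
#' @param db An `annotation_db`.
#' @param matrix Matrix name.
#' @param error A [synthetic_error_model()] (default: no error).
#' @param n_decoys Number of decoy peaks (default 0).
#' @param seed Integer seed fixing noise and decoys.
#' @return List with `features` (data frame with column `mz`, sorted
#'   ascending) and `truth` (data frame: `mz`, `true_mz`, `metabolite_id`,
#'   `form`; decoy rows have `NA` ids).
#' @export
make_feature_list <- function(db, matrix, error = synthetic_error_model(),
                              n_decoys = 0L, seed = 1L) {
  cand <- filter_candidates(db, matrix = matrix)
  if (!nrow(cand)) stop("no candidates for matrix ", matrix)
  set.seed(seed)
  obs <- .perturb(cand$mz, error)
  truth <- data.frame(mz = obs, true_mz = cand$mz,
                      metabolite_id = cand$metabolite_id,
                      form = cand$form, stringsAsFactors = FALSE)
  if (n_decoys > 0L) {
    rng <- range(cand$mz)
    dec <- stats::runif(n_decoys, rng[1], rng[2])
    truth <- rbind(truth,
                   data.frame(mz = dec, true_mz = NA_real_,
                              metabolite_id = NA_character_,
                              form = NA_character_,
                              stringsAsFactors = FALSE))
  }
  truth <- truth[order(truth$mz), , drop = FALSE]
  rownames(truth) <- NULL
  list(features = data.frame(mz = truth$mz), truth = truth)
}

#' Generate a synthetic MS2 reference library
#'
#' `n` synthetic reference spectra with 10-40 fragment peaks each (m/z
#' 50-440, exponential-ish intensities), optionally carrying the
#' class-diagnostic product ions of a matrix, plus paired noisy query
#' spectra (relative Gaussian intensity noise).
#'
#' @param n Number of reference spectra (>= 1).
#' @param seed Integer seed.
#' @param noise Relative intensity noise of the paired queries (default
#'   0.05 = 5\%).
#' @param diagnostic Optional character vector recycled over entries, each
#'   element `""` (no diagnostic ions), `"phenolic_hydroxyl"`,
#'   `"primary_amine"`, or `"both"`; the named FMP-10 product ions are
#'   appended to the reference and its query.
#' @param dir Optional directory: each query spectrum is also written as
#'   `query_<k>.mzML`.
#' @return List with `references` (named list of [ms2_spectrum]), `queries`
#'   (same length), and `paths` (mzML files, or NULL).
#' @export
make_ms2_library <- function(n, seed = 1L, noise = 0.05,
                             diagnostic = NULL, dir = NULL) {
  stopifnot(n >= 1)
  set.seed(seed)
  diag_mz <- diagnostic_ions(fmp10())
  diagnostic <- if (is.null(diagnostic)) rep("", n)
  else rep_len(diagnostic, n)
  refs <- list(); queries <- list(); paths <- NULL
  for (k in seq_len(n)) {
    np <- sample(10:40, 1)
    mz <- sort(stats::runif(np, 50, 440))
    inten <- stats::rexp(np, rate = 1 / 100)
    if (diagnostic[k] %in% c("phenolic_hydroxyl", "both")) {
      mz <- c(mz, diag_mz[["phenolic_hydroxyl"]]); inten <- c(inten, 150)
    }
    if (diagnostic[k] %in% c("primary_amine", "both")) {
      mz <- c(mz, diag_mz[["primary_amine"]]); inten <- c(inten, 150)
    }
    id <- sprintf("ref%03d", k)
    refs[[id]] <- ms2_spectrum(mz, inten, precursor_mz = 450,
                               collision_energy = 30,
                               isolation_window = 1,
                               metadata = list(id = id,
                                               name = sprintf("synthetic-%03d", k),
                                               label = "1A"))
    qint <- pmax(inten * (1 + stats::rnorm(length(inten), 0, noise)), 0)
    queries[[id]] <- ms2_spectrum(mz, qint, precursor_mz = 450,
                                  collision_energy = 30,
                                  isolation_window = 1,
                                  metadata = list(id = paste0("query_", id)))
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- vapply(seq_len(n), function(k) {
      p <- file.path(dir, sprintf("query_%03d.mzML", k))
      write_mzml(queries[[k]], p)
      p
    }, character(1))
  }
  list(references = refs, queries = queries, paths = paths)
}
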