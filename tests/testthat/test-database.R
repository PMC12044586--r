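# Candidate store construction, filtering, importers, and persistence.

test_that("the isomer panel builds the expected candidate index", {
  db <- fig3_db()
  cand <- db$candidates
  expect_identical(nrow(cand), 12L)
  forms <- split(cand$form, cand$metabolite_id)
  expect_identical(sort(forms$iso1),
                   sort(c("1A", "2A", "2B", "3AA", "3AB", "3BB")))
  expect_identical(sort(forms$iso2), sort(c("1A", "2A", "2B")))
  expect_identical(sort(forms$iso3), sort(c("1A", "2A", "2B")))
  expect_false("iso4" %in% cand$metabolite_id)  # zero targets
  expect_false(is.unsorted(cand$mz))
  # rebuild is idempotent
  expect_identical(build_database(fig_isomer_panel())$candidates, cand)
})

test_that("build validates ids, stored masses, and SMILES", {
  panel <- fig_isomer_panel()
  expect_error(build_database(rbind(panel, panel[1, ])), "iso1")

  with_mass <- cbind(panel, mass = c(153.078979, 153.078979, 160.0, NA))
  expect_warning(db <- build_database(with_mass), "iso3")
  expect_identical(attr(db, "rejected"), "iso3")
  expect_identical(nrow(db$metabolites), 3L)

  broken <- panel
  broken$smiles[2] <- "x(x(x"
  expect_message(db2 <- build_database(broken,
                                       adducts = default_adducts("positive")),
                 "iso2")
  expect_identical(attr(db2, "non_derivatizable"), "iso2")
  # kept for adduct search, absent from derivative candidates
  expect_true("iso2" %in%
                db2$candidates$metabolite_id[db2$candidates$kind == "adduct"])
  expect_false("iso2" %in%
                 db2$candidates$metabolite_id[db2$candidates$kind ==
                                                "derivative"])
  expect_identical(nrow(build_database(panel[0, ])$candidates), 0L)
})

test_that("precomputed target counts match fresh structure counts", {
  db <- fig3_db()
  for (id in db$metabolites$id[db$metabolites$derivatizable]) {
    smi <- db$metabolites$smiles[db$metabolites$id == id]
    fresh <- count_targets(smi, db$patterns[fmp10()$target_patterns])
    stored <- db$target_counts[db$target_counts$metabolite_id == id, ]
    expect_identical(stats::setNames(stored$count, stored$pattern)[
      names(fresh$counts)], fresh$counts, label = id)
  }
})

test_that("candidate filtering follows the two-step query semantics", {
  db <- fig3_db()
  # only dopamine can carry three tags: the high-mass window is exclusive
  hi <- filter_candidates(db, matrix = "FMP-10", mz_range = c(900, 950))
  expect_identical(unique(hi$metabolite_id), "iso1")
  expect_true(all(hi$n_tags == 3L))
  expect_identical(nrow(filter_candidates(db, matrix = "FMP-10",
                                          mz_range = c(0, 0))), 0L)
  expect_error(filter_candidates(db, matrix = "nope"), "unknown matrix")
  # a narrower tag cap drops insufficient-target forms
  capped <- filter_candidates(db, matrix = "FMP-10", max_tags = 1)
  expect_true(all(capped$n_tags == 1L))
})

test_that("endogeneity and tissue filters are monotone restrictions", {
  db <- standards_db()
  all_cand <- filter_candidates(db, matrix = "FMP-10")
  endo <- filter_candidates(db, matrix = "FMP-10",
                            endogeneity = "endogenous")
  endo_ids <- db$metabolites$id[db$metabolites$endogeneity == "endogenous"]
  expect_length(endo_ids, 28L)
  expect_true(all(endo$metabolite_id %in% endo_ids))
  expect_true(all(interaction(endo$metabolite_id, endo$form) %in%
                    interaction(all_cand$metabolite_id, all_cand$form)))

  brain <- filter_candidates(db, matrix = "FMP-10",
                             endogeneity = "endogenous", tissues = "brain")
  expect_lte(nrow(brain), nrow(endo))
  expect_identical(nrow(filter_candidates(db, matrix = "FMP-10",
                                          tissues = "any")),
                   nrow(all_cand))
  # combination semantics: union of selected flags
  both <- filter_candidates(db, matrix = "FMP-10",
                            endogeneity = c("endogenous", "exogenous"))
  expect_gte(nrow(both), nrow(endo))
  expect_lte(nrow(both), nrow(all_cand))
})

test_that("metabolite tables import with defaults and schema errors", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,name,formula,smiles,endogeneity,tissues",
               'm1,dopamine,C8H11NO2,NCCc1ccc(O)c(O)c1,endogenous,brain',
               'm2,glucose,C6H12O6,OCC1OC(O)C(O)C(O)C1O,,'), tmp)
  recs <- import_metabolite_table(tmp)
  expect_identical(nrow(recs), 2L)
  expect_identical(recs$endogeneity, c("endogenous", "unspecified"))

  hdr <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,name,formula,smiles", hdr)
  expect_identical(nrow(import_metabolite_table(hdr)), 0L)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,name,smiles", "a,b,c"), bad)
  expect_error(import_metabolite_table(bad), "formula")

  # tab- and semicolon-separated variants parse identically
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tname\tformula\tsmiles",
               "m1\tdopamine\tC8H11NO2\tNCCc1ccc(O)c(O)c1"), tsv)
  expect_identical(import_metabolite_table(tsv)$formula, "C8H11NO2")
})

test_that("export then re-import reproduces the candidate index exactly", {
  db <- standards_db()
  tmp <- withr::local_tempfile(fileext = ".csv")
  export_metabolite_table(db, tmp)
  again <- build_database(import_metabolite_table(tmp),
                          adducts = default_adducts("positive"))
  expect_identical(again$candidates, db$candidates)
  expect_identical(again$target_counts, db$target_counts)
})

test_that("HMDB-dialect snippets import with recomputed masses", {
  snippet <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n<hmdb>\n',
    '<metabolite><accession>TST0001</accession><name>dopamine</name>',
    '<chemical_formula>C8H11NO2</chemical_formula>',
    '<monisotopic_molecular_weight>153.078979</monisotopic_molecular_weight>',
    '<smiles>NCCc1ccc(O)c(O)c1</smiles>',
    '<ontology><root><term>Disposition</term><descendants><descendant>',
    '<term>Endogenous</term></descendant></descendants></root></ontology>',
    '<biospecimen_locations><biospecimen>Blood</biospecimen>',
    '<biospecimen>Cerebrospinal Fluid</biospecimen></biospecimen_locations>',
    '</metabolite>\n',
    '<metabolite><accession>TST0002</accession><name>caffeine</name>',
    '<chemical_formula>C8H10N4O2</chemical_formula>',
    '<ontology><term>Exogenous</term></ontology>',
    '<smiles>Cn1cnc2c1c(=O)n(C)c(=O)n2C</smiles></metabolite>\n',
    '<metabolite><accession>TST0003</accession><name>mystery</name>',
    '<chemical_formula>C2H5NO2</chemical_formula></metabolite>\n',
    '</hmdb>')
  tmp <- withr::local_tempfile(fileext = ".xml")
  writeLines(snippet, tmp)
  recs <- import_hmdb_snippet(tmp)
  expect_identical(nrow(recs), 3L)
  expect_identical(recs$endogeneity,
                   c("endogenous", "exogenous", "unspecified"))
  expect_true(grepl("Blood", recs$tissues[1]))

  db <- suppressMessages(build_database(recs))
  expect_equal(round(db$metabolites$neutral_mass[1], 5), 153.07898)
  # record without SMILES is kept but non-derivatizable
  expect_true("TST0003" %in% attr(db, "non_derivatizable"))

  empty <- withr::local_tempfile(fileext = ".xml")
  writeLines("<hmdb></hmdb>", empty)
  expect_identical(nrow(import_hmdb_snippet(empty)), 0L)

  mal <- withr::local_tempfile(fileext = ".xml")
  writeLines("<hmdb><metabolite>", mal)
  expect_error(import_hmdb_snippet(mal), "malformed XML")
})

test_that("databases persist through JSON round-trips with spectra", {
  db <- build_database(fig_isomer_panel(),
                       adducts = default_adducts("positive"))
  spec <- ms2_spectrum(c(100.1, 286.122641), c(10, 50),
                       precursor_mz = 421.19, collision_energy = 30,
                       metadata = list(id = "dop1A", name = "dopamine",
                                       label = "1A"))
  db <- add_spectrum(db, spec)
  expect_error(add_spectrum(db, spec), "dop1A")
  tmp <- withr::local_tempfile(fileext = ".json")
  write_database(db, tmp)
  back <- read_database(tmp)
  expect_identical(back$candidates, db$candidates)
  expect_identical(back$metabolites$id, db$metabolites$id)
  expect_equal(back$spectra$dop1A$mz, spec$mz)
  expect_equal(back$spectra$dop1A$intensity, spec$intensity)
  back <- remove_spectrum(back, "dop1A")
  expect_length(back$spectra, 0L)
  expect_error(remove_spectrum(back, "dop1A"), "dop1A")
})
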