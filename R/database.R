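# The annotation database: metabolite records, precomputed target counts per
# matrix, sorted candidate m/z indexes for derivative forms and adducts,
# endogeneity/tissue metadata, and MS2 reference spectra.
#
# The store is an in-memory S3 object of data frames with single-file JSON
# persistence, so builds and tests are hermetic; masses are always
# recomputed from formulas, never stored as primary data.

.ENDOGENEITY_LEVELS <- c("endogenous", "exogenous", "unspecified")

#' Construct a metabolite record
#'
#' @param id Unique record id.
#' @param name Compound name.
#' @param formula Hill formula (defines the neutral monoisotopic mass).
#' @param smiles SMILES structure (may be `NA`; such records are kept for
#'   adduct search but flagged non-derivatizable).
#' @param endogeneity One of `"endogenous"`, `"exogenous"`, `"unspecified"`.
#' @param tissues Character vector of tissue/biofluid tags.
#' @return One-row data frame in the metabolite-table schema.
#' @export
metabolite_record <- function(id, name, formula, smiles = NA_character_,
                              endogeneity = "unspecified",
                              tissues = character()) {
  endogeneity <- match.arg(endogeneity, .ENDOGENEITY_LEVELS)
  data.frame(id = id, name = name, formula = formula,
             smiles = as.character(smiles), endogeneity = endogeneity,
             tissues = paste(tissues, collapse = ";"),
             stringsAsFactors = FALSE)
}

.norm_records <- function(records) {
  if (is.data.frame(records)) df <- records
  else df <- do.call(rbind, records)
  need <- c("id", "name", "formula", "smiles")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metabolite table is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(df$endogeneity))
    df$endogeneity <- rep("unspecified", nrow(df))
  df$endogeneity[is.na(df$endogeneity) | !nzchar(df$endogeneity)] <-
    "unspecified"
  bad <- setdiff(unique(df$endogeneity), .ENDOGENEITY_LEVELS)
  if (length(bad))
    stop("invalid endogeneity value(s): ", paste(bad, collapse = ", "))
  if (is.null(df$tissues)) df$tissues <- rep("", nrow(df))
  df$tissues[is.na(df$tissues)] <- ""
  rownames(df) <- NULL
  df[c("id", "name", "formula", "smiles", "endogeneity", "tissues")] |>
    cbind(df[setdiff(names(df), c("id", "name", "formula", "smiles",
                                  "endogeneity", "tissues"))])
}

#' Build the annotation database
#'
#' Validates records, precomputes per-matrix target counts from SMILES,
#' enumerates every target-feasible derivative form and every requested
#' adduct ion, and materializes a candidate index sorted ascending by m/z.
#' Rebuilding from the same inputs is idempotent.
#'
#' Records whose stored `mass` column (if present) disagrees with their
#' formula by more than 1e-6 Da are rejected; the validation report is
#' attached as attribute `"rejected"` and a warning is raised.  Records with
#' unparseable SMILES are kept for adduct search, flagged non-derivatizable,
#' and listed in attribute `"non_derivatizable"`.
#'
#' @param records Metabolite table (data frame or list of
#'   [metabolite_record()] rows).
#' @param matrices List of [deriv_matrix] objects (default `list(fmp10())`).
#' @param adducts List of `ms_adduct` objects, or NULL for none.
#' @param patterns Named list of [functional_group] patterns resolving the
#'   matrices' `target_patterns` names (default FMP-10 + AMPP sets).
#' @return An object of class `annotation_db`.
#' @export
build_database <- function(records, matrices = list(fmp10()),
                           adducts = NULL,
                           patterns = c(fmp10_patterns(), ampp_patterns())) {
  df <- .norm_records(records)
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup))
    stop("duplicate metabolite id(s): ", paste(dup, collapse = ", "))

  df$neutral_mass <- vapply(df$formula,
                            function(f) monoisotopic_mz(parse_formula(f)),
                            numeric(1), USE.NAMES = FALSE)
  rejected <- character()
  if (!is.null(df$mass)) {
    stored <- suppressWarnings(as.numeric(df$mass))
    bad <- !is.na(stored) & abs(stored - df$neutral_mass) > 1e-6
    if (any(bad)) {
      rejected <- df$id[bad]
      warning("rejected ", sum(bad),
              " record(s) whose stored mass disagrees with the formula: ",
              paste(rejected, collapse = ", "))
      df <- df[!bad, , drop = FALSE]
    }
  }
  df$derivatizable <- !is.na(df$smiles) & nzchar(df$smiles) &
    vapply(df$smiles, function(s)
      !is.na(s) && nzchar(s) && smiles_parses(s), logical(1),
      USE.NAMES = FALSE)
  nonderiv <- df$id[!df$derivatizable]
  if (length(nonderiv))
    message("record(s) without usable SMILES kept for adduct search only: ",
            paste(nonderiv, collapse = ", "))

  names(matrices) <- vapply(matrices, `[[`, character(1), "name")

  # per-matrix, per-pattern target counts
  tc_rows <- list()
  for (mx in matrices) {
    pats <- patterns[intersect(mx$target_patterns, names(patterns))]
    for (i in which(df$derivatizable)) {
      tc <- count_targets(df$smiles[i], pats)
      tc_rows[[length(tc_rows) + 1L]] <- data.frame(
        metabolite_id = df$id[i], matrix = mx$name,
        pattern = names(tc$counts), count = unname(tc$counts),
        stringsAsFactors = FALSE)
    }
  }
  target_counts <- if (length(tc_rows)) do.call(rbind, tc_rows)
  else data.frame(metabolite_id = character(), matrix = character(),
                  pattern = character(), count = integer())

  # candidate index: derivative forms (target-feasible) + adducts
  cand <- list()
  for (mx in matrices) {
    tc_mx <- target_counts[target_counts$matrix == mx$name, , drop = FALSE]
    totals <- if (nrow(tc_mx))
      with(stats::aggregate(count ~ metabolite_id, data = tc_mx, FUN = sum),
           stats::setNames(count, metabolite_id))
    else stats::setNames(integer(), character())
    for (i in seq_len(nrow(df))) {
      ttl <- if (df$id[i] %in% names(totals)) totals[[df$id[i]]] else 0L
      forms <- enumerate_derivatives(df$neutral_mass[i], ttl, mx)
      if (nrow(forms))
        cand[[length(cand) + 1L]] <- data.frame(
          mz = forms$mz, metabolite_id = df$id[i], form = forms$label,
          source = mx$name, kind = "derivative", polarity = "positive",
          n_tags = forms$n_tags, stringsAsFactors = FALSE)
    }
  }
  for (ad in adducts) {
    if (!nrow(df)) break
    cand[[length(cand) + 1L]] <- data.frame(
      mz = vapply(df$neutral_mass, adduct_mz, numeric(1), adduct = ad),
      metabolite_id = df$id, form = ad$name, source = ad$name,
      kind = "adduct", polarity = ad$polarity, n_tags = 0L,
      stringsAsFactors = FALSE)
  }
  candidates <- if (length(cand)) do.call(rbind, cand)
  else data.frame(mz = numeric(), metabolite_id = character(),
                  form = character(), source = character(),
                  kind = character(), polarity = character(),
                  n_tags = integer())
  candidates <- candidates[order(candidates$mz, candidates$metabolite_id,
                                 candidates$form), , drop = FALSE]
  rownames(candidates) <- NULL

  db <- structure(list(metabolites = df, target_counts = target_counts,
                       candidates = candidates,
                       matrices = matrices,
                       adducts = adducts %||% list(),
                       patterns = patterns,
                       spectra = list()),
                  class = "annotation_db")
  attr(db, "rejected") <- rejected
  attr(db, "non_derivatizable") <- nonderiv
  db
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.annotation_db <- function(x, ...) {
  cat(sprintf(
    "<annotation_db: %d metabolites, %d candidates (%d derivative / %d adduct), %d matrices, %d MS2 spectra>\n",
    nrow(x$metabolites), nrow(x$candidates),
    sum(x$candidates$kind == "derivative"),
    sum(x$candidates$kind == "adduct"),
    length(x$matrices), length(x$spectra)))
  invisible(x)
}

#' Total derivatization targets per metabolite for one matrix
#'
#' @param db An `annotation_db`.
#' @param matrix Matrix name.
#' @return Named integer vector, metabolite id to total target count
#'   (ids absent from the matrix's count table, e.g. records without
#'   SMILES, get 0).
#' @export
target_totals <- function(db, matrix) {
  tc <- db$target_counts[db$target_counts$matrix == matrix, , drop = FALSE]
  out <- stats::setNames(integer(nrow(db$metabolites)), db$metabolites$id)
  if (nrow(tc)) {
    agg <- stats::aggregate(count ~ metabolite_id, data = tc, FUN = sum)
    out[agg$metabolite_id] <- agg$count
  }
  out
}

.tissue_set <- function(s) {
  if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1]]
}

#' Select candidate rows (Step 1 of the two-step query)
#'
#' Applies, in order: source selection (one matrix or a set of adducts),
#' m/z range, derivatizability (a matrix that cannot derivatize a metabolite
#' contributes no rows), tag sufficiency (forms needing more tags than the
#' metabolite has targets are dropped), endogeneity, and tissue filters.
#' The result stays sorted ascending by m/z.
#'
#' @param db An `annotation_db`.
#' @param matrix Matrix name to search, or NULL.
#' @param adducts Character vector of adduct names to search, or NULL.
#' @param endogeneity NULL (no filter) or a subset of
#'   `c("endogenous", "exogenous", "unspecified")`; a record passes if its
#'   flag is in the set.
#' @param tissues NULL or `"any"` (no filter) or a character vector; a
#'   record passes if its tissue set intersects the selection.
#' @param mz_range Numeric length-2, inclusive bounds.
#' @param max_tags Optional cap on tags per form.
#' @return Candidate data frame, sorted ascending by m/z.
#' @export
filter_candidates <- function(db, matrix = NULL, adducts = NULL,
                              endogeneity = NULL, tissues = NULL,
                              mz_range = c(0, Inf), max_tags = Inf) {
  stopifnot(inherits(db, "annotation_db"))
  cand <- db$candidates
  sources <- character()
  if (!is.null(matrix)) {
    if (!matrix %in% names(db$matrices))
      stop("unknown matrix: ", matrix)
    sources <- c(sources, matrix)
  }
  if (!is.null(adducts)) {
    bad <- setdiff(adducts, names(db$adducts))
    if (length(bad)) stop("unknown adduct(s): ", paste(bad, collapse = ", "))
    sources <- c(sources, adducts)
  }
  if (length(sources))
    cand <- cand[cand$source %in% sources, , drop = FALSE]
  cand <- cand[cand$mz >= mz_range[1] & cand$mz <= mz_range[2], ,
               drop = FALSE]
  if (!is.null(matrix) && nrow(cand)) {
    tot <- target_totals(db, matrix)
    is_deriv <- cand$kind == "derivative" & cand$source == matrix
    feas <- tot[cand$metabolite_id]
    drop <- is_deriv & (feas == 0L | cand$n_tags > feas |
                          cand$n_tags > max_tags)
    cand <- cand[!drop, , drop = FALSE]
  }
  meta <- db$metabolites
  if (!is.null(endogeneity) && nrow(cand)) {
    keep_ids <- meta$id[meta$endogeneity %in% endogeneity]
    cand <- cand[cand$metabolite_id %in% keep_ids, , drop = FALSE]
  }
  if (!is.null(tissues) && !identical(tissues, "any") && nrow(cand)) {
    keep_ids <- meta$id[vapply(meta$tissues, function(s)
      length(intersect(.tissue_set(s), tissues)) > 0, logical(1))]
    cand <- cand[cand$metabolite_id %in% keep_ids, , drop = FALSE]
  }
  cand <- cand[order(cand$mz, cand$metabolite_id, cand$form), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Import a delimited metabolite table
#'
#' Reads a csv/tsv (UTF-8, header row, sniffed delimiter among comma,
#' semicolon, tab) with mandatory columns id, name, formula, smiles and
#' optional endogeneity / tissues (defaults: unspecified / empty).
#'
#' @param path File path.
#' @return Metabolite data frame in the canonical schema.
#' @export
import_metabolite_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty metabolite table: ", path)
  header <- lines[1]
  sep <- c(",", ";", "\t")[which.max(vapply(
    c(",", ";", "\t"), function(s) lengths(gregexpr(s, header, fixed = TRUE)),
    numeric(1)))]
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "",
                          colClasses = "character", encoding = "UTF-8")
  need <- c("id", "name", "formula", "smiles")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metabolite table ", path, " is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (!nrow(df))
    return(.norm_records(data.frame(id = character(), name = character(),
                                    formula = character(),
                                    smiles = character())))
  .norm_records(df)
}

#' Export the metabolite table of a database
#'
#' Writes the canonical delimited schema; re-importing and rebuilding
#' reproduces the candidate index bit-identically (masses are recomputed
#' from formulas, never stored).
#'
#' @param db An `annotation_db` or a metabolite data frame.
#' @param path Output csv path.
#' @return `path`, invisibly.
#' @export
export_metabolite_table <- function(db, path) {
  df <- if (inherits(db, "annotation_db")) db$metabolites else db
  utils::write.csv(df[c("id", "name", "formula", "smiles", "endogeneity",
                        "tissues")],
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Import metabolite records from an HMDB-dialect XML snippet
#'
#' Extracts accession, name, chemical formula, SMILES, monoisotopic mass
#' (cross-checked against the formula), endogeneity (from disposition /
#' ontology terms "Endogenous" / "Exogenous") and tissue locations from one
#' or more `<metabolite>` elements.
#'
#' @param path Path to an XML file (or a literal XML string).
#' @return Metabolite data frame; zero rows for a document without
#'   metabolite elements.
#' @export
import_hmdb_snippet <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed XML: ",
                                           conditionMessage(e),
                                           call. = FALSE))
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, "//metabolite")
  if (!length(nodes))
    return(.norm_records(data.frame(id = character(), name = character(),
                                    formula = character(),
                                    smiles = character())))
  one <- function(node) {
    gettext1 <- function(xp) {
      v <- xml2::xml_text(xml2::xml_find_first(node, xp))
      if (is.na(v) || !nzchar(v)) NA_character_ else v
    }
    terms <- xml2::xml_text(xml2::xml_find_all(
      node, ".//term | .//disposition | .//origin"))
    endo <- if (any(grepl("^Endogenous$", terms, ignore.case = TRUE)))
      "endogenous"
    else if (any(grepl("^Exogenous$", terms, ignore.case = TRUE)))
      "exogenous"
    else "unspecified"
    tiss <- xml2::xml_text(xml2::xml_find_all(
      node, ".//biospecimen_locations/biospecimen | .//tissue_locations/tissue"))
    data.frame(id = gettext1("accession"),
               name = gettext1("name"),
               formula = gettext1("chemical_formula"),
               smiles = gettext1("smiles"),
               endogeneity = endo,
               tissues = paste(tiss, collapse = ";"),
               mass = gettext1("monisotopic_molecular_weight") %||NA%
                 gettext1("monoisotopic_molecular_weight"),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(nodes, one))
  .norm_records(out)
}

`%||NA%` <- function(a, b) if (is.na(a)) b else a

#' Persist a database to a single JSON file
#'
#' @param db An `annotation_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_database <- function(db, path) {
  stopifnot(inherits(db, "annotation_db"))
  ser <- list(
    metabolites = db$metabolites[c("id", "name", "formula", "smiles",
                                   "endogeneity", "tissues")],
    matrices = lapply(db$matrices, .ser_matrix),
    adducts = lapply(db$adducts, function(a)
      list(name = a$name, add = format(a$add), remove = format(a$remove),
           charge = a$charge)),
    patterns = lapply(db$patterns, function(p)
      list(name = p$name, query = p$query, exclusions = p$exclusions)),
    spectra = lapply(db$spectra, .ser_spectrum)
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

.ser_matrix <- function(m) {
  list(name = m$name, reagent = format(m$reagent),
       leaving_group = format(m$leaving_group),
       target_patterns = m$target_patterns,
       losses = lapply(m$losses, format),
       max_tags = if (is.finite(m$max_tags)) m$max_tags else "all",
       diagnostic_adducts = if (!is.null(m$diagnostic_adducts))
         lapply(m$diagnostic_adducts, format))
}

.deser_matrix <- function(s) {
  deriv_matrix(
    name = s$name,
    reagent = parse_formula(s$reagent, charge = 1L),
    leaving_group = if (nzchar(s$leaving_group))
      parse_formula(s$leaving_group) else composition(),
    target_patterns = unlist(s$target_patterns),
    losses = lapply(s$losses, parse_formula, charge = 1L),
    max_tags = if (identical(s$max_tags, "all")) Inf else s$max_tags,
    diagnostic_adducts = if (!is.null(s$diagnostic_adducts))
      lapply(s$diagnostic_adducts, parse_formula)
  )
}

#' Load a database written by [write_database()]
#'
#' The candidate index is rebuilt from the stored records, so the loaded
#' database is bit-identical to a fresh [build_database()] on the same
#' inputs.
#'
#' @param path JSON file path.
#' @return An `annotation_db`.
#' @export
read_database <- function(path) {
  if (!file.exists(path)) stop("no such database file: ", path)
  ser <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE,
                             simplifyMatrix = FALSE)
  matrices <- lapply(
    if (is.data.frame(ser$matrices)) split(ser$matrices,
                                           seq_len(nrow(ser$matrices)))
    else ser$matrices, .deser_matrix)
  adducts <- lapply(ser$adducts, function(a)
    adduct(a$name, add = a$add, remove = a$remove, charge = a$charge))
  names(adducts) <- vapply(adducts, `[[`, character(1), "name")
  patterns <- lapply(ser$patterns, function(p)
    functional_group(p$name, p$query, unlist(p$exclusions) %||% character()))
  names(patterns) <- vapply(patterns, `[[`, character(1), "name")
  db <- suppressMessages(build_database(ser$metabolites,
                                        matrices = matrices,
                                        adducts = adducts,
                                        patterns = patterns))
  for (s in ser$spectra) db <- add_spectrum(db, .deser_spectrum(s))
  db
}

#' Add an MS2 reference spectrum to the database
#'
#' @param db An `annotation_db`.
#' @param spectrum An [ms2_spectrum]; its metadata `id` keys the library
#'   entry (one is generated when absent).
#' @return The updated database.
#' @export
add_spectrum <- function(db, spectrum) {
  stopifnot(inherits(db, "annotation_db"),
            inherits(spectrum, "ms2_spectrum"))
  id <- spectrum$metadata$id %||%
    sprintf("spec%03d", length(db$spectra) + 1L)
  spectrum$metadata$id <- id
  if (id %in% names(db$spectra))
    stop("a spectrum with id '", id, "' already exists")
  db$spectra[[id]] <- spectrum
  db
}

#' Remove an MS2 reference spectrum from the database
#'
#' @param db An `annotation_db`.
#' @param id Spectrum id.
#' @return The updated database.
#' @export
remove_spectrum <- function(db, id) {
  if (!id %in% names(db$spectra)) stop("no spectrum with id '", id, "'")
  db$spectra[[id]] <- NULL
  db
}
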