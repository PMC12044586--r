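# Functional-group counting on SMILES structures.
#
# A derivatizing matrix reacts with specific functional groups; the number of
# reactive sites ("targets") on a metabolite bounds how many tags it can
# carry.  Counting is SMARTS substructure matching (OpenBabel via ChemmineOB)
# with optional exclusion patterns subtracted, floored at zero.

#' Define a functional-group pattern
#'
#' @param name Pattern name (e.g. `"phenolic_hydroxyl"`).
#' @param query SMARTS substructure query; one match = one reactive site.
#' @param exclusions Character vector of SMARTS patterns whose match counts
#'   are subtracted from the query count (e.g. amide nitrogens matched by a
#'   plain amine query); net counts never go below zero.
#' @return An object of class `functional_group`.
#' @export
functional_group <- function(name, query, exclusions = character()) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(query), length(query) == 1L,
            is.character(exclusions))
  structure(list(name = name, query = query, exclusions = exclusions),
            class = "functional_group")
}

#' @export
print.functional_group <- function(x, ...) {
  cat(sprintf("<functional_group %s: %s%s>\n", x$name, x$query,
              if (length(x$exclusions))
                paste0(" minus {", paste(x$exclusions, collapse = ", "), "}")
              else ""))
  invisible(x)
}

#' Default target patterns for FMP-10-style charge tagging
#'
#' FMP-10 derivatizes phenolic hydroxyls and primary or secondary amines.
#' A phenolic hydroxyl is a hydroxyl oxygen bonded to an aromatic carbon, so
#' carboxylic and aliphatic (e.g. benzylic) hydroxyls never count.  Amine
#' patterns exclude amide and sulfonamide nitrogens; aromatic ring NH (e.g.
#' an indole nitrogen) is not a secondary-amine target unless
#' `include_ring_nh = TRUE`.
#'
#' @param include_secondary Include the secondary-amine pattern (default
#'   TRUE).
#' @param include_ring_nh Also count aromatic ring NH as a secondary amine
#'   (default FALSE).
#' @return Named list of [functional_group] objects.
#' @export
fmp10_patterns <- function(include_secondary = TRUE, include_ring_nh = FALSE) {
  pats <- list(
    phenolic_hydroxyl = functional_group(
      "phenolic_hydroxyl", "[OX2H][c]"),
    primary_amine = functional_group(
      "primary_amine", "[NX3;H2][#6]",
      exclusions = c("[NX3;H2][CX3]=[OX1]", "[NX3;H2][SX4](=[OX1])=[OX1]"))
  )
  if (include_secondary) {
    pats$secondary_amine <- functional_group(
      "secondary_amine", "[NX3;H1]([#6])[#6]",
      exclusions = c("[NX3;H1]([#6])[CX3]=[OX1]",
                     "[NX3;H1]([#6])[SX4](=[OX1])=[OX1]"))
    if (include_ring_nh)
      pats$ring_nh <- functional_group("ring_nh", "[nX3H]")
  }
  pats
}

#' Target patterns for AMPP-style amide coupling
#'
#' AMPP couples to carboxylic acids (losing water).
#'
#' @return Named list with the carboxylic-acid pattern.
#' @export
ampp_patterns <- function() {
  list(carboxylic_acid = functional_group(
    "carboxylic_acid", "[CX3](=[OX1])[OX2H]"))
}

# raw SMARTS match count on one parsed molecule (unique atom mappings)
.ob_ns <- function() getNamespace("ChemmineOB")

.smarts_count_mol <- function(mol, smarts) {
  ns <- .ob_ns()
  sp <- get("OBSmartsPattern", ns)()
  if (!get("OBSmartsPattern_Init", ns)(sp, smarts))
    stop("failed to parse SMARTS pattern: ", smarts)
  get("OBSmartsPattern_Match", ns)(sp, mol)
  umap <- get("OBSmartsPattern_GetUMapList", ns)(sp)
  length(umap)
}

.with_molecule <- function(smiles, fn) {
  res <- tryCatch(
    ChemmineOB::forEachMol("SMILES", smiles, fn),
    error = function(e)
      stop("unparseable SMILES '", smiles, "': ", conditionMessage(e),
           call. = FALSE)
  )
  res[[1]]
}

#' Count derivatization targets on a structure
#'
#' Parses a SMILES string and counts, per pattern, the net number of reactive
#' sites: SMARTS query matches (deduplicated over symmetric atom mappings)
#' minus exclusion-pattern matches, floored at zero.
#'
#' @param smiles Character scalar SMILES.
#' @param patterns List of [functional_group] objects (default
#'   [fmp10_patterns()]).
#' @return A `target_count`: list with `counts` (named integer per pattern)
#'   and `total`.
#' @examples
#' count_targets("NCCc1ccc(O)c(O)c1")   # dopamine: 2 phenolic OH + 1 amine
#' @export
count_targets <- function(smiles, patterns = fmp10_patterns()) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  counts <- .with_molecule(smiles, function(mol) {
    vapply(patterns, function(p) {
      n <- .smarts_count_mol(mol, p$query)
      for (ex in p$exclusions) n <- n - .smarts_count_mol(mol, ex)
      max(0L, as.integer(n))
    }, integer(1))
  })
  names(counts) <- vapply(patterns, `[[`, character(1), "name")
  structure(list(counts = counts, total = sum(counts)),
            class = "target_count")
}

#' @export
print.target_count <- function(x, ...) {
  cat("<target_count total", x$total, "|",
      paste(names(x$counts), x$counts, sep = "=", collapse = " "), ">\n")
  invisible(x)
}

#' Check whether a SMILES string parses
#'
#' @param smiles Character scalar.
#' @return TRUE if OpenBabel parses the string into a molecule with at least
#'   one atom.
#' @export
smiles_parses <- function(smiles) {
  ok <- tryCatch({
    n <- .with_molecule(smiles, function(mol)
      get("OBMol_NumAtoms", .ob_ns())(mol))
    n > 0
  }, error = function(e) FALSE)
  isTRUE(ok)
}
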