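# Derivatizing matrices and enumeration of observable derivative ions.
#
# A charge-tagging matrix adds, per reaction, a fixed cationic tag (reagent
# cation minus a neutral leaving group) and one positive charge.  Multiply
# tagged species return to charge +1 through charge-reduction losses: for
# FMP-10 loss of a methyl cation (label "A", demethylated form) or of a
# proton (label "B", dehydrogenated form).  An n-tag +1 ion therefore
# carries exactly n - 1 losses.

#' Define a derivatizing matrix
#'
#' @param name Matrix name (e.g. `"FMP-10"`).
#' @param reagent `elemental_composition` of the intact reagent cation
#'   (charge +1).
#' @param leaving_group Neutral `elemental_composition` lost in each tagging
#'   reaction (HF for FMP-10, H2O for amide coupling).
#' @param target_patterns Character vector of functional-group pattern names
#'   this matrix reacts with.
#' @param losses Named list of charge-reduction losses: single-letter label
#'   to +1 `elemental_composition` (the cation lost).
#' @param max_tags Maximum tags to enumerate, or `Inf` for "all targets".
#' @param diagnostic_adducts Optional named list, pattern name to neutral
#'   `elemental_composition`, describing the neutral retained on the tag
#'   fragment in the class-diagnostic MS2 product ion (H2O for phenolic
#'   hydroxyls, NH3 for primary amines under FMP-10).
#' @return An object of class `deriv_matrix`.
#' @export
deriv_matrix <- function(name, reagent, leaving_group, target_patterns,
                         losses, max_tags = Inf,
                         diagnostic_adducts = NULL) {
  stopifnot(inherits(reagent, "elemental_composition"),
            inherits(leaving_group, "elemental_composition"))
  if (reagent$charge != 1L)
    stop("matrix reagent must be a +1 cation (got charge ",
         reagent$charge, ")")
  if (leaving_group$charge != 0L)
    stop("matrix leaving group must be neutral")
  for (l in losses)
    if (l$charge != 1L)
      stop("every charge-reduction loss must be a +1 cation")
  if (is.null(names(losses)) || any(nchar(names(losses)) != 1L))
    stop("losses must be named by single-letter labels")
  structure(list(name = name, reagent = reagent,
                 leaving_group = leaving_group,
                 target_patterns = target_patterns,
                 losses = losses, max_tags = max_tags,
                 diagnostic_adducts = diagnostic_adducts),
            class = "deriv_matrix")
}

#' @export
print.deriv_matrix <- function(x, ...) {
  cat(sprintf("<deriv_matrix %s: +%s -%s per tag (shift %.6f Da), losses {%s}, targets {%s}>\n",
              x$name, format(x$reagent), format(x$leaving_group),
              tag_shift(x), paste(names(x$losses), collapse = ","),
              paste(x$target_patterns, collapse = ",")))
  invisible(x)
}

#' The FMP-10 charge-tagging matrix
#'
#' 4-(anthracen-9-yl)-2-fluoro-1-methylpyridin-1-ium: tags phenolic
#' hydroxyls and primary/secondary amines with loss of neutral HF, adding
#' 268.112076 Da and one positive charge per tag.  Charge-reduction losses
#' are A = methyl cation, B = proton.
#'
#' @param max_tags Maximum tags to enumerate (default 3, the highest
#'   derivatization state observed for its target metabolites).
#' @return A [deriv_matrix].
#' @export
fmp10 <- function(max_tags = 3L) {
  deriv_matrix(
    name = "FMP-10",
    reagent = parse_formula("C20H15FN", charge = 1L),
    leaving_group = parse_formula("HF"),
    target_patterns = c("phenolic_hydroxyl", "primary_amine",
                        "secondary_amine"),
    losses = list(A = parse_formula("CH3", charge = 1L),
                  B = parse_formula("H", charge = 1L)),
    max_tags = max_tags,
    diagnostic_adducts = list(phenolic_hydroxyl = parse_formula("H2O"),
                              primary_amine = parse_formula("NH3"))
  )
}

#' The AMPP amide-coupling matrix
#'
#' (4-aminomethylphenyl)pyridinium couples to carboxylic acids with loss of
#' water.  Shipped as configuration; no charge-reduction losses are defined
#' because multiply tagged AMPP ions are not modelled.
#'
#' @return A [deriv_matrix].
#' @export
ampp <- function() {
  deriv_matrix(
    name = "AMPP",
    reagent = parse_formula("C12H13N2", charge = 1L),
    leaving_group = parse_formula("H2O"),
    target_patterns = "carboxylic_acid",
    losses = list(A = parse_formula("CH3", charge = 1L),
                  B = parse_formula("H", charge = 1L)),
    max_tags = 1L
  )
}

#' Neutral mass shift added per tagging reaction
#'
#' The reagent cation mass minus the neutral leaving-group mass; for FMP-10
#' this is 268.112076 Da, which also equals the m/z of the reagent fragment
#' peak observed in spectra.
#'
#' @param matrix A [deriv_matrix].
#' @return Mass shift in Da.
#' @export
tag_shift <- function(matrix) {
  stopifnot(inherits(matrix, "deriv_matrix"))
  monoisotopic_mz(matrix$reagent) - monoisotopic_mz(matrix$leaving_group)
}

# all size-k multisets from a label set, as a character matrix (k rows);
# k = 0 yields a single empty multiset
.loss_multisets <- function(labels, k) {
  if (k == 0L) return(list(character(0)))
  idx <- utils::combn(seq_len(length(labels) + k - 1L), k, simplify = FALSE)
  lapply(idx, function(ix) labels[ix - seq_len(k) + 1L])
}

.form_label <- function(n_tags, losses) {
  paste0(n_tags, paste(sort(losses), collapse = ""),
         if (n_tags == 1L) "A" else "")
}

#' Enumerate observable derivative ions of a metabolite
#'
#' For each tag count n from 1 to `min(max_tags, n_targets)` and each
#' multiset of n - 1 charge-reduction losses, computes the m/z of the
#' resulting +1 ion:
#' neutral mass + n * (reagent cation - leaving group) - sum(loss cations).
#' The single-tag species needs no loss and is labelled "1A" by convention;
#' multi-tag labels append the sorted loss letters ("2A", "2B", "3AA", ...).
#' Forms whose m/z coincide within 1e-9 Da are merged, keeping all labels.
#'
#' @param neutral_mass Neutral monoisotopic mass of the metabolite (Da).
#' @param n_targets Total derivatization targets (from [count_targets()]).
#' @param matrix A [deriv_matrix].
#' @param strict_losses If TRUE, only uniform loss multisets (all-A or
#'   all-B) are enumerated; the default enumerates all multisets (mixed
#'   forms such as "3AB" included).
#' @return Data frame with columns `label`, `n_tags`, `losses`, `mz`,
#'   ordered by `n_tags` then label; zero rows when `n_targets` is 0.
#' @examples
#' enumerate_derivatives(153.0789786, 3, fmp10())  # the dopamine series
#' @export
enumerate_derivatives <- function(neutral_mass, n_targets, matrix,
                                  strict_losses = FALSE) {
  stopifnot(inherits(matrix, "deriv_matrix"), neutral_mass >= 0)
  if (inherits(n_targets, "target_count")) n_targets <- n_targets$total
  n_max <- min(matrix$max_tags, n_targets)
  empty <- data.frame(label = character(), n_tags = integer(),
                      losses = character(), mz = numeric(),
                      stringsAsFactors = FALSE)
  if (n_max < 1L) return(empty)
  shift <- tag_shift(matrix)
  loss_mz <- vapply(matrix$losses, monoisotopic_mz, numeric(1))
  rows <- list()
  for (n in seq_len(n_max)) {
    sets <- .loss_multisets(names(matrix$losses), n - 1L)
    if (strict_losses && n > 1L)
      sets <- Filter(function(s) length(unique(s)) == 1L, sets)
    for (s in sets) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = .form_label(n, s), n_tags = n,
        losses = paste(sort(s), collapse = ""),
        mz = neutral_mass + n * shift - sum(loss_mz[s]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  # merge coincident m/z, keeping all labels
  if (nrow(out) > 1L) {
    key <- round(out$mz / 1e-9)
    if (anyDuplicated(key)) {
      keep <- !duplicated(key)
      merged <- vapply(key[keep], function(k)
        paste(out$label[key == k], collapse = "|"), character(1))
      out <- out[keep, ]
      out$label <- merged
    }
  }
  out[order(out$n_tags, out$label), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Define an ionization adduct
#'
#' An adduct attaches and/or removes atoms from the neutral molecule and
#' leaves a singly charged ion.
#'
#' @param name Adduct name, e.g. `"[M+H]+"`.
#' @param add Formula of atoms gained (e.g. `"Na"`), `""` for none.
#' @param remove Formula of atoms lost (e.g. `"H2"`), `""` for none.
#' @param charge Ion charge, +1 or -1.
#' @return An object of class `ms_adduct`.
#' @export
adduct <- function(name, add = "", remove = "", charge = 1L) {
  if (abs(charge) != 1L)
    stop("adduct '", name, "' must yield |charge| = 1")
  .adduct_spec(name, add = add, remove = remove, charge = charge)
}

.adduct_spec <- function(name, add = "", remove = "", charge) {
  a <- if (nzchar(add)) parse_formula(add) else composition()
  r <- if (nzchar(remove)) parse_formula(remove) else composition()
  structure(list(name = name, add = a, remove = r,
                 charge = as.integer(charge),
                 polarity = if (charge > 0) "positive" else "negative"),
            class = "ms_adduct")
}

#' Common singly charged adducts
#'
#' Positive: `[M+H]+`, `[M+Na]+`, `[M+K]+`; negative: `[M-H]-`, `[M+Cl]-`,
#' `[M+Na-2H]-`, `[M+K-2H]-`, `[M-H2O-H]-`.
#'
#' @param polarity `"positive"`, `"negative"`, or `"both"` (default).
#' @return Named list of `ms_adduct` objects.
#' @export
default_adducts <- function(polarity = c("both", "positive", "negative")) {
  polarity <- match.arg(polarity)
  all <- list(
    .adduct_spec("[M+H]+",  add = "H",  charge = 1L),
    .adduct_spec("[M+Na]+", add = "Na", charge = 1L),
    .adduct_spec("[M+K]+",  add = "K",  charge = 1L),
    .adduct_spec("[M-H]-",  remove = "H",  charge = -1L),
    .adduct_spec("[M+Cl]-", add = "Cl", charge = -1L),
    .adduct_spec("[M+Na-2H]-", add = "Na", remove = "H2", charge = -1L),
    .adduct_spec("[M+K-2H]-",  add = "K",  remove = "H2", charge = -1L),
    .adduct_spec("[M-H2O-H]-", remove = "H3O", charge = -1L)
  )
  names(all) <- vapply(all, `[[`, character(1), "name")
  if (polarity == "both") all
  else Filter(function(a) a$polarity == polarity, all)
}

#' m/z of an adduct ion of a neutral molecule
#'
#' Electron-mass-correct: the delta mass includes gain/loss of the electron
#' implied by the adduct charge.
#'
#' @param neutral_mass Neutral monoisotopic mass (Da), > 0.
#' @param adduct An `ms_adduct` (see [default_adducts()]).
#' @return m/z of the singly charged adduct ion.
#' @examples
#' adduct_mz(180.063388, default_adducts()[["[M-H]-"]])  # deprotonated glucose
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  stopifnot(inherits(adduct, "ms_adduct"), neutral_mass > 0)
  delta <- sum(.ISOTOPE_MASS[names(adduct$add$counts)] * adduct$add$counts,
               0) -
    sum(.ISOTOPE_MASS[names(adduct$remove$counts)] * adduct$remove$counts,
        0) -
    adduct$charge * .ELECTRON_MASS
  mz <- neutral_mass + delta
  if (mz <= 0)
    stop("adduct ", adduct$name, " yields non-positive m/z for mass ",
         neutral_mass)
  mz
}
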