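# MS2 spectra: mzML I/O, binning, cosine similarity, library search,
# mirror export, and matrix-specific diagnostic product ions.

#' Construct an MS2 spectrum
#'
#' @param mz Numeric vector of fragment m/z values.
#' @param intensity Non-negative intensities, same length.
#' @param precursor_mz Optional precursor m/z.
#' @param collision_energy Optional CID collision energy (eV).
#' @param isolation_window Optional isolation window width (Da).
#' @param metadata Named list (compound name, derivative label, id, ...).
#' @return An object of class `ms2_spectrum`; peaks are stored sorted by
#'   m/z.
#' @export
ms2_spectrum <- function(mz, intensity, precursor_mz = NA_real_,
                         collision_energy = NA_real_,
                         isolation_window = NA_real_,
                         metadata = list()) {
  stopifnot(length(mz) == length(intensity), length(mz) >= 1)
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (any(mz <= 0)) stop("fragment m/z must be positive")
  ord <- order(mz)
  structure(list(mz = as.numeric(mz[ord]),
                 intensity = as.numeric(intensity[ord]),
                 precursor_mz = precursor_mz,
                 collision_energy = collision_energy,
                 isolation_window = isolation_window,
                 metadata = metadata),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum%s: %d peaks%s%s>\n",
              if (!is.null(x$metadata$id)) paste0(" ", x$metadata$id) else "",
              length(x$mz),
              if (!is.na(x$precursor_mz))
                sprintf(", precursor %.4f", x$precursor_mz) else "",
              if (!is.na(x$collision_energy))
                sprintf(", CID %g eV", x$collision_energy) else ""))
  invisible(x)
}

.ser_spectrum <- function(s) {
  list(mz = s$mz, intensity = s$intensity, precursor_mz = s$precursor_mz,
       collision_energy = s$collision_energy,
       isolation_window = s$isolation_window, metadata = s$metadata)
}

.deser_spectrum <- function(l) {
  ms2_spectrum(unlist(l$mz), unlist(l$intensity),
               precursor_mz = l$precursor_mz %||% NA_real_,
               collision_energy = l$collision_energy %||% NA_real_,
               isolation_window = l$isolation_window %||% NA_real_,
               metadata = as.list(l$metadata))
}

#' Read MS2 scans from an mzML file
#'
#' Returns one spectrum per centroided MS2 scan with precursor m/z,
#' collision energy, and isolation-window width where present; peaks are
#' sorted on load.  A file whose MS2 scans are profile mode is rejected
#' with advice to centroid first.
#'
#' @param path mzML file path.
#' @return List of [ms2_spectrum] objects (empty, with a warning, when the
#'   file holds no MS2 scans).
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  f <- mzR::openMSfile(path)
  on.exit(mzR::close(f), add = TRUE)
  h <- mzR::header(f)
  ms2 <- which(h$msLevel == 2L)
  if (!length(ms2)) {
    warning("no MS2 scans in ", path)
    return(list())
  }
  if (any(!is.na(h$centroided[ms2]) & !h$centroided[ms2]))
    stop("mzML file contains profile-mode MS2 scans; centroid the data ",
         "before import: ", path)
  lapply(ms2, function(i) {
    pk <- mzR::peaks(f, i)
    iso <- NA_real_
    if (all(c("isolationWindowLowerOffset", "isolationWindowUpperOffset")
            %in% names(h))) {
      lo <- h$isolationWindowLowerOffset[i]
      up <- h$isolationWindowUpperOffset[i]
      if (!is.na(lo) && !is.na(up)) iso <- lo + up
    }
    ms2_spectrum(pk[, 1], pk[, 2],
                 precursor_mz = h$precursorMZ[i],
                 collision_energy = h$collisionEnergy[i],
                 isolation_window = iso,
                 metadata = list(scan = i, file = basename(path)))
  })
}

# --- minimal centroid-MS2 mzML writer (fixtures are generated in-repo) ---

.b64_doubles <- function(x)
  gsub("[\r\n]", "", jsonlite::base64_enc(writeBin(as.double(x), raw(),
                                                   size = 8,
                                                   endian = "little")))

.mzml_spectrum_xml <- function(idx, s) {
  n <- length(s$mz)
  mzb <- .b64_doubles(s$mz)
  inb <- .b64_doubles(s$intensity)
  half <- if (is.na(s$isolation_window)) 0.5 else s$isolation_window / 2
  prec <- if (is.na(s$precursor_mz)) 0 else s$precursor_mz
  ce <- if (is.na(s$collision_energy)) 0 else s$collision_energy
  paste0(
    sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">\n',
            idx, idx + 1L, n),
    '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="2"/>\n',
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>\n',
    '<scanList count="1"><scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="',
    idx + 1L, '" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/></scan></scanList>\n',
    '<precursorList count="1"><precursor><isolationWindow>',
    sprintf('<cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="%.6f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>', prec),
    sprintf('<cvParam cvRef="MS" accession="MS:1000828" name="isolation window lower offset" value="%.4f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>', half),
    sprintf('<cvParam cvRef="MS" accession="MS:1000829" name="isolation window upper offset" value="%.4f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>', half),
    '</isolationWindow><selectedIonList count="1"><selectedIon>',
    sprintf('<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.6f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>', prec),
    '</selectedIon></selectedIonList><activation>',
    '<cvParam cvRef="MS" accession="MS:1000133" name="collision-induced dissociation" value=""/>',
    sprintf('<cvParam cvRef="MS" accession="MS:1000045" name="collision energy" value="%.2f" unitCvRef="UO" unitAccession="UO:0000266" unitName="electronvolt"/>', ce),
    '</activation></precursor></precursorList>\n',
    '<binaryDataArrayList count="2">\n',
    sprintf('<binaryDataArray encodedLength="%d">', nchar(mzb)),
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '<binary>', mzb, '</binary></binaryDataArray>\n',
    sprintf('<binaryDataArray encodedLength="%d">', nchar(inb)),
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '<binary>', inb, '</binary></binaryDataArray>\n',
    '</binaryDataArrayList></spectrum>')
}

#' Write centroid MS2 spectra to a minimal mzML file
#'
#' A deliberately small writer (one run, centroid MS2 scans, uncompressed
#' 64-bit arrays) sufficient for round-trip testing against [read_mzml()].
#'
#' @param spectra List of [ms2_spectrum] objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path) {
  if (inherits(spectra, "ms2_spectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1)
  body <- paste(vapply(seq_along(spectra), function(i)
    .mzml_spectrum_xml(i - 1L, spectra[[i]]), character(1)),
    collapse = "\n")
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="2">\n',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>\n',
    '<cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>\n',
    '</cvList>\n',
    '<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/></fileContent></fileDescription>\n',
    '<softwareList count="1"><software id="sw" version="0.1"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="derivmz"/></software></softwareList>\n',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>\n',
    sprintf('<run id="run1" defaultInstrumentConfigurationRef="IC1">\n<spectrumList count="%d" defaultDataProcessingRef="dp">\n',
            length(spectra)),
    body,
    '\n</spectrumList></run></mzML>\n')
  writeLines(doc, path, useBytes = TRUE)
  invisible(path)
}

#' Bin a spectrum onto a fixed-width m/z grid
#'
#' Bins have origin 0 and left-closed floor indexing
#' (`index = floor(m/z / bin_size)`); intensities of peaks sharing a bin
#' are summed; peaks above `max_mz` are dropped before binning.  The bin
#' size sets the resolution of spectral comparison; the maximum m/z is
#' typically set slightly above the precursor ion's m/z, and with no limit
#' the whole spectrum is used.
#'
#' @param s An [ms2_spectrum].
#' @param bin_size Bin width in Da (> 0).
#' @param max_mz Optional upper m/z cutoff (Da); `NULL` = unbounded.
#' @return A `binned_spectrum`: sparse vector of per-bin intensities with
#'   fields `index` (0-based bin indices), `intensity`, `bin_size`,
#'   `max_mz`, and `length` (conceptual dense length).
#' @export
bin_spectrum <- function(s, bin_size, max_mz = NULL) {
  stopifnot(inherits(s, "ms2_spectrum"))
  if (bin_size <= 0) stop("bin_size must be positive")
  keep <- if (is.null(max_mz)) rep(TRUE, length(s$mz)) else s$mz <= max_mz
  mz <- s$mz[keep]; inten <- s$intensity[keep]
  if (!length(mz)) {
    return(structure(list(index = integer(), intensity = numeric(),
                          bin_size = bin_size, max_mz = max_mz,
                          length = 0L),
                     class = "binned_spectrum"))
  }
  idx <- floor(mz / bin_size)
  agg <- rowsum(inten, idx)
  structure(list(index = as.numeric(rownames(agg)),
                 intensity = as.numeric(agg),
                 bin_size = bin_size, max_mz = max_mz,
                 length = floor((if (is.null(max_mz)) max(mz) else max_mz) /
                                  bin_size) + 1),
            class = "binned_spectrum")
}

#' @export
print.binned_spectrum <- function(x, ...) {
  cat(sprintf("<binned_spectrum: %d occupied bins of %g Da%s>\n",
              length(x$index), x$bin_size,
              if (!is.null(x$max_mz)) sprintf(", max m/z %g", x$max_mz)
              else ""))
  invisible(x)
}

#' Cosine similarity of two binned spectra
#'
#' The normalized dot product of the binned intensity vectors: 1 indicates
#' perfect spectral alignment, 0 no shared signal.  Symmetric and invariant
#' under global intensity scaling; both spectra must be binned with the
#' same bin size.
#'
#' @param x,y `binned_spectrum` objects (or [ms2_spectrum]s, binned with
#'   `bin_size`/`max_mz`).
#' @param bin_size,max_mz Used only when `x`/`y` are raw spectra.
#' @return Cosine score in [0, 1] for non-negative spectra.
#' @export
cosine_similarity <- function(x, y, bin_size = 0.01, max_mz = NULL) {
  if (inherits(x, "ms2_spectrum")) x <- bin_spectrum(x, bin_size, max_mz)
  if (inherits(y, "ms2_spectrum")) y <- bin_spectrum(y, bin_size, max_mz)
  stopifnot(inherits(x, "binned_spectrum"), inherits(y, "binned_spectrum"))
  if (!isTRUE(all.equal(x$bin_size, y$bin_size)))
    stop("spectra binned with different bin sizes (",
         x$bin_size, " vs ", y$bin_size, ")")
  nx <- sqrt(sum(x$intensity^2)); ny <- sqrt(sum(y$intensity^2))
  if (nx == 0 || ny == 0)
    stop("cosine similarity undefined for an all-zero spectrum")
  common <- intersect(x$index, y$index)
  if (!length(common)) return(0)
  dot <- sum(x$intensity[match(common, x$index)] *
               y$intensity[match(common, y$index)])
  dot / (nx * ny)
}

#' Search a reference spectral library
#'
#' Bins query and every reference identically, scores each reference by
#' cosine similarity, and ranks hits by descending score with a
#' deterministic tie-break on reference id.
#'
#' @param query An [ms2_spectrum].
#' @param library Named list of reference [ms2_spectrum]s (e.g.
#'   `db$spectra`), or an `annotation_db`.
#' @param bin_size Bin width in Da (default 0.01).
#' @param max_mz Optional upper m/z cutoff applied to both sides.
#' @return Data frame of class `library_hits` with columns `id`, `name`,
#'   `label`, `collision_energy`, `score`, `rank` (1 = best).
#' @export
search_library <- function(query, library, bin_size = 0.01, max_mz = NULL) {
  if (inherits(library, "annotation_db")) library <- library$spectra
  if (!length(library)) stop("reference library is empty")
  if (is.null(names(library)) || any(!nzchar(names(library))))
    names(library) <- vapply(seq_along(library), function(i)
      library[[i]]$metadata$id %||% sprintf("spec%03d", i), character(1))
  qb <- bin_spectrum(query, bin_size, max_mz)
  scores <- vapply(library, function(ref)
    cosine_similarity(qb, bin_spectrum(ref, bin_size, max_mz)), numeric(1))
  ord <- order(-scores, names(library))
  out <- data.frame(
    id = names(library)[ord],
    name = vapply(library[ord], function(s)
      s$metadata$name %||% NA_character_, character(1)),
    label = vapply(library[ord], function(s)
      s$metadata$label %||% NA_character_, character(1)),
    collision_energy = vapply(library[ord], function(s)
      s$collision_energy %||% NA_real_, numeric(1)),
    score = unname(scores[ord]),
    rank = seq_along(ord),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("library_hits", "data.frame")
  out
}

#' Export a mirrored query/reference spectrum pair as csv
#'
#' Rows are (mz, intensity, source) with reference intensities negated so
#' the table plots directly as a mirror; [read_mirror()] reconstructs both
#' spectra exactly.
#'
#' @param query,reference [ms2_spectrum] objects (both nonempty).
#' @param path Output csv path.
#' @return `path`, invisibly.
#' @export
export_mirror <- function(query, reference, path) {
  stopifnot(inherits(query, "ms2_spectrum"),
            inherits(reference, "ms2_spectrum"))
  tab <- rbind(
    data.frame(mz = query$mz, intensity = query$intensity,
               source = "query"),
    data.frame(mz = reference$mz, intensity = -reference$intensity,
               source = "reference"))
  utils::write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Re-import a mirror csv written by [export_mirror()]
#'
#' @param path Mirror csv path.
#' @return List with elements `query` and `reference` ([ms2_spectrum]s).
#' @export
read_mirror <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  q <- tab[tab$source == "query", ]
  r <- tab[tab$source == "reference", ]
  list(query = ms2_spectrum(q$mz, q$intensity),
       reference = ms2_spectrum(r$mz, -r$intensity))
}

#' Class-diagnostic MS2 product ions of a derivatizing matrix
#'
#' Under CID, a derivatized metabolite releases the tag fragment still
#' bound to a class-specific neutral: for FMP-10, tag + H2O marks phenolic
#' hydroxyl derivatization (m/z 286.122641) and tag + NH3 marks primary
#' amine derivatization (m/z 285.138625).
#'
#' @param matrix A [deriv_matrix] with configured `diagnostic_adducts`.
#' @return Named numeric vector, pattern name to product-ion m/z.
#' @export
diagnostic_ions <- function(matrix) {
  stopifnot(inherits(matrix, "deriv_matrix"))
  if (is.null(matrix$diagnostic_adducts) ||
      !length(matrix$diagnostic_adducts))
    stop("matrix '", matrix$name,
         "' has no configured diagnostic fragment adducts")
  frag <- matrix$reagent - matrix$leaving_group  # tag fragment cation
  vapply(matrix$diagnostic_adducts,
         function(nl) monoisotopic_mz(frag + nl), numeric(1))
}

#' Flag which functional classes a query MS2 spectrum exhibits
#'
#' A class is flagged when the spectrum contains a peak within `tol` ppm of
#' the matrix's diagnostic product ion for that class.
#'
#' @param spectrum An [ms2_spectrum].
#' @param matrix A [deriv_matrix] with diagnostic ions configured.
#' @param tol Tolerance in ppm (default 5).
#' @return Named logical vector over the matrix's diagnostic classes.
#' @export
flag_diagnostic_ions <- function(spectrum, matrix, tol = 5) {
  ions <- diagnostic_ions(matrix)
  vapply(ions, function(mz)
    any(abs(ppm_error(spectrum$mz, mz)) <= tol), logical(1))
}
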