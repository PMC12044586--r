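# MS1 feature annotation: ppm-window matching of experimental feature lists
# against the sorted candidate index (Step 2 of the two-step query).

#' Read an MS1 feature list
#'
#' `.txt` files hold one numeric m/z per line.  Delimited files (`.csv` and
#' friends) are sniffed for comma/semicolon/tab; the m/z column is the first
#' whose header matches `m/z`, `mz`, `m.z`, ... case-insensitively, else the
#' first numeric column.  All other columns (intensity, area, ...) are
#' carried through untouched.
#'
#' @param path Input file path.
#' @return Data frame with column `mz` first, extras after; attribute
#'   `"source"` records the path.  Input row order is preserved.
#' @export
read_feature_list <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "txt") {
    vals <- scan(path, what = numeric(), quiet = TRUE, comment.char = "#")
    out <- data.frame(mz = vals)
  } else {
    header <- readLines(path, n = 1L, encoding = "UTF-8")
    sep <- c(",", ";", "\t")[which.max(vapply(
      c(",", ";", "\t"),
      function(s) lengths(gregexpr(s, header, fixed = TRUE)), numeric(1)))]
    df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                            stringsAsFactors = FALSE, comment.char = "",
                            encoding = "UTF-8", check.names = FALSE)
    hit <- grep("^m[./]?z$", names(df), ignore.case = TRUE)
    if (!length(hit)) hit <- which(vapply(df, is.numeric, logical(1)))
    if (!length(hit))
      stop("no m/z column found in ", path)
    col <- hit[1]
    out <- cbind(data.frame(mz = as.numeric(df[[col]])),
                 df[, setdiff(names(df), names(df)[col]), drop = FALSE])
  }
  if (any(!is.finite(out$mz) | out$mz <= 0))
    stop("feature list ", path, " contains non-positive or missing m/z")
  attr(out, "source") <- path
  out
}

#' Inclusive bounds of a multiplicative ppm window
#'
#' @param query Query m/z.
#' @param tol Tolerance in ppm (> 0).
#' @return Numeric length-2: `query * (1 - tol*1e-6)` and
#'   `query * (1 + tol*1e-6)`.
#' @export
window_bounds <- function(query, tol) {
  if (tol < 0) stop("ppm tolerance must be non-negative")
  c(query * (1 - tol * 1e-6), query * (1 + tol * 1e-6))
}

#' Index range of sorted values inside a window (bisection)
#'
#' Binary search for the half-open index range `[i, j)` of entries with
#' `low <= x <= high` in an ascending vector; O(log n), equivalent to a
#' linear scan on any input.
#'
#' @param sorted_mz Ascending numeric vector.
#' @param low,high Inclusive window bounds.
#' @return Integer length-2 `c(i, j)`; empty range has `i == j`.
#' @export
bisect_range <- function(sorted_mz, low, high) {
  n <- length(sorted_mz)
  if (n == 0L || low > high) return(c(1L, 1L))
  # first index with value >= low
  lo <- 1L; hi <- n + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (sorted_mz[mid] < low) lo <- mid + 1L else hi <- mid
  }
  i <- lo
  # first index with value > high
  lo <- i; hi <- n + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (sorted_mz[mid] <= high) lo <- mid + 1L else hi <- mid
  }
  c(i, lo)
}

#' Annotate an MS1 feature list against the database
#'
#' Runs the two-step query: Step 1 selects candidate rows via
#' [filter_candidates()]; Step 2 iterates over the query m/z values and,
#' using bisection on the sorted index, keeps every candidate within the
#' ppm window.  Every match is reported (no arbitrary best-pick); matches
#' are sorted by |delta ppm| then metabolite id.
#'
#' @param features Data frame from [read_feature_list()], or a numeric
#'   vector of m/z values.
#' @param db An `annotation_db`.
#' @param matrix,adducts,endogeneity,tissues,mz_range Passed to
#'   [filter_candidates()].
#' @param tol Tolerance in ppm (default 2).
#' @param exclude Optional numeric vector of matrix/reagent peaks to
#'   exclude: features matching one within `tol` are reported unannotated.
#' @return An `annotation_set`: list with `features` (input order
#'   preserved), `matches` (long data frame keyed by `feature` row index),
#'   `tol`, and per-run summary counts.
#' @export
annotate_features <- function(features, db, matrix = NULL, adducts = NULL,
                              tol = 2, endogeneity = NULL, tissues = NULL,
                              mz_range = c(0, Inf), exclude = NULL) {
  if (is.numeric(features)) features <- data.frame(mz = features)
  stopifnot(is.data.frame(features), "mz" %in% names(features))
  if (!nrow(features)) warning("empty feature list")
  cand <- filter_candidates(db, matrix = matrix, adducts = adducts,
                            endogeneity = endogeneity, tissues = tissues,
                            mz_range = mz_range)
  meta_name <- stats::setNames(db$metabolites$name, db$metabolites$id)
  rows <- list()
  for (k in seq_len(nrow(features))) {
    q <- features$mz[k]
    if (!is.null(exclude) &&
        any(abs(ppm_error(q, exclude)) <= tol)) next
    w <- window_bounds(q, tol)
    r <- bisect_range(cand$mz, w[1], w[2])
    if (r[2] > r[1]) {
      hit <- cand[seq(r[1], r[2] - 1L), , drop = FALSE]
      d <- ppm_error(q, hit$mz)
      ord <- order(abs(d), hit$metabolite_id, hit$form)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = k, query_mz = q,
        metabolite_id = hit$metabolite_id[ord],
        name = unname(meta_name[hit$metabolite_id[ord]]),
        form = hit$form[ord], source = hit$source[ord],
        theoretical_mz = hit$mz[ord], delta_ppm = d[ord],
        stringsAsFactors = FALSE)
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows)
  else data.frame(feature = integer(), query_mz = numeric(),
                  metabolite_id = character(), name = character(),
                  form = character(), source = character(),
                  theoretical_mz = numeric(), delta_ppm = numeric())
  rownames(matches) <- NULL
  n_ann <- length(unique(matches$feature))
  structure(list(features = features, matches = matches, tol = tol,
                 n_features = nrow(features), n_annotated = n_ann,
                 fraction_annotated = if (nrow(features))
                   n_ann / nrow(features) else NA_real_),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set: %d/%d features annotated (%.1f%%) at %.3g ppm, %d candidate matches>\n",
    x$n_annotated, x$n_features, 100 * x$fraction_annotated, x$tol,
    nrow(x$matches)))
  invisible(x)
}

#' @export
summary.annotation_set <- function(object, ...) {
  m <- object$matches
  data.frame(features = object$n_features,
             annotated = object$n_annotated,
             fraction = object$fraction_annotated,
             matches = nrow(m),
             mean_abs_ppm = if (nrow(m)) mean(abs(m$delta_ppm)) else NA_real_)
}

#' Export annotations as csv
#'
#' One row per (feature, match); `full-table` mode also emits unannotated
#' features with empty match columns.  Output is RFC-4180 csv, UTF-8, "."
#' decimal separator regardless of locale.
#'
#' @param results An `annotation_set`.
#' @param path Output path.
#' @param mode `"annotated-only"` (default) or `"full-table"`.
#' @param adjusted_mz Optional numeric vector (one per feature) of
#'   recalibrated m/z values to include as a column.
#' @return `path`, invisibly.
#' @export
export_annotations <- function(results, path,
                               mode = c("annotated-only", "full-table"),
                               adjusted_mz = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(results, "annotation_set"))
  m <- results$matches
  if (mode == "annotated-only" && !nrow(m))
    stop("no annotated features to export; use mode = 'full-table'")
  tab <- data.frame(query_mz = m$query_mz)
  if (!is.null(adjusted_mz)) tab$adjusted_mz <- adjusted_mz[m$feature]
  tab$metabolite <- m$metabolite_id
  tab$name <- m$name
  tab$form <- m$form
  tab$theoretical_mz <- m$theoretical_mz
  tab$delta_ppm <- m$delta_ppm
  if (mode == "full-table") {
    un <- setdiff(seq_len(nrow(results$features)), m$feature)
    if (length(un)) {
      extra <- data.frame(query_mz = results$features$mz[un])
      if (!is.null(adjusted_mz)) extra$adjusted_mz <- adjusted_mz[un]
      extra$metabolite <- ""; extra$name <- ""; extra$form <- ""
      extra$theoretical_mz <- NA_real_; extra$delta_ppm <- NA_real_
      ord_key <- c(m$feature, un)
      tab <- rbind(tab, extra)
      tab <- tab[order(ord_key, seq_along(ord_key)), , drop = FALSE]
    }
  }
  old <- Sys.getlocale("LC_NUMERIC")
  on.exit(suppressWarnings(Sys.setlocale("LC_NUMERIC", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_NUMERIC", "C"))
  utils::write.csv(tab, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}
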