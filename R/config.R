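# Configuration: matrices, adducts and pattern sets are defined in a YAML
# file so users can add their own without code changes.

#' Path of the packaged default configuration
#'
#' @return File path of the YAML configuration shipped with the package.
#' @export
default_config_path <- function() {
  system.file("extdata", "config.yaml", package = "derivmz",
              mustWork = TRUE)
}

#' Read a run configuration file
#'
#' @param path YAML configuration path (default: the packaged file).
#' @return List of class `run_config` with components `defaults`,
#'   `patterns` (named [functional_group] list), `matrices` (named
#'   [deriv_matrix] list), `adducts` (named adduct list), and
#'   `exclude_peaks`.
#' @export
read_config <- function(path = default_config_path()) {
  raw <- yaml::read_yaml(path)
  patterns <- lapply(names(raw$patterns), function(nm) {
    p <- raw$patterns[[nm]]
    functional_group(nm, p$query,
                     exclusions = unlist(p$exclusions) %||% character())
  })
  names(patterns) <- names(raw$patterns)
  matrices <- lapply(names(raw$matrices), function(nm) {
    m <- raw$matrices[[nm]]
    deriv_matrix(
      name = nm,
      reagent = parse_formula(m$reagent, charge = 1L),
      leaving_group = if (!is.null(m$leaving_group) &&
                          nzchar(m$leaving_group))
        parse_formula(m$leaving_group) else composition(),
      target_patterns = unlist(m$target_patterns),
      losses = lapply(m$losses, parse_formula, charge = 1L),
      max_tags = if (is.null(m$max_tags) ||
                     identical(m$max_tags, "all")) Inf else m$max_tags,
      diagnostic_adducts = if (!is.null(m$diagnostic_adducts))
        lapply(m$diagnostic_adducts, parse_formula))
  })
  names(matrices) <- names(raw$matrices)
  adducts <- lapply(names(raw$adducts), function(nm) {
    a <- raw$adducts[[nm]]
    adduct(nm, add = a$add %||% "", remove = a$remove %||% "",
           charge = a$charge)
  })
  names(adducts) <- names(raw$adducts)
  structure(list(defaults = raw$defaults, patterns = patterns,
                 matrices = matrices, adducts = adducts,
                 exclude_peaks = as.numeric(unlist(raw$exclude_peaks))),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config: %d matrices (%s), %d adducts, %d patterns, ppm %.3g, bin %.3g>\n",
              length(x$matrices), paste(names(x$matrices), collapse = ", "),
              length(x$adducts), length(x$patterns),
              x$defaults$ppm %||% 2, x$defaults$bin_size %||% 0.01))
  invisible(x)
}
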