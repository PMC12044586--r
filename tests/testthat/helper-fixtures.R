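# Shared fixture objects, built once per test run.

fig3_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) db <<- build_database(fig_isomer_panel())
    db
  }
})

standards_db <- local({
  db <- NULL
  function() {
    if (is.null(db))
      db <<- build_database(standards_panel(),
                            adducts = default_adducts("positive"))
    db
  }
})

dopamine_mass <- function() monoisotopic_mz(parse_formula("C8H11NO2"))

# independent m/z oracle: plain sum over a hand-expanded atom list
oracle_mass <- function(elements, charge = 0) {
  m <- isotope_masses()
  sum(m[elements]) - charge * electron_mass()
}
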