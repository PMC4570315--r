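#' Taste-related chemicals tracked by the pipeline
#'
#' The eleven analytes quantified per wine sample: three sugars, seven
#' organic acids, and total tannin (tannic-acid equivalents). All
#' concentrations are in mg/L.
#'
#' @format Character vector of length 11.
#' @export
wine_chemicals <- c(
  "sucrose", "glucose", "fructose",
  "citric", "malic", "tartaric", "succinic", "lactic", "acetic", "formic",
  "tannin"
)

#' @rdname wine_chemicals
#' @export
wine_sugars <- c("sucrose", "glucose", "fructose")

#' @rdname wine_chemicals
#' @export
wine_acids <- c("citric", "malic", "tartaric", "succinic", "lactic",
                "acetic", "formic")

#' Molar masses of the wine organic acids
#'
#' Standard molar masses (g/mol) used to convert acid concentrations from
#' mg/L to mmol/L for the sourness score.
#'
#' @format Named numeric vector, g/mol.
#' @export
acid_molar_masses <- c(
  citric   = 192.12,
  malic    = 134.09,
  tartaric = 150.09,
  succinic = 118.09,
  lactic   = 90.08,
  acetic   = 60.05,
  formic   = 46.03
)

# Observed per-chemical concentration ranges (mg/L) across the 23-wine panel;
# zero minima are floored at a small positive value for log-scale sampling.
chem_ranges <- function() {
  rbind(
    sucrose  = c(32, 4232),
    glucose  = c(95, 31005),
    fructose = c(376, 64258),
    citric   = c(0, 253),
    malic    = c(311, 46291),
    tartaric = c(996, 21191),
    succinic = c(101, 4588),
    lactic   = c(0, 1318),
    acetic   = c(75, 272),
    formic   = c(96, 1855),
    tannin   = c(72, 573)
  )
}

# Per-cluster score bands: sweet wines vs dry wines, as observed on the
# 23-wine panel (sweetness in weighted mg/L, sourness in mmol/L).
score_bands <- function() {
  list(
    sweet = list(sweetness = c(46800, 123019), sourness = c(220, 478)),
    dry   = list(sweetness = c(1029, 19705),   sourness = c(36, 100))
  )
}
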