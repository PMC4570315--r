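#' Weighted sweetness score
#'
#' Sweetness is the sugar content weighted by relative perceived sweetness:
#' \deqn{0.75 \cdot glucose + 1 \cdot sucrose + 1.5 \cdot fructose}
#' with all concentrations in mg/L.
#'
#' @param profile Named concentration vector (mg/L) or one-row
#'   \code{chem_panel}; must contain the three sugars.
#' @return Sweetness score (weighted mg/L equivalents), >= 0.
#' @examples
#' sweetness(c(glucose = 1000, sucrose = 1000, fructose = 1000))  # 3250
#' @export
sweetness <- function(profile) {
  conc <- as_conc_vector(profile)
  missing <- setdiff(wine_sugars, names(conc))
  if (length(missing))
    stop_invalid("profile lacks sugar(s): ", paste(missing, collapse = ", "))
  0.75 * conc$glucose + 1.0 * conc$sucrose + 1.5 * conc$fructose
}

#' Molar sourness score
#'
#' Sourness sums the organic acid concentrations each divided by its molar
#' mass, i.e. total acid molarity in mmol/L (mg/L divided by g/mol). Sugars
#' and tannin are excluded. Formic acid is included by default; set
#' \code{include_formic = FALSE} to restrict the sum to the six acids
#' citric, malic, tartaric, succinic, lactic and acetic.
#'
#' @param profile Named concentration vector (mg/L) or one-row
#'   \code{chem_panel}.
#' @param molar_masses Named vector of molar masses (g/mol); defaults to
#'   \code{\link{acid_molar_masses}}.
#' @param include_formic Include formic acid in the sum?
#' @return Sourness in mmol/L.
#' @examples
#' sourness(c(malic = 1340.9))  # 10
#' @export
sourness <- function(profile, molar_masses = acid_molar_masses,
                     include_formic = TRUE) {
  conc <- as_conc_vector(profile)
  acids <- intersect(names(conc), wine_acids)
  if (!include_formic) acids <- setdiff(acids, "formic")
  no_mass <- setdiff(acids, names(molar_masses))
  if (length(no_mass))
    stop_invalid("no molar mass supplied for acid(s): ",
                 paste(no_mass, collapse = ", "))
  if (any(molar_masses[acids] <= 0))
    stop_invalid("molar masses must be > 0")
  sum(vapply(acids, function(a) conc[[a]] / molar_masses[[a]], numeric(1)))
}

#' Fit a tannic-acid standard curve
#'
#' Converts transmittance readings at 410 nm to absorbance
#' \eqn{A = -\log_{10}(T)} and fits a least-squares line of absorbance
#' against tannic-acid concentration (ppm). The fitted curve calibrates the
#' Folin-Ciocalteu astringency assay.
#'
#' @param points Data.frame (or list) with columns/elements \code{ppm} and
#'   \code{transmittance}; >= 2 distinct concentrations, transmittance in
#'   (0, 1].
#' @return Object of class \code{tannin_curve}: \code{slope},
#'   \code{intercept}, \code{r_squared}, and the calibration points.
#' @export
fit_tannin_curve <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("ppm", "transmittance") %in% names(points)))
    stop_invalid("`points` needs columns ppm and transmittance")
  if (length(unique(points$ppm)) < 2)
    stop_invalid("need >= 2 distinct calibration concentrations")
  if (any(points$transmittance <= 0 | points$transmittance > 1))
    stop_invalid("transmittance must lie in (0, 1]")
  A <- -log10(points$transmittance)
  fit <- stats::lm(A ~ ppm, data = data.frame(ppm = points$ppm, A = A))
  sst <- sum((A - mean(A))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 points = data.frame(ppm = points$ppm,
                                     transmittance = points$transmittance,
                                     absorbance = A)),
            class = "tannin_curve")
}

#' @export
print.tannin_curve <- function(x, ...) {
  cat(sprintf(
    "Tannic-acid standard curve: A = %.5f * ppm + %.5f (R^2 = %.4f, %d points)\n",
    x$slope, x$intercept, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Astringency from a transmittance reading
#'
#' Inverts the tannic-acid standard curve: the reading's absorbance
#' \eqn{-\log_{10}(T)} is mapped to ppm tannic acid and multiplied by the
#' sample dilution factor (wine is assayed 100-fold diluted). Negative
#' inversions clamp to zero with a warning.
#'
#' @param transmittance Reading in (0, 1].
#' @param curve A \code{\link{tannin_curve}}.
#' @param dilution_factor Sample dilution before the assay; >= 1.
#' @return Astringency in mg/L tannic-acid equivalents.
#' @export
astringency <- function(transmittance, curve, dilution_factor = 100) {
  if (!inherits(curve, "tannin_curve")) stop_invalid("`curve` must be a tannin_curve")
  if (curve$slope == 0) stop_invalid("zero-slope curve is not invertible")
  if (dilution_factor < 1) stop_invalid("`dilution_factor` must be >= 1")
  if (any(transmittance <= 0 | transmittance > 1))
    stop_invalid("transmittance must lie in (0, 1]")
  ppm <- (-log10(transmittance) - curve$intercept) / curve$slope
  if (any(ppm < 0)) {
    warning("negative curve inversion clamped to 0", call. = FALSE)
    ppm <- pmax(ppm, 0)
  }
  ppm * dilution_factor
}

#' Taste scores for a panel of samples
#'
#' Computes sweetness, sourness and astringency for every sample of a
#' chemical panel. Astringency is taken directly as the tannin
#' concentration (tannic-acid equivalents, mg/L); the transmittance-based
#' route is available through \code{\link{fit_tannin_curve}} and
#' \code{\link{astringency}} for assay data.
#'
#' @param panel A \code{chem_panel} data.frame.
#' @param include_formic Passed to \code{\link{sourness}}.
#' @return Data.frame with columns \code{sample_id}, \code{sweetness},
#'   \code{sourness}, \code{astringency}.
#' @export
taste_scores <- function(panel, include_formic = TRUE) {
  data.frame(
    sample_id = panel$sample_id,
    sweetness = vapply(seq_len(nrow(panel)),
                       function(i) sweetness(profile_conc(panel, i)), numeric(1)),
    sourness = vapply(seq_len(nrow(panel)),
                      function(i) sourness(profile_conc(panel, i),
                                           include_formic = include_formic),
                      numeric(1)),
    astringency = panel$tannin,
    stringsAsFactors = FALSE
  )
}
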