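#' Dye names of the standard eight-well sensor array
#' @export
dye_names <- c("alizarin", "calconcarboxylic", "cresol_red", "crystal_violet",
               "fluorescein", "methylthymol_blue", "phenol_red", "xylenol_orange")

#' Construct a dye response model
#'
#' A \code{dye_model} describes how each of the eight dye-bead conjugates in
#' the sensor array responds to the taste chemicals. Colour change follows a
#' saturating (Langmuir-form) dose response: the contribution of chemical
#' \eqn{c} at concentration \eqn{x} to channel \eqn{ch} of dye \eqn{d} is
#' \deqn{sensitivity[d, ch, c] \cdot x / (x + K_c)}
#' where \eqn{K_c} is the chemical's half-saturation concentration. Each dye
#' also carries a set of Gaussian absorbance peaks for the spectral model.
#'
#' @param baseline_rgb 8x3 matrix of baseline well colours, 0-255.
#' @param sensitivity 3-d array \code{[dye, channel, chemical]} of signed
#'   maximal colour changes (RGB counts at full saturation).
#' @param half_saturation Named vector, mg/L, one per chemical; > 0.
#' @param peaks Named list (per dye) of data.frames with columns
#'   \code{center}, \code{width} (nm) and \code{height}, plus a
#'   \code{chemical_gain} matrix \code{[peak, chemical]} used by
#'   \code{\link{simulate_spectrum}}.
#' @return An object of class \code{dye_model}.
#' @seealso \code{\link{default_dye_model}}
#' @export
dye_model <- function(baseline_rgb, sensitivity, half_saturation, peaks) {
  stopifnot(is.matrix(baseline_rgb), ncol(baseline_rgb) == 3,
            length(dim(sensitivity)) == 3)
  if (any(baseline_rgb < 0 | baseline_rgb > 255))
    stop_invalid("baseline_rgb must lie in [0, 255]")
  if (any(half_saturation <= 0))
    stop_invalid("half_saturation must be > 0 for every chemical")
  rows <- apply(sensitivity, 1, paste, collapse = ",")
  if (anyDuplicated(rows))
    stop_invalid("two dyes share an identical sensitivity pattern")
  structure(list(baseline_rgb = baseline_rgb, sensitivity = sensitivity,
                 half_saturation = half_saturation, peaks = peaks),
            class = "dye_model")
}

#' Default eight-dye response model
#'
#' A fixed, reproducible dye model for the standard array: plausible baseline
#' dye colours, a deterministic signed sensitivity pattern in which each dye
#' responds appreciably to a different subset of chemicals (no two dyes share
#' a response pattern), half-saturation constants at the top of each
#' chemical's observed concentration range — so the dyes operate below
#' half-saturation across wine-relevant concentrations, mirroring the
#' near-linear absorbance-versus-concentration responses observed for the
#' real dye-bead conjugates — and two to three Gaussian absorbance peaks
#' per dye in the 400-780 nm window.
#'
#' @return A \code{\link{dye_model}}.
#' @export
default_dye_model <- function() {
  rng <- chem_ranges()
  half_sat <- setNames(rng[, 2], rownames(rng))

  baseline <- matrix(c(
    185,  95,  75,   # alizarin: orange-red
     80,  90, 165,   # calconcarboxylic: blue
    170,  75,  85,   # cresol red
    100,  70, 150,   # crystal violet
    165, 185,  75,   # fluorescein: yellow-green
     75, 120, 170,   # methylthymol blue
    180, 120,  85,   # phenol red
    185, 140,  70    # xylenol orange
  ), nrow = 8, byrow = TRUE,
  dimnames = list(dye_names, c("R", "G", "B")))

  nd <- length(dye_names); nch <- length(wine_chemicals)
  with_seed(48151623, {
    sens <- array(0, dim = c(nd, 3, nch),
                  dimnames = list(dye_names, c("R", "G", "B"), wine_chemicals))
    for (d in seq_len(nd)) {
      # each dye strongly senses 4-6 chemicals, weakly the rest
      strong <- sample.int(nch, sample(4:6, 1))
      for (c in seq_len(nch)) {
        amp <- if (c %in% strong) runif(1, 15, 40) else runif(1, 0, 5)
        sgn <- sample(c(-1, 1), 3, replace = TRUE)
        sens[d, , c] <- sgn * amp * runif(3, 0.5, 1)
      }
    }
    peaks <- lapply(seq_len(nd), function(d) {
      np <- sample(2:3, 1)
      pk <- data.frame(center = runif(np, 430, 740),
                       width  = runif(np, 25, 60),
                       height = runif(np, 0.4, 1.2))
      gain <- matrix(runif(np * nch, -0.6, 0.9), np, nch,
                     dimnames = list(NULL, wine_chemicals))
      list(table = pk, chemical_gain = gain)
    })
    names(peaks) <- dye_names
    dye_model(baseline, sens, half_sat, peaks)
  })
}

#' @export
print.dye_model <- function(x, ...) {
  cat("Dye response model:", nrow(x$baseline_rgb), "dyes,",
      dim(x$sensitivity)[3], "chemicals\n")
  cat("Dyes:", paste(rownames(x$baseline_rgb), collapse = ", "), "\n")
  invisible(x)
}

# Langmuir saturation term, theta in [0, 1)
langmuir <- function(conc, K) conc / (conc + K)

#' Simulate the colour response of the array to one sample
#'
#' Computes the ground-truth 8x3 colour-change matrix (after minus before,
#' RGB counts) for a chemical profile under the saturating dose-response
#' model, optionally with additive Gaussian measurement noise.
#'
#' @param profile Named concentration vector (mg/L) or one-row
#'   \code{chem_panel}.
#' @param model A \code{\link{dye_model}}.
#' @param noise_sd Standard deviation of additive Gaussian noise per matrix
#'   cell (RGB counts); >= 0.
#' @param seed Integer seed for the noise draw.
#' @return 8x3 numeric matrix (dyes x RGB).
#' @export
simulate_color_response <- function(profile, model, noise_sd = 0, seed = 1) {
  if (!inherits(model, "dye_model")) stop_invalid("`model` must be a dye_model")
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  conc <- as_conc_vector(profile)
  unknown <- setdiff(names(conc), dimnames(model$sensitivity)[[3]])
  if (length(unknown))
    stop_invalid("unknown chemical in profile: ", paste(unknown, collapse = ", "))

  theta <- langmuir(unlist(conc), model$half_saturation[names(conc)])
  nd <- dim(model$sensitivity)[1]
  delta <- matrix(0, nd, 3, dimnames = dimnames(model$sensitivity)[1:2])
  for (ch in names(conc))
    delta <- delta + model$sensitivity[, , ch] * theta[[ch]]
  if (noise_sd > 0)
    delta <- delta + with_seed(seed, matrix(rnorm(nd * 3, 0, noise_sd), nd, 3))
  delta
}

as_conc_vector <- function(profile) {
  if (inherits(profile, "chem_panel") || is.data.frame(profile)) {
    if (nrow(profile) != 1) stop_invalid("`profile` must be a single sample")
    profile <- profile_conc(profile, 1)
  }
  if (is.null(names(profile))) stop_invalid("`profile` must be named by chemical")
  if (any(profile < 0)) stop_invalid("concentrations must be >= 0")
  as.list(profile)
}

#' Simulate a dye-bead absorbance spectrum
#'
#' Absorbance spectrum (400-780 nm, 1 nm steps) of one dye-bead conjugate
#' mixed with a single taste chemical. Each Gaussian peak's height is
#' modulated monotonically with concentration through the same Langmuir
#' saturation term used for the colour response; absorbance is floored at
#' zero.
#'
#' @param dye Dye name (one of \code{\link{dye_names}}).
#' @param chemical Chemical name.
#' @param conc Concentration in mg/L; >= 0.
#' @param model A \code{\link{dye_model}}.
#' @return Named numeric vector of absorbance at 400:780 nm.
#' @export
simulate_spectrum <- function(dye, chemical, conc, model = default_dye_model()) {
  if (!dye %in% names(model$peaks)) stop_invalid("unknown dye: ", dye)
  if (!chemical %in% names(model$half_saturation))
    stop_invalid("unknown chemical: ", chemical)
  if (conc < 0) stop_invalid("`conc` must be >= 0")
  pk <- model$peaks[[dye]]
  theta <- langmuir(conc, model$half_saturation[[chemical]])
  wl <- 400:780
  spec <- numeric(length(wl))
  for (p in seq_len(nrow(pk$table))) {
    h <- pk$table$height[p] * max(0, 1 + pk$chemical_gain[p, chemical] * theta)
    spec <- spec + h * exp(-((wl - pk$table$center[p])^2) / (2 * pk$table$width[p]^2))
  }
  names(spec) <- wl
  pmax(spec, 0)
}

#' Read or write a dye model as YAML
#' @param model A \code{\link{dye_model}}.
#' @param path File path.
#' @export
write_dye_model <- function(model, path) {
  obj <- list(
    baseline_rgb = as.list(as.data.frame(t(model$baseline_rgb))),
    sensitivity = lapply(rownames(model$baseline_rgb), function(d)
      as.list(as.data.frame(model$sensitivity[d, , ]))),
    half_saturation = as.list(model$half_saturation),
    peaks = lapply(model$peaks, function(p)
      list(table = as.list(p$table),
           chemical_gain = as.list(as.data.frame(p$chemical_gain))))
  )
  names(obj$sensitivity) <- rownames(model$baseline_rgb)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_dye_model
#' @export
read_dye_model <- function(path) {
  obj <- yaml::read_yaml(path)
  dyes <- names(obj$sensitivity)
  baseline <- do.call(rbind, obj$baseline_rgb)
  dimnames(baseline) <- list(dyes, c("R", "G", "B"))
  chems <- names(obj$sensitivity[[1]])
  sens <- array(0, c(length(dyes), 3, length(chems)),
                dimnames = list(dyes, c("R", "G", "B"), chems))
  for (d in seq_along(dyes))
    for (ch in chems)
      sens[d, , ch] <- obj$sensitivity[[d]][[ch]]
  peaks <- lapply(obj$peaks, function(p) {
    gain <- do.call(cbind, p$chemical_gain)
    list(table = as.data.frame(p$table), chemical_gain = gain)
  })
  dye_model(baseline, sens, unlist(obj$half_saturation), peaks)
}
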