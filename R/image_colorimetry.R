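#' Locate the sensor wells in an array image
#'
#' Segments the approximately circular wells from the uniform background by
#' colour thresholding, labels connected components, filters them by area
#' and circularity, and returns the well regions in canonical row-major
#' order (top-to-bottom, then left-to-right).
#'
#' The background colour is estimated as the per-channel median of the
#' image border; pixels whose maximum channel deviation from it exceeds
#' \code{threshold} are foreground.
#'
#' @param image height x width x 3 array, 0-255.
#' @param n_wells Number of wells expected.
#' @param threshold Foreground threshold in RGB counts.
#' @param min_area Minimum component area (px) kept.
#' @param min_fill Minimum fill fraction (component area over its bounding
#'   circle) for an accepted, roughly circular component.
#' @return Data.frame with one row per well: \code{x}, \code{y} (centre)
#'   and \code{radius}, in row-major order.
#' @export
detect_wells <- function(image, n_wells = 8, threshold = 25,
                         min_area = 50, min_fill = 0.6) {
  stopifnot(length(dim(image)) == 3)
  h <- dim(image)[1]; w <- dim(image)[2]
  bg <- vapply(1:3, function(k) {
    ch <- image[, , k]
    stats::median(c(ch[c(1, h), ], ch[, c(1, w)]))
  }, numeric(1))
  dev <- pmax(abs(image[, , 1] - bg[1]),
              abs(image[, , 2] - bg[2]),
              abs(image[, , 3] - bg[3]))
  mask <- dev > threshold
  labels <- EBImage::bwlabel(mask * 1)
  n_comp <- max(labels)
  found <- list()
  for (l in seq_len(n_comp)) {
    idx <- which(labels == l, arr.ind = TRUE)
    area <- nrow(idx)
    if (area < min_area) next
    cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
    # radius from area; circularity via fill of the bounding circle
    r <- sqrt(area / pi)
    span <- max(max(idx[, 1]) - min(idx[, 1]), max(idx[, 2]) - min(idx[, 2])) / 2
    fill <- area / (pi * max(span, 1)^2)
    aspect <- (max(idx[, 1]) - min(idx[, 1]) + 1) / (max(idx[, 2]) - min(idx[, 2]) + 1)
    if (fill < min_fill || aspect > 1.5 || aspect < 1 / 1.5) next
    found[[length(found) + 1]] <- c(x = cx, y = cy, radius = r)
  }
  if (length(found) != n_wells)
    stop_invalid(sprintf("well detection failed: found %d candidate regions, expected %d",
                         length(found), n_wells))
  wells <- as.data.frame(do.call(rbind, found))
  # row-major sort: group rows by y within a well radius, then sort by x
  ord <- order(wells$y, wells$x)
  wells <- wells[ord, ]
  row_id <- cumsum(c(1, diff(wells$y) > mean(wells$radius)))
  wells <- wells[order(row_id, wells$x), ]
  rownames(wells) <- NULL
  wells
}

#' Extract the 24-value colour-difference feature vector
#'
#' Averages each RGB channel over each well region in the \emph{after} and
#' \emph{before} images and returns the after-minus-before differences,
#' ordered dye-major (well 1 R, G, B, well 2 R, G, B, ...). Pixels within
#' 80\% of each well's radius are averaged to avoid edge artefacts.
#'
#' @param before,after height x width x 3 arrays, 0-255, same dimensions.
#' @param wells Data.frame of well regions (\code{x}, \code{y},
#'   \code{radius}) in canonical order, e.g. from \code{\link{detect_wells}}
#'   or an \code{array_image_pair}'s layout.
#' @param dye_order Names attached to the wells, canonical dye order.
#' @param inner_fraction Fraction of the radius averaged.
#' @return Named numeric vector of 24 values (\code{<dye>_R}, \code{<dye>_G},
#'   \code{<dye>_B} for the 8 dyes).
#' @export
extract_features <- function(before, after, wells, dye_order = dye_names,
                             inner_fraction = 0.8) {
  if (!identical(dim(before), dim(after)))
    stop_invalid("before and after images must share dimensions")
  wells <- as_wells(wells)
  h <- dim(before)[1]; w <- dim(before)[2]
  vals <- numeric(0)
  for (d in seq_len(nrow(wells))) {
    mask <- well_mask(h, w, wells$x[d], wells$y[d],
                      wells$radius[d] * inner_fraction)
    if (!any(mask)) stop_invalid("well region ", d, " contains no pixels")
    for (k in 1:3)
      vals <- c(vals, mean(after[, , k][mask]) - mean(before[, , k][mask]))
  }
  names(vals) <- paste(rep(dye_order[seq_len(nrow(wells))], each = 3),
                       c("R", "G", "B"), sep = "_")
  vals
}

as_wells <- function(wells) {
  if (is.list(wells) && !is.null(wells$centers))   # array_image_pair layout
    return(data.frame(x = wells$centers[, "x"], y = wells$centers[, "y"],
                      radius = wells$radius))
  as.data.frame(wells)
}

#' Feature matrix for a panel of image pairs
#'
#' @param pairs List of \code{array_image_pair} objects.
#' @param use_detection Detect wells from each before image
#'   (\code{TRUE}) or trust the stored layout (\code{FALSE}).
#' @return n x 24 matrix, rows named by list names.
#' @export
extract_panel_features <- function(pairs, use_detection = TRUE) {
  feats <- t(vapply(pairs, function(p) {
    wells <- if (use_detection) detect_wells(p$before) else p$layout
    extract_features(p$before, p$after, wells)
  }, numeric(3 * nrow(pairs[[1]]$layout$centers))))
  rownames(feats) <- names(pairs)
  feats
}

#' Spectral colour bands
#'
#' Wavelength intervals over which absorbance is averaged per colour
#' channel: red 620-780 nm, green 500-580 nm, blue 450-500 nm (inclusive).
#' @export
color_bands <- list(red = c(620, 780), green = c(500, 580), blue = c(450, 500))

#' Average absorbance over a wavelength band
#'
#' @param spectrum Numeric vector of absorbance named by wavelength (nm),
#'   e.g. from \code{\link{simulate_spectrum}}.
#' @param band Length-2 numeric interval (nm), inclusive bounds, or a name
#'   from \code{\link{color_bands}}.
#' @return Arithmetic mean absorbance over the band's sample points.
#' @export
band_average <- function(spectrum, band) {
  if (is.character(band)) band <- color_bands[[match.arg(band, names(color_bands))]]
  wl <- as.numeric(names(spectrum))
  if (any(is.na(wl))) stop_invalid("spectrum must be named by wavelength")
  if (band[1] < min(wl) || band[2] > max(wl))
    stop_invalid("band outside spectrum support")
  mean(spectrum[wl >= band[1] & wl <= band[2]])
}

#' Coefficient of determination of band absorbance against concentration
#'
#' Squared Pearson correlation of a simple linear fit of band-averaged
#' absorbance on analyte concentration. Zero variance in either vector is
#' defined as 0 with a warning.
#'
#' @param concs Concentrations (mg/L), >= 3 points.
#' @param band_absorbances Matching absorbance values.
#' @return R-squared in [0, 1].
#' @export
concentration_response_r2 <- function(concs, band_absorbances) {
  if (length(concs) != length(band_absorbances))
    stop_invalid("inputs must have equal length")
  if (length(concs) < 3) stop_invalid("need >= 3 paired points")
  if (stats::var(concs) == 0 || stats::var(band_absorbances) == 0) {
    warning("zero variance: R^2 defined as 0", call. = FALSE)
    return(0)
  }
  stats::cor(concs, band_absorbances)^2
}

#' Write or read a feature matrix as CSV
#' @param features n x 24 matrix with row and column names.
#' @param path File path.
#' @export
write_features <- function(features, path) {
  df <- data.frame(sample_id = rownames(features), features,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
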