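#' Default 2x4 well layout for rendered array images
#'
#' Circular wells in a 2-row by 4-column grid, row-major order (the
#' canonical dye order runs left-to-right, top-to-bottom).
#'
#' @param radius Well radius in pixels.
#' @param pitch Centre-to-centre spacing in pixels.
#' @param margin Distance from image edge to the nearest well centre.
#' @return List with \code{width}, \code{height}, \code{radius} and an 8x2
#'   matrix \code{centers} of (x, y) pixel coordinates.
#' @export
well_layout <- function(radius = 20, pitch = 60, margin = 50) {
  cx <- margin + (0:3) * pitch
  cy <- margin + (0:1) * pitch
  centers <- cbind(x = rep(cx, times = 2), y = rep(cy, each = 4))
  list(width = max(cx) + margin, height = max(cy) + margin,
       radius = radius, centers = centers)
}

#' Render a before/after sensor-array image pair
#'
#' Paints the eight wells of the array on a uniform background: the
#' \emph{before} image at each dye's baseline colour and the \emph{after}
#' image at baseline plus the supplied colour change (clipped to the 8-bit
#' channel range), then adds independent per-pixel Gaussian noise. The
#' unclipped deltas are retained as ground truth.
#'
#' @param deltas 8x3 colour-change matrix (RGB counts), e.g. from
#'   \code{\link{simulate_color_response}}.
#' @param model A \code{\link{dye_model}} supplying baseline colours.
#' @param pixel_noise_sd Per-pixel Gaussian noise sd (RGB counts); >= 0.
#' @param seed Integer seed for the pixel noise.
#' @param layout Well geometry from \code{\link{well_layout}}.
#' @param background Length-3 background colour, 0-255.
#' @return Object of class \code{array_image_pair}: \code{before} and
#'   \code{after} (height x width x 3 arrays, 0-255), \code{layout},
#'   \code{truth_delta} (pre-clip), and \code{clipped} (logical 8-vector
#'   flagging wells whose mean colour hit the channel bounds).
#' @export
render_image_pair <- function(deltas, model, pixel_noise_sd = 0, seed = 1,
                              layout = well_layout(),
                              background = c(30, 30, 30)) {
  stopifnot(is.matrix(deltas), nrow(deltas) == nrow(layout$centers),
            ncol(deltas) == 3)
  if (pixel_noise_sd < 0) stop_invalid("`pixel_noise_sd` must be >= 0")
  r <- layout$radius
  if (any(layout$centers[, "x"] - r < 1 | layout$centers[, "x"] + r > layout$width |
          layout$centers[, "y"] - r < 1 | layout$centers[, "y"] + r > layout$height))
    stop_invalid("image too small for the well layout")

  h <- layout$height; w <- layout$width
  blank <- array(rep(background, each = h * w), dim = c(h, w, 3))
  before <- after <- blank
  after_rgb <- model$baseline_rgb + deltas
  clipped <- apply(after_rgb < 0 | after_rgb > 255, 1, any)
  if (any(clipped))
    warning("colour change clipped to [0,255] in wells: ",
            paste(which(clipped), collapse = ", "), call. = FALSE)
  after_rgb <- pmin(pmax(after_rgb, 0), 255)

  for (d in seq_len(nrow(layout$centers))) {
    mask <- well_mask(h, w, layout$centers[d, "x"], layout$centers[d, "y"], r)
    for (k in 1:3) {
      pb <- before[, , k]; pb[mask] <- model$baseline_rgb[d, k]; before[, , k] <- pb
      pa <- after[, , k];  pa[mask] <- after_rgb[d, k];          after[, , k]  <- pa
    }
  }
  if (pixel_noise_sd > 0) {
    noise <- with_seed(seed, array(rnorm(2 * h * w * 3, 0, pixel_noise_sd),
                                   dim = c(h, w, 6)))
    before <- pmin(pmax(before + noise[, , 1:3], 0), 255)
    after <- pmin(pmax(after + noise[, , 4:6], 0), 255)
  }
  structure(list(before = before, after = after, layout = layout,
                 truth_delta = deltas, clipped = clipped,
                 background = background),
            class = "array_image_pair")
}

# logical h x w mask of pixels within radius r of (cx, cy); pixel centres
# at integer coordinates, x = column, y = row
well_mask <- function(h, w, cx, cy, r) {
  outer(seq_len(h), seq_len(w), function(y, x) (x - cx)^2 + (y - cy)^2 <= r^2)
}

#' @export
print.array_image_pair <- function(x, ...) {
  d <- dim(x$before)
  cat(sprintf("Sensor array image pair: %dx%d px, %d wells (radius %d px)\n",
              d[2], d[1], nrow(x$layout$centers), x$layout$radius))
  if (any(x$clipped))
    cat("Clipped wells:", paste(which(x$clipped), collapse = ", "), "\n")
  invisible(x)
}

#' Write or read an RGB raster as 8-bit PNG
#'
#' Rasters are held in memory as 0-255 double arrays; writing quantises to
#' 8 bits, so a written-then-read raster may differ from the original by up
#' to 0.5 counts per channel.
#'
#' @param img height x width x 3 array, values 0-255.
#' @param path File path.
#' @export
write_image <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE] * 255
}
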