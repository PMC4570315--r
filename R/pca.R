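#' Principal component analysis of the colour feature matrix
#'
#' Mean-centred PCA by singular value decomposition. By default no
#' unit-variance scaling is applied: the 24 colour features share units
#' (RGB counts), so centring alone is the conventional chemometric choice;
#' set \code{scale = TRUE} to autoscale. The sign of each loading column is
#' fixed so its largest-magnitude element is positive, making score plots
#' reproducible.
#'
#' @param features n x p numeric matrix (samples x features).
#' @param n_components Number of components retained; at most
#'   \code{min(n - 1, p)}.
#' @param scale Autoscale features to unit variance?
#' @return Object of class \code{color_pca}: \code{center} (mean vector),
#'   \code{loadings} (orthonormal p x k), \code{scores} (n x k),
#'   \code{explained_variance_pct} (k values) and
#'   \code{explained_variance_pct_full} (all \code{min(n-1, p)} components,
#'   summing to 100).
#' @export
fit_pca <- function(features, n_components = 3, scale = FALSE) {
  features <- as.matrix(features)
  n <- nrow(features); p <- ncol(features)
  if (n < 2) stop_invalid("need >= 2 samples")
  kmax <- min(n - 1, p)
  if (n_components < 1 || n_components > kmax)
    stop_invalid("`n_components` must lie in [1, min(n-1, p)]")
  if (all(apply(features, 2, stats::var) == 0))
    stop_invalid("feature matrix has zero variance")

  pc <- stats::prcomp(features, center = TRUE, scale. = scale)
  evp_full <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  evp_full <- evp_full[seq_len(kmax)] * 100 / sum(evp_full[seq_len(kmax)])

  k <- n_components
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  # sign convention: largest-|.| element of each loading column positive
  for (j in seq_len(k)) {
    s <- sign(load[which.max(abs(load[, j])), j])
    if (s < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  structure(list(center = pc$center,
                 scale = if (scale) pc$scale else NULL,
                 loadings = load, scores = scores,
                 explained_variance_pct = evp_full[seq_len(k)],
                 explained_variance_pct_full = evp_full,
                 n = n),
            class = "color_pca")
}

#' @export
print.color_pca <- function(x, ...) {
  k <- ncol(x$loadings)
  cat(sprintf("PCA of %d samples x %d features, %d components retained\n",
              x$n, length(x$center), k))
  cat("Explained variance (%):",
      paste(sprintf("PC%d %.2f", seq_len(k), x$explained_variance_pct),
            collapse = ", "), "\n")
  cat(sprintf("Cumulative: %.2f%%\n", sum(x$explained_variance_pct)))
  invisible(x)
}

#' Project samples onto a fitted PCA model
#'
#' @param object A \code{color_pca} model.
#' @param newdata m x p matrix; defaults to reproducing the training scores.
#' @param ... Unused.
#' @return m x k score matrix.
#' @export
predict.color_pca <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  newdata <- as.matrix(newdata)
  if (is.null(dim(newdata)) || ncol(newdata) == 1 &&
      length(object$center) > 1 && nrow(newdata) == length(object$center))
    newdata <- t(newdata)
  if (ncol(newdata) != length(object$center))
    stop_invalid("feature width does not match the model")
  x <- sweep(newdata, 2, object$center)
  if (!is.null(object$scale)) x <- sweep(x, 2, object$scale, "/")
  x %*% object$loadings
}

#' Score plot of a fitted PCA
#'
#' @param x A \code{color_pca} model.
#' @param components Length-2 integer vector of components to plot.
#' @param labels Optional sample labels.
#' @param groups Optional factor colouring the points.
#' @param ... Passed to \code{plot}.
#' @export
plot.color_pca <- function(x, components = c(1, 2), labels = NULL,
                           groups = NULL, ...) {
  s <- x$scores[, components, drop = FALSE]
  col <- if (is.null(groups)) "black" else as.integer(factor(groups)) + 1
  plot(s[, 1], s[, 2], col = col, pch = 19,
       xlab = sprintf("PC%d (%.2f%%)", components[1],
                      x$explained_variance_pct[components[1]]),
       ylab = sprintf("PC%d (%.2f%%)", components[2],
                      x$explained_variance_pct[components[2]]), ...)
  if (!is.null(labels))
    graphics::text(s[, 1], s[, 2], labels, pos = 3, cex = 0.7)
  invisible(x)
}
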