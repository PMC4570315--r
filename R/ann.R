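#' Activation functions and their derivatives
#'
#' The five activation kinds available to the network: \code{sigmoid}
#' \eqn{1/(1+e^{-x})}, \code{linear} \eqn{x}, \code{gaussian}
#' \eqn{e^{-x^2}}, \code{sin} and \code{cos}.
#'
#' @param kind Activation name.
#' @param x Numeric input (vectorised).
#' @param deriv Return the derivative instead of the value?
#' @return Numeric of the same shape as \code{x}.
#' @export
activation <- function(kind, x, deriv = FALSE) {
  switch(kind,
    sigmoid = {
      s <- 1 / (1 + exp(-x))
      if (deriv) s * (1 - s) else s
    },
    linear = if (deriv) x * 0 + 1 else x,
    gaussian = {
      g <- exp(-x^2)
      if (deriv) -2 * x * g else g
    },
    sin = if (deriv) cos(x) else sin(x),
    cos = if (deriv) -sin(x) else cos(x),
    stop_invalid("unknown activation kind: ", kind)
  )
}

activation_kinds <- c("sigmoid", "linear", "gaussian", "sin", "cos")

# output range to which targets are min-max scaled, with a guard band so
# scaled targets stay away from activation asymptotes
activation_target_range <- function(kind) {
  switch(kind,
    sigmoid = c(0.1, 0.9),
    gaussian = c(0.1, 0.9),
    linear = c(0, 1),
    sin = c(-0.9, 0.9),
    cos = c(-0.9, 0.9),
    stop_invalid("unknown activation kind: ", kind))
}

#' Network training configuration
#'
#' One cell of the hyperparameter grid: training algorithm, learning rate
#' (used by the incremental and batch algorithms only), the two hidden
#' layer sizes (a second hidden layer of size 0 means absent) and the
#' per-layer activation functions.
#'
#' @param algorithm One of \code{"incremental"}, \code{"batch"},
#'   \code{"rprop"}, \code{"quickprop"}.
#' @param learning_rate Positive step size for incremental/batch.
#' @param hidden1_size Neurons in the first hidden layer (>= 1).
#' @param hidden1_activation,hidden2_activation,output_activation
#'   Activation kinds.
#' @param hidden2_size Neurons in the second hidden layer; 0 omits it.
#' @param max_epochs Training epoch cap.
#' @param target_mse Desired training MSE (scaled targets); training stops
#'   once reached. \code{NA} disables the check.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement) when validation data are supplied.
#' @param seed Integer seed for weight initialisation.
#' @return Object of class \code{ann_config}.
#' @export
ann_config <- function(algorithm = "rprop", learning_rate = 0.7,
                       hidden1_size = 9, hidden1_activation = "sigmoid",
                       hidden2_size = 0, hidden2_activation = "sigmoid",
                       output_activation = "linear",
                       max_epochs = 1000, patience = 50, seed = 1,
                       target_mse = NA_real_) {
  algorithm <- match.arg(algorithm, c("incremental", "batch", "rprop", "quickprop"))
  if (learning_rate <= 0) stop_invalid("`learning_rate` must be > 0")
  if (hidden1_size < 1) stop_invalid("`hidden1_size` must be >= 1")
  if (hidden2_size < 0) stop_invalid("`hidden2_size` must be >= 0")
  for (a in c(hidden1_activation, hidden2_activation, output_activation))
    if (!a %in% activation_kinds) stop_invalid("unknown activation kind: ", a)
  structure(list(algorithm = algorithm, learning_rate = learning_rate,
                 hidden1_size = as.integer(hidden1_size),
                 hidden1_activation = hidden1_activation,
                 hidden2_size = as.integer(hidden2_size),
                 hidden2_activation = hidden2_activation,
                 output_activation = output_activation,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed),
                 target_mse = as.numeric(target_mse)),
            class = "ann_config")
}

#' @export
print.ann_config <- function(x, ...) {
  arch <- if (x$hidden2_size > 0)
    sprintf("%d(%s)-%d(%s)", x$hidden1_size, x$hidden1_activation,
            x$hidden2_size, x$hidden2_activation)
  else sprintf("%d(%s)", x$hidden1_size, x$hidden1_activation)
  cat(sprintf("ANN config: %s, lr %.2f, hidden %s, output %s, max %d epochs\n",
              x$algorithm, x$learning_rate, arch, x$output_activation,
              x$max_epochs))
  invisible(x)
}

config_label <- function(cfg) {
  sprintf("%s_lr%.1f_h%d%s_h%d%s_out%s", cfg$algorithm, cfg$learning_rate,
          cfg$hidden1_size, cfg$hidden1_activation,
          cfg$hidden2_size, cfg$hidden2_activation, cfg$output_activation)
}

# ---- network construction and forward pass ---------------------------------

layer_sizes <- function(n_inputs, config) {
  s <- c(n_inputs, config$hidden1_size)
  if (config$hidden2_size > 0) s <- c(s, config$hidden2_size)
  c(s, 1L)
}

layer_activations <- function(config) {
  a <- config$hidden1_activation
  if (config$hidden2_size > 0) a <- c(a, config$hidden2_activation)
  c(a, config$output_activation)
}

init_network <- function(n_inputs, config) {
  sizes <- layer_sizes(n_inputs, config)
  acts <- layer_activations(config)
  with_seed(config$seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1)) {
      W[[l]] <- matrix(runif(sizes[l + 1] * sizes[l], -0.5, 0.5),
                       sizes[l + 1], sizes[l])
      b[[l]] <- runif(sizes[l + 1], -0.5, 0.5)
    }
    list(sizes = sizes, activations = acts, W = W, b = b)
  })
}

# forward pass for a batch: X is n x p; returns list of pre-activations Z
# and activations A per layer (A[[0]] stored as input)
forward_pass <- function(net, X) {
  A <- list(X); Z <- list()
  for (l in seq_along(net$W)) {
    Z[[l]] <- sweep(A[[l]] %*% t(net$W[[l]]), 2, net$b[[l]], "+")
    A[[l + 1]] <- activation(net$activations[l], Z[[l]])
  }
  list(Z = Z, A = A)
}

# summed-over-samples gradient of 0.5 * (output - target)^2 w.r.t. weights
# and biases; X n x p, t length n (scaled targets)
network_gradient <- function(net, X, t) {
  fp <- forward_pass(net, X)
  L <- length(net$W)
  delta <- (fp$A[[L + 1]] - t) * activation(net$activations[L], fp$Z[[L]], deriv = TRUE)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- t(delta) %*% fp$A[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1)
      delta <- (delta %*% net$W[[l]]) *
        activation(net$activations[l - 1], fp$Z[[l - 1]], deriv = TRUE)
  }
  list(W = gW, b = gb)
}

flatten_grad <- function(g) unlist(c(lapply(g$W, as.numeric), lapply(g$b, as.numeric)))
flatten_net <- function(net) unlist(c(lapply(net$W, as.numeric), lapply(net$b, as.numeric)))

unflatten_into <- function(net, v) {
  pos <- 0
  for (l in seq_along(net$W)) {
    k <- length(net$W[[l]])
    net$W[[l]][] <- v[pos + seq_len(k)]; pos <- pos + k
  }
  for (l in seq_along(net$b)) {
    k <- length(net$b[[l]])
    net$b[[l]][] <- v[pos + seq_len(k)]; pos <- pos + k
  }
  net
}

# ---- training algorithms ----------------------------------------------------

train_network <- function(net, X, t, config, Xval = NULL, tval = NULL) {
  n <- nrow(X)
  algo <- config$algorithm
  w <- flatten_net(net)
  nw <- length(w)
  # RPROP / QuickPROP state
  step <- rep(0.1, nw)         # RPROP Delta_0
  prev_g <- rep(0, nw)
  prev_dw <- rep(0, nw)
  eta_plus <- 1.2; eta_minus <- 0.5
  delta_max <- 50; delta_min <- 1e-6
  mu <- 1.75; decay <- 1e-4
  shrink <- mu / (1 + mu)

  trace <- numeric(config$max_epochs)
  best_val <- Inf; best_w <- w; stall <- 0
  n_epochs <- 0

  for (epoch in seq_len(config$max_epochs)) {
    if (algo == "incremental") {
      for (i in seq_len(n)) {
        g <- network_gradient(net, X[i, , drop = FALSE], t[i])
        for (l in seq_along(net$W)) {
          net$W[[l]] <- net$W[[l]] - config$learning_rate * g$W[[l]]
          net$b[[l]] <- net$b[[l]] - config$learning_rate * g$b[[l]]
        }
      }
      w <- flatten_net(net)
    } else {
      g <- flatten_grad(network_gradient(net, X, t))
      if (algo == "batch") {
        w <- w - config$learning_rate * g / n
      } else if (algo == "rprop") {
        # iRPROP- : sign-based per-weight step adaptation
        gp <- g * prev_g
        step <- ifelse(gp > 0, pmin(step * eta_plus, delta_max),
                       ifelse(gp < 0, pmax(step * eta_minus, delta_min), step))
        g[gp < 0] <- 0
        w <- w - sign(g) * step
        prev_g <- g
      } else { # quickprop (Fahlman), FANN-style slopes with weight decay
        slope <- -g - decay * w
        eps <- config$learning_rate / n
        dw <- numeric(nw)
        up <- prev_dw > 0.001; down <- prev_dw < -0.001
        mid <- !up & !down
        dw[mid] <- eps * slope[mid]
        if (any(up)) {
          i <- up
          dw[i] <- dw[i] + ifelse(slope[i] > 0, eps * slope[i], 0)
          quad <- slope[i] > shrink * prev_g[i]
          denom <- prev_g[i] - slope[i]
          dw[i] <- dw[i] + ifelse(quad, mu * prev_dw[i],
                                  prev_dw[i] * slope[i] / ifelse(abs(denom) < 1e-12,
                                                                 1e-12, denom))
        }
        if (any(down)) {
          i <- down
          dw[i] <- dw[i] + ifelse(slope[i] < 0, eps * slope[i], 0)
          quad <- slope[i] < shrink * prev_g[i]
          denom <- prev_g[i] - slope[i]
          dw[i] <- dw[i] + ifelse(quad, mu * prev_dw[i],
                                  prev_dw[i] * slope[i] / ifelse(abs(denom) < 1e-12,
                                                                 1e-12, denom))
        }
        w <- w + dw
        prev_dw <- dw
        prev_g <- slope
      }
      net <- unflatten_into(net, w)
    }

    pred <- forward_pass(net, X)$A[[length(net$W) + 1]]
    mse <- mean((pred - t)^2)
    trace[epoch] <- mse
    n_epochs <- epoch
    if (!is.finite(mse))
      stop("training diverged: non-finite MSE at epoch ", epoch,
           " (", algo, ")", call. = FALSE)
    if (!is.na(config$target_mse) && mse <= config$target_mse) break

    if (!is.null(Xval)) {
      vpred <- forward_pass(net, Xval)$A[[length(net$W) + 1]]
      vmse <- mean((vpred - tval)^2)
      if (vmse < best_val - 1e-12) {
        best_val <- vmse; best_w <- w; stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= config$patience) break
      }
    }
  }
  if (!is.null(Xval)) net <- unflatten_into(net, best_w)
  list(net = net, trace = trace[seq_len(n_epochs)])
}

# ---- user-facing fit --------------------------------------------------------

#' Fit a feed-forward taste-prediction network
#'
#' Trains a fully connected feed-forward network with one scalar output by
#' back-propagation, using one of four weight-update algorithms:
#' \describe{
#'   \item{incremental}{per-sample (online) gradient descent with the
#'     configured learning rate;}
#'   \item{batch}{mean-gradient descent per epoch;}
#'   \item{rprop}{iRPROP- resilient back-propagation (step growth 1.2,
#'     shrink 0.5, initial step 0.1, max step 50); no learning rate;}
#'   \item{quickprop}{Fahlman's quadratic-approximation update with growth
#'     limit mu = 1.75 and weight decay 1e-4.}
#' }
#' Inputs are standardised to training mean/sd; targets are min-max scaled
#' into the output activation's working range (e.g. (0.1, 0.9) for
#' sigmoid, (-0.9, 0.9) for sin/cos) and predictions are mapped back to
#' target units. With validation data, training stops early when the
#' validation MSE has not improved for \code{patience} epochs and the best
#' validation-epoch weights are kept.
#'
#' @param x n x p feature matrix.
#' @param y Length-n numeric target (taste score, in its own units).
#' @param config An \code{\link{ann_config}}.
#' @param x_val,y_val Optional validation set for early stopping.
#' @return Object of class \code{wine_ann} with methods \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{fitted},
#'   \code{residuals} and \code{plot} (training trace).
#' @export
ann_train <- function(x, y, config = ann_config(), x_val = NULL, y_val = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) == 0 || length(y) != nrow(x))
    stop_invalid("`x` and `y` must be non-empty with matching rows")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_invalid("non-finite values in training data")

  xc <- colMeans(x)
  xs <- apply(x, 2, stats::sd); xs[xs == 0 | !is.finite(xs)] <- 1
  Xs <- sweep(sweep(x, 2, xc), 2, xs, "/")

  rng <- activation_target_range(config$output_activation)
  ymin <- min(y); ymax <- max(y)
  span <- if (ymax > ymin) ymax - ymin else 1
  t <- rng[1] + (y - ymin) / span * (rng[2] - rng[1])

  Xv <- tv <- NULL
  if (!is.null(x_val)) {
    Xv <- sweep(sweep(as.matrix(x_val), 2, xc), 2, xs, "/")
    tv <- rng[1] + (as.numeric(y_val) - ymin) / span * (rng[2] - rng[1])
  }

  net <- init_network(ncol(x), config)
  fit <- train_network(net, Xs, t, config, Xv, tv)

  obj <- structure(list(net = fit$net, config = config,
                        x_center = xc, x_scale = xs,
                        y_min = ymin, y_max = ymax, y_span = span,
                        out_range = rng, trace = fit$trace,
                        x_names = colnames(x), y = y, x = x),
                   class = "wine_ann")
  obj$fitted_values <- predict(obj, x)
  obj
}

scale_targets <- function(object, y) {
  object$out_range[1] + (y - object$y_min) / object$y_span *
    diff(object$out_range)
}

#' @export
predict.wine_ann <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted_values)
  newdata <- as.matrix(newdata)
  if (any(!is.finite(newdata))) stop_invalid("non-finite input")
  Xs <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, "/")
  raw <- forward_pass(object$net, Xs)$A[[length(object$net$W) + 1]]
  as.numeric(object$y_min +
               (raw - object$out_range[1]) / diff(object$out_range) *
               object$y_span)
}

#' @export
fitted.wine_ann <- function(object, ...) object$fitted_values

#' @export
residuals.wine_ann <- function(object, ...) object$y - object$fitted_values

#' @export
coef.wine_ann <- function(object, ...) {
  v <- flatten_net(object$net)
  names(v) <- weight_names(object$net)
  v
}

weight_names <- function(net) {
  nm <- character(0)
  for (l in seq_along(net$W))
    nm <- c(nm, sprintf("W%d[%d,%d]", l,
                        rep(seq_len(nrow(net$W[[l]])), ncol(net$W[[l]])),
                        rep(seq_len(ncol(net$W[[l]])), each = nrow(net$W[[l]]))))
  for (l in seq_along(net$b))
    nm <- c(nm, sprintf("b%d[%d]", l, seq_along(net$b[[l]])))
  nm
}

#' Replace a network's weights (flattened vector)
#'
#' Mainly useful for gradient checking and serialisation round-trips.
#' @param object A \code{wine_ann}.
#' @param weights Numeric vector matching \code{length(coef(object))}.
#' @return The modified \code{wine_ann}.
#' @export
ann_set_weights <- function(object, weights) {
  if (length(weights) != length(flatten_net(object$net)))
    stop_invalid("weight vector length mismatch")
  object$net <- unflatten_into(object$net, weights)
  object$fitted_values <- predict(object, object$x)
  object
}

#' Sum-of-squares loss and its analytic gradient
#'
#' Loss \eqn{\sum_i \frac12 (\hat y_i - t_i)^2} on scaled targets, as used
#' by the training algorithms, together with the back-propagated gradient
#' with respect to the flattened weight vector. Exposed for gradient
#' verification.
#'
#' @param object A \code{wine_ann}.
#' @param x n x p feature matrix (target units as supplied to
#'   \code{\link{ann_train}}).
#' @param y Length-n target vector.
#' @return \code{ann_loss}: a number. \code{ann_gradient}: a numeric vector
#'   aligned with \code{coef(object)}.
#' @export
ann_loss <- function(object, x, y) {
  Xs <- sweep(sweep(as.matrix(x), 2, object$x_center), 2, object$x_scale, "/")
  t <- scale_targets(object, y)
  pred <- forward_pass(object$net, Xs)$A[[length(object$net$W) + 1]]
  sum(0.5 * (pred - t)^2)
}

#' @rdname ann_loss
#' @export
ann_gradient <- function(object, x, y) {
  Xs <- sweep(sweep(as.matrix(x), 2, object$x_center), 2, object$x_scale, "/")
  t <- scale_targets(object, y)
  flatten_grad(network_gradient(object$net, Xs, t))
}

#' @export
print.wine_ann <- function(x, ...) {
  cat("Feed-forward taste network\n")
  print(x$config)
  cat(sprintf("Architecture: %s; %d weights; trained %d epochs (final MSE %.3g)\n",
              paste(x$net$sizes, collapse = "-"),
              length(flatten_net(x$net)), length(x$trace),
              x$trace[length(x$trace)]))
  invisible(x)
}

#' @export
summary.wine_ann <- function(object, ...) {
  res <- residuals(object)
  out <- list(config = object$config, sizes = object$net$sizes,
              epochs = length(object$trace),
              final_mse = object$trace[length(object$trace)],
              train_rmsep = sqrt(mean(res^2)),
              train_r2 = if (stats::var(object$y) > 0)
                stats::cor(object$y, object$fitted_values)^2 else NA_real_)
  class(out) <- "summary.wine_ann"
  out
}

#' @export
print.summary.wine_ann <- function(x, ...) {
  cat("Feed-forward taste network\n")
  print(x$config)
  cat(sprintf("Architecture %s, trained %d epochs\n",
              paste(x$sizes, collapse = "-"), x$epochs))
  cat(sprintf("Training RMSEP %.4g, training R^2 %.4f\n",
              x$train_rmsep, x$train_r2))
  invisible(x)
}

#' @export
plot.wine_ann <- function(x, ...) {
  plot(seq_along(x$trace), x$trace, type = "l", log = "y",
       xlab = "epoch", ylab = "training MSE (scaled targets)", ...)
  invisible(x)
}

#' Serialise a fitted network to YAML
#' @param object A \code{wine_ann}.
#' @param path File path.
#' @export
write_ann <- function(object, path) {
  obj <- list(sizes = object$net$sizes, activations = object$net$activations,
              weights = as.numeric(flatten_net(object$net)),
              x_center = as.numeric(object$x_center),
              x_scale = as.numeric(object$x_scale),
              y_min = object$y_min, y_max = object$y_max,
              out_range = object$out_range,
              config = unclass(object$config))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}
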