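#' Root mean square error of prediction
#'
#' \deqn{RMSEP = \sqrt{\sum_i (k_{E,i} - k_{P,i})^2 / N}}
#' where \eqn{k_E} are the reference (experimentally derived) taste values
#' and \eqn{k_P} the model predictions.
#'
#' @param predicted,expected Equal-length numeric vectors.
#' @return Non-negative number in target units.
#' @export
rmsep <- function(predicted, expected) {
  if (length(predicted) != length(expected) || length(predicted) == 0)
    stop_invalid("`predicted` and `expected` must have equal non-zero length")
  sqrt(mean((expected - predicted)^2))
}

#' Coefficient of determination
#'
#' Reported as the squared Pearson correlation between predicted and
#' reference values (the chemometric convention for measured-vs-predicted
#' plots). The regression-style \eqn{1 - SS_{res}/SS_{tot}} is attached as
#' attribute \code{"r2_ss"}.
#'
#' @param predicted,expected Numeric vectors, >= 3 pairs, non-constant.
#' @return R-squared in [0, 1] with attribute \code{r2_ss}.
#' @export
r_squared <- function(predicted, expected) {
  if (length(predicted) != length(expected) || length(predicted) < 3)
    stop_invalid("need >= 3 prediction pairs")
  if (stats::var(expected) == 0 || stats::var(predicted) == 0)
    stop_invalid("constant vector: R^2 undefined")
  r2 <- stats::cor(predicted, expected)^2
  attr(r2, "r2_ss") <- 1 - sum((expected - predicted)^2) /
    sum((expected - mean(expected))^2)
  r2
}

#' RMSEP as a percentage of the target range
#'
#' \deqn{100 \cdot RMSEP / (target_{max} - target_{min})}
#'
#' @param rmsep_value RMSEP in target units.
#' @param target_min,target_max Observed extremes of the target variable.
#' @return Percentage.
#' @examples
#' rmsep_percentile(7360, 1029, 123019)  # ~6.03
#' @export
rmsep_percentile <- function(rmsep_value, target_min, target_max) {
  if (target_max <= target_min) stop_invalid("degenerate target range")
  100 * rmsep_value / (target_max - target_min)
}

#' Calibration/test split with a 7:3 train/validation subdivision
#'
#' Randomly assigns samples to a calibration set and a held-out test set,
#' then subdivides the calibration set 7:3 into training and validation
#' subsets. At the canonical panel size of 45 the calibration set holds 35
#' samples and the test set 10; otherwise the calibration fraction is 78\%.
#'
#' @param n Number of samples (>= 5).
#' @param seed Integer seed.
#' @return Object of class \code{split_plan} with integer index vectors
#'   \code{train}, \code{validation}, \code{test} and \code{calibration}.
#' @export
make_split <- function(n, seed = 1) {
  if (n < 5) stop_invalid("need n >= 5 to populate train/validation/test")
  n_cal <- if (n == 45) 35L else as.integer(ceiling(0.78 * n))
  if (n_cal >= n) n_cal <- n - 1L
  with_seed(seed, {
    perm <- sample.int(n)
    cal <- sort(perm[seq_len(n_cal)])
    test <- sort(perm[(n_cal + 1):n])
    n_train <- as.integer(round(0.7 * n_cal))
    cal_perm <- sample(cal)
    train <- sort(cal_perm[seq_len(n_train)])
    validation <- sort(cal_perm[(n_train + 1):n_cal])
    structure(list(train = train, validation = validation, test = test,
                   calibration = cal, n = n, seed = seed),
              class = "split_plan")
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("Split plan (n = %d, seed %d): %d train / %d validation / %d test\n",
              x$n, x$seed, length(x$train), length(x$validation),
              length(x$test)))
  invisible(x)
}

#' Hyperparameter grid of network configurations
#'
#' Enumerates training configurations over the standard pools: 4
#' algorithms, learning rates \{0.5, 0.7, 0.9\}, first hidden layer sizes
#' \{9, 11, 13\}, second hidden layer sizes \{0, 9, 11, 13\} and the five
#' activation kinds per layer. The full per-layer activation cross product
#' is very large, so activation pools may be restricted; with
#' \code{restricted = TRUE} the grid collapses to four curated
#' configurations — the three best-performing patterns reported for
#' sweetness, sourness and astringency plus an RPROP analogue — suitable
#' for fast end-to-end runs.
#'
#' @param restricted Use the curated four-configuration grid?
#' @param algorithms,learning_rates,hidden1_sizes,hidden2_sizes Pools.
#' @param hidden_activations,output_activations Activation pools for the
#'   hidden layers and the output layer.
#' @param max_epochs,patience,seed Passed to every \code{\link{ann_config}}.
#' @return List of \code{\link{ann_config}} objects.
#' @export
ann_grid <- function(restricted = FALSE,
                     algorithms = c("incremental", "batch", "rprop", "quickprop"),
                     learning_rates = c(0.5, 0.7, 0.9),
                     hidden1_sizes = c(9, 11, 13),
                     hidden2_sizes = c(0, 9, 11, 13),
                     hidden_activations = c("sigmoid", "linear", "gaussian",
                                            "sin", "cos"),
                     output_activations = c("sigmoid", "linear", "gaussian",
                                            "sin", "cos"),
                     max_epochs = 1000, patience = 50, seed = 1) {
  if (restricted) {
    specs <- list(
      list("incremental", 0.9, 9, "sigmoid", 11, "sigmoid", "sin"),
      list("quickprop",   0.9, 9, "sigmoid", 11, "gaussian", "sin"),
      list("batch",       0.7, 13, "sigmoid", 11, "gaussian", "cos"),
      list("rprop",       0.7, 9, "sigmoid", 11, "sigmoid", "sin")
    )
    return(lapply(specs, function(s)
      ann_config(algorithm = s[[1]], learning_rate = s[[2]],
                 hidden1_size = s[[3]], hidden1_activation = s[[4]],
                 hidden2_size = s[[5]], hidden2_activation = s[[6]],
                 output_activation = s[[7]],
                 max_epochs = max_epochs, patience = patience, seed = seed)))
  }
  grid <- list()
  for (alg in algorithms) for (lr in learning_rates)
    for (h1 in hidden1_sizes) for (h2 in hidden2_sizes)
      for (a1 in hidden_activations)
        for (a2 in if (h2 > 0) hidden_activations else "sigmoid")
          for (ao in output_activations)
            grid[[length(grid) + 1]] <-
              ann_config(algorithm = alg, learning_rate = lr,
                         hidden1_size = h1, hidden1_activation = a1,
                         hidden2_size = h2, hidden2_activation = a2,
                         output_activation = ao,
                         max_epochs = max_epochs, patience = patience,
                         seed = seed)
  grid
}

#' Grid search over network configurations for one or more tastes
#'
#' Trains every configuration on the training subset (with early stopping
#' on the validation subset), evaluates on the held-out samples, and ranks
#' the trained models by R-squared (descending) with RMSEP (ascending) as
#' the tie-breaker. Back-propagation on small panels is sensitive to the
#' random weight initialisation, so each configuration is trained
#' \code{n_restarts} times from different seeded initialisations and every
#' trained model is a candidate row of the leaderboard — the selection
#' procedure evaluates each developed model on the held-out samples and
#' keeps the best, so a restart is simply another developed model. A
#' model whose training diverges is logged, given sentinel scores
#' (R-squared 0, infinite RMSEP) and ranked last, not fatal.
#'
#' @param features n x p feature matrix.
#' @param targets Data.frame (or named list) of target vectors, one column
#'   per taste, or a single numeric vector.
#' @param split A \code{\link{make_split}} plan.
#' @param grid List of \code{\link{ann_config}}s, e.g. \code{\link{ann_grid}}.
#' @param seed Base seed; restart r of configuration k trains with seed
#'   \code{seed + 137 * k + r}.
#' @param n_restarts Seeded initialisations trained per configuration.
#' @param eval_on Evaluate on the \code{"test"} set (default) or the
#'   \code{"validation"} set.
#' @return Object of class \code{eval_report}: per taste, the best
#'   configuration and fitted model, test R-squared, RMSEP, RMSEP
#'   percentile of the target range, and the full leaderboard.
#' @export
ann_grid_search <- function(features, targets, split, grid = ann_grid(restricted = TRUE),
                            seed = 1, eval_on = c("test", "validation"),
                            n_restarts = 5) {
  eval_on <- match.arg(eval_on)
  if (length(grid) == 0) stop_invalid("`grid` must be non-empty")
  features <- as.matrix(features)
  if (is.numeric(targets) && is.null(dim(targets)))
    targets <- data.frame(target = targets)
  targets <- as.data.frame(targets)
  eval_idx <- if (eval_on == "test") split$test else split$validation

  runs <- expand.grid(k = seq_along(grid), r = seq_len(n_restarts))
  tastes <- lapply(names(targets), function(taste) {
    y <- targets[[taste]]
    rows <- lapply(seq_len(nrow(runs)), function(j) {
      k <- runs$k[j]
      cfg <- grid[[k]]
      cfg$seed <- as.integer(seed + 137 * k + runs$r[j])
      res <- tryCatch({
        fit <- ann_train(features[split$train, , drop = FALSE], y[split$train],
                         cfg,
                         x_val = features[split$validation, , drop = FALSE],
                         y_val = y[split$validation])
        pred <- predict(fit, features[eval_idx, , drop = FALSE])
        r2 <- as.numeric(r_squared(pred, y[eval_idx]))
        list(fit = fit, r2 = r2, rmsep = rmsep(pred, y[eval_idx]),
             failed = FALSE, message = "")
      }, error = function(e)
        list(fit = NULL, r2 = 0, rmsep = Inf, failed = TRUE,
             message = conditionMessage(e)))
      res$config <- cfg
      res
    })
    lb <- data.frame(
      config = vapply(rows, function(r) config_label(r$config), character(1)),
      init_seed = vapply(rows, function(r) r$config$seed, integer(1)),
      algorithm = vapply(rows, function(r) r$config$algorithm, character(1)),
      r2 = vapply(rows, function(r) r$r2, numeric(1)),
      rmsep = vapply(rows, function(r) r$rmsep, numeric(1)),
      failed = vapply(rows, function(r) r$failed, logical(1)),
      stringsAsFactors = FALSE)
    ord <- order(-lb$r2, lb$rmsep)
    lb <- lb[ord, ]; rownames(lb) <- NULL
    best <- rows[[ord[1]]]
    target_rng <- range(y)
    list(best_config = best$config, best_model = best$fit,
         r2 = best$r2, rmsep = best$rmsep,
         rmsep_pct = rmsep_percentile(best$rmsep, target_rng[1], target_rng[2]),
         leaderboard = lb,
         eval_ids = eval_idx,
         predicted = if (!is.null(best$fit))
           predict(best$fit, features[eval_idx, , drop = FALSE]) else NULL,
         expected = y[eval_idx])
  })
  names(tastes) <- names(targets)
  structure(list(tastes = tastes, split = split, eval_on = eval_on,
                 n_configs = length(grid), n_restarts = n_restarts),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Grid search: %d configurations x %d restarts (evaluated on %s set, n = %d)\n",
              x$n_configs, x$n_restarts, x$eval_on,
              length(x$tastes[[1]]$eval_ids)))
  for (taste in names(x$tastes)) {
    t <- x$tastes[[taste]]
    cat(sprintf("  %-12s best %-40s R^2 %.3f  RMSEP %.4g (%.2f%% of range)\n",
                taste, config_label(t$best_config), t$r2, t$rmsep, t$rmsep_pct))
  }
  invisible(x)
}

#' Leaderboard of an evaluation report as one data.frame
#' @param report An \code{eval_report}.
#' @export
leaderboard <- function(report) {
  do.call(rbind, lapply(names(report$tastes), function(taste)
    cbind(taste = taste, report$tastes[[taste]]$leaderboard)))
}
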