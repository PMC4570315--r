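# Shared fixtures, built in code so every test run regenerates them.

# minimal named concentration vector covering all chemicals
zero_profile <- function() setNames(rep(0, length(wine_chemicals)), wine_chemicals)

# a tiny two-dye model with hand-set numbers, for exact arithmetic checks
tiny_dye_model <- function() {
  dyes <- c("dyeA", "dyeB")
  baseline <- matrix(c(100, 120, 140, 90, 110, 130), 2, 3, byrow = TRUE,
                     dimnames = list(dyes, c("R", "G", "B")))
  chems <- wine_chemicals
  sens <- array(0, c(2, 3, length(chems)),
                dimnames = list(dyes, c("R", "G", "B"), chems))
  sens["dyeA", , "glucose"] <- c(10, -20, 30)
  sens["dyeB", , "malic"] <- c(-6, 8, 12)
  sens["dyeA", , "tannin"] <- c(4, 4, -4)
  half <- setNames(rep(1000, length(chems)), chems)
  peaks <- list(
    dyeA = list(table = data.frame(center = 550, width = 30, height = 1),
                chemical_gain = matrix(0.5, 1, length(chems),
                                       dimnames = list(NULL, chems))),
    dyeB = list(table = data.frame(center = c(470, 650), width = c(25, 40),
                                   height = c(0.8, 0.4)),
                chemical_gain = matrix(0.3, 2, length(chems),
                                       dimnames = list(NULL, chems)))
  )
  dye_model(baseline, sens, half, peaks)
}

xor_data <- function() {
  list(x = matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE),
       y = c(0, 1, 1, 0))
}

config_label_test <- function(cfg) vinotaste:::config_label(cfg)

# evaluate `expr` under a local seed without disturbing the session RNG
with_seed_test <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# finite-difference gradient of the network loss at the current weights
fd_gradient <- function(fit, x, y, idx, h = 1e-6) {
  w <- coef(fit)
  vapply(idx, function(i) {
    wp <- w; wp[i] <- w[i] + h
    wm <- w; wm[i] <- w[i] - h
    (ann_loss(ann_set_weights(fit, wp), x, y) -
       ann_loss(ann_set_weights(fit, wm), x, y)) / (2 * h)
  }, numeric(1))
}
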