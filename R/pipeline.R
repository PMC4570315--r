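#' Pipeline run configuration
#'
#' Seeds and options controlling a full simulate-to-report run. All seeds
#' are recorded in the run manifest so any stage can be reproduced.
#'
#' @param out_dir Output directory (created if absent).
#' @param n_base,n_mixtures Panel composition.
#' @param panel_seed,noise_seed,split_seed,ann_seed Stage seeds.
#' @param noise_sd Colour-response measurement noise (RGB counts).
#' @param pixel_noise_sd Per-pixel image noise (RGB counts).
#' @param restricted_grid Use the curated four-configuration grid?
#' @param max_epochs Epoch cap per configuration.
#' @param n_restarts Seeded initialisations trained per configuration.
#' @param write_images Render and write the per-sample PNG image pairs?
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(out_dir = tempfile("vinotaste_run_"),
                       n_base = 23, n_mixtures = 22,
                       panel_seed = 1, noise_seed = 2, split_seed = 3,
                       ann_seed = 4,
                       noise_sd = 0.5, pixel_noise_sd = 1,
                       restricted_grid = TRUE, max_epochs = 2000,
                       n_restarts = 5, write_images = TRUE) {
  structure(list(out_dir = out_dir, n_base = n_base, n_mixtures = n_mixtures,
                 panel_seed = panel_seed, noise_seed = noise_seed,
                 split_seed = split_seed, ann_seed = ann_seed,
                 noise_sd = noise_sd, pixel_noise_sd = pixel_noise_sd,
                 restricted_grid = restricted_grid, max_epochs = max_epochs,
                 n_restarts = n_restarts, write_images = write_images),
            class = "run_config")
}

pipeline_stages <- c("simulate", "extract", "score", "pca", "train", "report")

#' Run the end-to-end taste-sensor pipeline
#'
#' Executes, in order: \code{simulate} (panel CSV, dye model YAML, and the
#' per-sample before/after array images), \code{extract} (24-feature CSV
#' from the images), \code{score} (taste-score CSV), \code{pca} (scores,
#' loadings, explained variance and score plots), \code{train} (grid
#' search per taste) and \code{report} (leaderboard CSV, evaluation JSON
#' and measured-vs-predicted plots). Every stage reads its inputs from and
#' writes its outputs to \code{config$out_dir}, so individual stages can
#' be re-run (or run on user-supplied files) independently; a JSON
#' manifest records seeds and completed stages.
#'
#' @param config A \code{\link{run_config}}.
#' @param stages Subset of stages to run (in canonical order).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = run_config(), stages = pipeline_stages) {
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(config$out_dir, ...)
  manifest_path <- p("manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  else list(package_version = as.character(utils::packageVersion("vinotaste")),
            config = unclass(config)[setdiff(names(unclass(config)), "out_dir")],
            completed_stages = character(0))

  for (stage in pipeline_stages[pipeline_stages %in% stages]) {
    result <- tryCatch(switch(stage,
      simulate = stage_simulate(config, p),
      extract = stage_extract(config, p),
      score = stage_score(config, p),
      pca = stage_pca(config, p),
      train = stage_train(config, p),
      report = stage_report(config, p)
    ), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$completed_stages <- union(manifest$completed_stages, stage)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  invisible(manifest)
}

stage_simulate <- function(config, p) {
  panel <- generate_panel(config$n_base, config$n_mixtures, config$panel_seed)
  model <- default_dye_model()
  write_panel(panel, p("panel.csv"))
  write_dye_model(model, p("dye_model.yaml"))
  deltas <- panel_deltas(panel, model, config)
  utils::write.csv(
    data.frame(sample_id = panel$sample_id,
               t(vapply(deltas, as.numeric, numeric(24))),
               check.names = FALSE),
    p("deltas.csv"), row.names = FALSE)
  if (config$write_images) {
    dir.create(p("images"), showWarnings = FALSE)
    for (i in seq_len(nrow(panel))) {
      pair <- render_image_pair(deltas[[i]], model,
                                pixel_noise_sd = config$pixel_noise_sd,
                                seed = config$noise_seed * 1000 + i)
      write_image(pair$before, p("images", paste0(panel$sample_id[i], "_before.png")))
      write_image(pair$after, p("images", paste0(panel$sample_id[i], "_after.png")))
    }
  }
  invisible(TRUE)
}

panel_deltas <- function(panel, model, config) {
  out <- lapply(seq_len(nrow(panel)), function(i)
    simulate_color_response(profile_conc(panel, i), model,
                            noise_sd = config$noise_sd,
                            seed = config$noise_seed + i))
  names(out) <- panel$sample_id
  out
}

stage_extract <- function(config, p) {
  panel <- read_panel(p("panel.csv"))
  model <- read_dye_model(p("dye_model.yaml"))
  layout <- well_layout()
  feats <- matrix(NA_real_, nrow(panel), 24,
                  dimnames = list(panel$sample_id,
                                  paste(rep(dye_names, each = 3),
                                        c("R", "G", "B"), sep = "_")))
  for (i in seq_len(nrow(panel))) {
    id <- panel$sample_id[i]
    bpath <- p("images", paste0(id, "_before.png"))
    apath <- p("images", paste0(id, "_after.png"))
    if (file.exists(bpath) && file.exists(apath)) {
      before <- read_image(bpath); after <- read_image(apath)
    } else {
      # images absent: re-render deterministically from the stored panel,
      # dye model and manifest seeds
      delta <- simulate_color_response(profile_conc(panel, i), model,
                                       noise_sd = config$noise_sd,
                                       seed = config$noise_seed + i)
      pair <- render_image_pair(delta, model,
                                pixel_noise_sd = config$pixel_noise_sd,
                                seed = config$noise_seed * 1000 + i)
      # match the 8-bit quantisation a PNG round trip would apply
      before <- round(pair$before); after <- round(pair$after)
    }
    wells <- detect_wells(before)
    feats[i, ] <- extract_features(before, after, wells)
  }
  write_features(feats, p("features.csv"))
  invisible(TRUE)
}

stage_score <- function(config, p) {
  panel <- read_panel(p("panel.csv"))
  utils::write.csv(taste_scores(panel), p("scores.csv"), row.names = FALSE)
  invisible(TRUE)
}

stage_pca <- function(config, p) {
  feats <- read_features(p("features.csv"))
  panel <- read_panel(p("panel.csv"))
  model <- fit_pca(feats, n_components = 3)
  utils::write.csv(data.frame(sample_id = rownames(feats), model$scores),
                   p("pca_scores.csv"), row.names = FALSE)
  utils::write.csv(data.frame(feature = colnames(feats), model$loadings),
                   p("pca_loadings.csv"), row.names = FALSE)
  utils::write.csv(data.frame(component = seq_along(model$explained_variance_pct_full),
                              explained_pct = model$explained_variance_pct_full),
                   p("pca_explained.csv"), row.names = FALSE)
  for (comps in list(c(1, 2), c(1, 3))) {
    grDevices::png(p(sprintf("pca_pc%d_pc%d.png", comps[1], comps[2])),
                   width = 700, height = 600)
    plot(model, components = comps, labels = rownames(feats),
         groups = panel$cluster,
         main = "Sensor-array PCA score plot")
    grDevices::dev.off()
  }
  invisible(TRUE)
}

stage_train <- function(config, p) {
  feats <- read_features(p("features.csv"))
  scores <- utils::read.csv(p("scores.csv"))
  split <- make_split(nrow(feats), seed = config$split_seed)
  grid <- ann_grid(restricted = config$restricted_grid,
                   max_epochs = config$max_epochs)
  report <- ann_grid_search(feats, scores[, c("sweetness", "sourness",
                                              "astringency")],
                            split, grid, seed = config$ann_seed,
                            n_restarts = config$n_restarts)
  write_report_files(report, p)
  invisible(TRUE)
}

# persist the report as plain text (leaderboard CSV + JSON summary +
# predictions CSV) so the report stage can be regenerated without R objects
write_report_files <- function(report, p) {
  utils::write.csv(leaderboard(report), p("leaderboard.csv"), row.names = FALSE)
  summ <- lapply(report$tastes, function(t)
    list(best_config = config_label(t$best_config),
         r2 = t$r2, rmsep = t$rmsep, rmsep_pct = t$rmsep_pct))
  jsonlite::write_json(summ, p("eval_report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  preds <- do.call(rbind, lapply(names(report$tastes), function(taste)
    data.frame(taste = taste, sample = report$tastes[[taste]]$eval_ids,
               expected = report$tastes[[taste]]$expected,
               predicted = report$tastes[[taste]]$predicted)))
  utils::write.csv(preds, p("predictions.csv"), row.names = FALSE)
  invisible(TRUE)
}

stage_report <- function(config, p) {
  preds <- utils::read.csv(p("predictions.csv"))
  for (taste in unique(preds$taste)) {
    d <- preds[preds$taste == taste, ]
    grDevices::png(p(sprintf("measured_vs_predicted_%s.png", taste)),
                   width = 600, height = 600)
    plot(d$expected, d$predicted, pch = 19,
         xlab = sprintf("measured %s", taste),
         ylab = sprintf("predicted %s", taste),
         main = sprintf("%s: R^2 = %.3f", taste,
                        as.numeric(r_squared(d$predicted, d$expected))))
    graphics::abline(0, 1, lty = 2)
    grDevices::dev.off()
  }
  invisible(TRUE)
}
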