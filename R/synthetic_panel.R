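#' Generate a synthetic wine taste-chemical panel
#'
#' Emulates the study design of a white-wine tasting panel: a set of base
#' wines falling into two taste clusters (sweet and dry) plus pairwise
#' mixtures of base wines. Each base wine's total sweetness and total
#' sourness are drawn log-uniformly within its cluster's observed score
#' band and then partitioned across the individual sugars and acids
#' (fructose the dominant sugar, malic and tartaric the dominant acids),
#' so the two clusters are strictly separated in sweetness and sourness.
#' Mixtures are convex combinations of two distinct base wines with a
#' random mixing weight.
#'
#' @param n_base Number of base wines (>= 2). About 30\% (7 of 23 at the
#'   default panel size) are assigned to the sweet cluster.
#' @param n_mixtures Number of pairwise mixtures (>= 0).
#' @param seed Integer seed; the same seed reproduces the panel exactly.
#' @return A data.frame of class \code{chem_panel} with columns
#'   \code{sample_id}, \code{cluster} (\code{"sweet"}, \code{"dry"} or
#'   \code{"mixture"}), and one column per chemical in
#'   \code{\link{wine_chemicals}} (mg/L).
#' @examples
#' panel <- generate_panel(23, 22, seed = 1)
#' nrow(panel)  # 45
#' @export
generate_panel <- function(n_base, n_mixtures = 0, seed = 1) {
  if (!is.numeric(n_base) || length(n_base) != 1 || n_base < 2)
    stop_invalid("`n_base` must be a single count >= 2")
  if (!is.numeric(n_mixtures) || length(n_mixtures) != 1 || n_mixtures < 0)
    stop_invalid("`n_mixtures` must be a single count >= 0")
  n_base <- as.integer(n_base); n_mixtures <- as.integer(n_mixtures)

  with_seed(seed, {
    n_sweet <- max(1L, as.integer(round(n_base * 7 / 23)))
    cluster <- rep("dry", n_base)
    cluster[sample.int(n_base, n_sweet)] <- "sweet"

    base <- t(vapply(cluster, sample_base_profile, numeric(length(wine_chemicals))))
    colnames(base) <- wine_chemicals

    conc <- base
    mix_cluster <- character(0)
    if (n_mixtures > 0) {
      mixes <- matrix(0, n_mixtures, length(wine_chemicals))
      for (m in seq_len(n_mixtures)) {
        ij <- sample.int(n_base, 2)
        w <- runif(1)
        mixes[m, ] <- w * base[ij[1], ] + (1 - w) * base[ij[2], ]
      }
      conc <- rbind(base, mixes)
      mix_cluster <- rep("mixture", n_mixtures)
    }

    ids <- c(sprintf("W%02d", seq_len(n_base)),
             if (n_mixtures > 0) sprintf("M%02d", seq_len(n_mixtures)))
    out <- data.frame(sample_id = ids,
                      cluster = c(cluster, mix_cluster),
                      conc, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    class(out) <- c("chem_panel", "data.frame")
    out
  })
}

# One base wine: draw cluster-band score totals, partition across chemicals.
sample_base_profile <- function(cluster) {
  bands <- score_bands()[[cluster]]
  rng <- chem_ranges()
  conc <- setNames(numeric(length(wine_chemicals)), wine_chemicals)

  # sweetness S = 0.75*glucose + sucrose + 1.5*fructose, fructose dominant
  S <- rloguni(1, bands$sweetness[1], bands$sweetness[2])
  f_frac <- runif(1, 0.55, 0.85)
  g_frac <- (1 - f_frac) * runif(1, 0.60, 0.95)
  s_frac <- 1 - f_frac - g_frac
  conc["fructose"] <- S * f_frac / 1.5
  conc["glucose"]  <- S * g_frac / 0.75
  conc["sucrose"]  <- S * s_frac

  # sourness T (mmol/L) = sum conc_i / M_i, malic + tartaric dominant
  sr <- rloguni(1, bands$sourness[1], bands$sourness[2])
  m_frac <- runif(1, 0.50, 0.75)
  t_frac <- (1 - m_frac) * runif(1, 0.55, 0.90)
  rest <- 1 - m_frac - t_frac
  minor <- c("succinic", "formic", "lactic", "citric", "acetic")
  w <- runif(5); w <- w / sum(w)
  mmol <- c(malic = sr * m_frac, tartaric = sr * t_frac, setNames(sr * rest * w, minor))
  conc[names(mmol)] <- mmol * acid_molar_masses[names(mmol)]

  conc["tannin"] <- rloguni(1, rng["tannin", 1], rng["tannin", 2])

  # clip to the observed per-chemical extremes (floor 0)
  pmin(pmax(conc, 0), rng[wine_chemicals, 2])
}

#' @export
print.chem_panel <- function(x, ...) {
  cat(sprintf("Synthetic wine panel: %d samples (%d sweet, %d dry, %d mixtures)\n",
              nrow(x), sum(x$cluster == "sweet"), sum(x$cluster == "dry"),
              sum(x$cluster == "mixture")))
  print.data.frame(utils::head(as.data.frame(x), 5), digits = 4)
  if (nrow(x) > 5) cat("...", nrow(x) - 5, "more rows\n")
  invisible(x)
}

#' Read or write a chemical panel as CSV
#'
#' @param panel A \code{chem_panel} data.frame.
#' @param path File path.
#' @return \code{read_panel} returns a \code{chem_panel}.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop_invalid("panel file not found: ", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(wine_chemicals, names(out))
  if (length(missing))
    stop_invalid("panel CSV lacks chemical columns: ", paste(missing, collapse = ", "))
  class(out) <- c("chem_panel", "data.frame")
  out
}

# concentrations of one panel row as a named vector
profile_conc <- function(panel, i) {
  unlist(panel[i, wine_chemicals, drop = TRUE])
}
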