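#' Apply pellet-group field rules to raw observations
#'
#' Converts raw pellet observations into per-plot pellet-group counts
#' under the field protocol: a pellet group is a discrete accumulation of
#' more than 5 pellets from one defecation event, so smaller scatters are
#' discarded; for latrine-forming species (nilgai, chowsingha) all
#' observations sharing one site collapse to a single pellet group.
#'
#' @param obs data.frame of raw observations with columns `transect_id`,
#'   `plot_id`, `habitat`, `species`, `n_pellets` and optionally `site`
#'   (a within-plot location key; defaults to one site per row).
#' @param species Character vector fixing the species set of the survey
#'   (columns of the output); defaults to the species present.
#' @param latrine_species Species whose co-located groups collapse to one.
#' @param min_pellets Minimum pellet count for a valid group (strict
#'   threshold: a group must exceed it).
#' @return data.frame of plots: `transect_id`, `plot_id`, `habitat`, one
#'   count column per species.
#' @export
latrine_rule <- function(obs, species = NULL,
                         latrine_species = c("nilgai", "chowsingha"),
                         min_pellets = 5) {
  need <- c("transect_id", "plot_id", "habitat", "species", "n_pellets")
  if (!all(need %in% names(obs))) stop("obs needs columns ", paste(need, collapse = ", "))
  if (is.null(obs$site)) obs$site <- seq_len(nrow(obs))
  if (is.null(species)) species <- sort(unique(obs$species))
  plots <- unique(obs[, c("transect_id", "plot_id", "habitat")])
  keep <- obs[obs$n_pellets > min_pellets, , drop = FALSE]
  # latrines: one group per distinct site
  is_lat <- keep$species %in% latrine_species
  lat <- unique(keep[is_lat, c("transect_id", "plot_id", "species", "site")])
  keep <- rbind(keep[!is_lat, names(lat)], lat)
  for (sp in species) {
    k <- keep[keep$species == sp, , drop = FALSE]
    cnt <- if (nrow(k))
      stats::aggregate(list(n = rep(1L, nrow(k))),
                       k[, c("transect_id", "plot_id")], sum)
    else data.frame(transect_id = character(), plot_id = integer(),
                    n = integer())
    m <- merge(plots, cnt, all.x = TRUE, by = c("transect_id", "plot_id"))
    m <- m[order(match(paste(m$transect_id, m$plot_id),
                       paste(plots$transect_id, plots$plot_id))), ]
    plots[[sp]] <- ifelse(is.na(m$n), 0L, m$n)
  }
  rownames(plots) <- NULL
  plots
}

species_columns <- function(plots) {
  setdiff(names(plots), c("transect_id", "plot_id", "habitat"))
}

#' Per-plot pellet densities with standard errors
#'
#' Mean pellet groups per plot with standard error (sample standard
#' deviation over the square root of the plot count) for every
#' habitat-by-species stratum, plus pooled `All` rows over all plots. The
#' SE of a single-plot stratum is undefined and reported `NA`.
#'
#' @param plots Plot table as produced by [latrine_rule()] or
#'   [generate_survey()]: `transect_id`, `habitat`, one count column per
#'   species.
#' @return data.frame `habitat`, `species`, `n_plots`, `mean_per_plot`,
#'   `se_per_plot`, `mean_per_ha`.
#' @export
density_per_plot <- function(plots) {
  sp <- species_columns(plots)
  if (!length(sp)) stop("no species columns in plots")
  strata <- c(split(plots, plots$habitat), list(All = plots))
  out <- do.call(rbind, lapply(names(strata), function(h) {
    d <- strata[[h]]
    do.call(rbind, lapply(sp, function(s) {
      x <- d[[s]]
      n <- length(x)
      data.frame(habitat = h, species = s, n_plots = n,
                 mean_per_plot = mean(x),
                 se_per_plot = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_)
    }))
  }))
  out$mean_per_ha <- density_per_hectare(out$mean_per_plot)
  rownames(out) <- NULL
  out
}

#' Convert per-plot pellet density to per-hectare
#'
#' Belt-transect plots are 10 m x 2 m (20 m²), so one hectare holds
#' exactly 500 plots: density per hectare is 500 times density per plot.
#'
#' @param x Mean pellet groups per plot (>= 0).
#' @return `500 * x`.
#' @export
density_per_hectare <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("densities must be >= 0")
  x * 500
}

#' Rank habitats by pellet density
#'
#' For each species, habitats are ranked by pellet density in decreasing
#' order: the densest habitat takes rank 1 and the lowest — including
#' zero density — the worst rank; ties share the mean of their rank
#' positions. Per-species ranks are summed into a cumulative rank per
#' habitat and habitats ordered ascending (lowest cumulative rank = most
#' preferred prey base).
#'
#' @param densities Either a habitat x species numeric matrix of
#'   densities, or the data.frame from [density_per_plot()] (the `All`
#'   rows are dropped and `mean_per_plot` used).
#' @return A list of class `habitat_ranking`: `ranks` (habitat x species
#'   matrix), `cumulative` (named vector), `order` (habitats, most
#'   preferred first).
#' @export
rank_habitats <- function(densities) {
  if (is.data.frame(densities)) {
    d <- densities[densities$habitat != "All", ]
    densities <- stats::xtabs(mean_per_plot ~ habitat + species, data = d)
    densities <- matrix(as.numeric(densities), nrow(densities),
                        ncol(densities), dimnames = dimnames(densities))
  }
  if (nrow(densities) < 2) stop("need at least two habitats to rank")
  ranks <- apply(densities, 2, function(x) rank(-x, ties.method = "average"))
  cumulative <- rowSums(ranks)
  ord <- names(sort(cumulative))
  structure(list(ranks = ranks, cumulative = cumulative, order = ord),
            class = "habitat_ranking")
}

#' @export
print.habitat_ranking <- function(x, ...) {
  cat("<habitat_ranking> most to least preferred:\n  ",
      paste(x$order, collapse = " > "), "\n")
  print(cbind(x$ranks, cumulative = x$cumulative))
  invisible(x)
}

#' Zero-count profile of a pellet survey
#'
#' Number and percentage of plots in which a species left no pellet
#' groups, per habitat and over all plots — a coarse relative-abundance
#' profile (the rarer the species, the higher its zero percentage).
#'
#' @inheritParams density_per_plot
#' @return data.frame `habitat` (including an `All` row set), `species`,
#'   `n_plots`, `n_zero`, `pct_zero`.
#' @export
zero_counts <- function(plots) {
  sp <- species_columns(plots)
  strata <- c(split(plots, plots$habitat), list(All = plots))
  out <- do.call(rbind, lapply(names(strata), function(h) {
    d <- strata[[h]]
    do.call(rbind, lapply(sp, function(s) {
      nz <- sum(d[[s]] == 0)
      data.frame(habitat = h, species = s, n_plots = nrow(d), n_zero = nz,
                 pct_zero = 100 * nz / nrow(d))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Read / write pellet-plot tables
#'
#' CSV exchange of plot tables (`transect_id`, `habitat`, one column per
#' species).
#'
#' @param plots Plot table.
#' @param path CSV file path.
#' @return `read_plots` returns the plot data.frame.
#' @export
write_plots <- function(plots, path) {
  utils::write.csv(plots, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plots
#' @export
read_plots <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
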