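#' Describe a synthetic two-park landscape
#'
#' Collects every knob of the seeded landscape generator: extent and
#' resolution, the two protected-area rectangles, the habitat mosaic
#' (per-class target fractions and an autocorrelation scale), road, rail,
#' settlement and water specifications, and two kinds of engineered
#' ground truth — a planted low-cost channel between the parks (the
#' generator then guarantees the channel is the unique cheap corridor)
#' and forest necks of known width (constrictions a weak-link analysis
#' must recover).
#'
#' @param seed Integer master seed; it is split deterministically per
#'   sub-generator, so one seed fixes every output bit-exactly.
#' @param extent_km `(width, height)` of the landscape in km.
#' @param cell_size Cell edge in metres.
#' @param park_A,park_B `(xmin, ymin, xmax, ymax)` rectangles in km.
#' @param habitat_fractions Named target class fractions (must sum to 1).
#' @param autocorr_km Smoothing scale of the habitat mosaic random field.
#' @param n_streams,n_tanks,n_road,n_settlement_clusters,
#'   settlement_cluster_size,population_range Infrastructure knobs.
#' @param planted_channel `NULL`, or `list(width_km =)` to plant a
#'   low-cost channel joining the two park peripheries.
#' @param necks `NULL`, or a list of `list(position =, width_km =,
#'   length_km =)` forest constrictions along the central spine
#'   (`position` is the fraction of the park-to-park distance).
#' @return A `landscape_scenario` list.
#' @export
landscape_scenario <- function(seed = 1,
                               extent_km = c(30, 20),
                               cell_size = 100,
                               park_A = c(1, 7, 4, 13),
                               park_B = c(26, 7, 29, 13),
                               habitat_fractions = c(
                                 "Non-Forest" = 0.25, "Miscellaneous" = 0.20,
                                 "Teak" = 0.12, "Teak Mixed" = 0.15,
                                 "Mixed Bamboo" = 0.15, "Bamboo Mixed" = 0.13),
                               autocorr_km = 1.5,
                               n_streams = 2, n_tanks = 8,
                               n_road = 3,
                               n_settlement_clusters = 6,
                               settlement_cluster_size = 8,
                               population_range = c(50, 2000),
                               planted_channel = NULL,
                               necks = NULL) {
  if (abs(sum(habitat_fractions) - 1) > 1e-8)
    stop("habitat_fractions must sum to 1")
  if (any(habitat_fractions < 0)) stop("habitat fractions must be >= 0")
  if (park_A[3] > park_B[1]) stop("parks must be disjoint (A west of B)")
  structure(as.list(environment()), class = "landscape_scenario")
}

sub_seed <- function(seed, k) as.integer((seed %% 1000003L) * 1009L + k)

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_filter <- function(x) {
    n <- length(x)
    xp <- c(rev(x[seq_len(r)]), x, rev(x[(n - r + 1):n]))
    as.numeric(stats::filter(xp, k, sides = 2))[(r + 1):(r + n)]
  }
  m <- apply(m, 2, pad_filter)
  t(apply(m, 1, pad_filter))
}

rect_mask <- function(rect_km, spec) {
  cc <- cell_centres(spec)
  xin <- cc$x >= rect_km[1] * 1000 & cc$x <= rect_km[3] * 1000
  yin <- cc$y >= rect_km[2] * 1000 & cc$y <= rect_km[4] * 1000
  outer(yin, xin) * 1
}

#' Generate a synthetic landscape
#'
#' Realises a [landscape_scenario()] into the full input bundle of the
#' corridor pipeline: a categorical habitat raster (thresholded smoothed
#' random field, class fractions matched by quantile construction), road,
#' rail, settlement, stream and tank vector layers, park masks, and the
#' start/destination cells for corridor tracing.
#'
#' With a planted channel the matrix is non-forest, the channel and parks
#' are prime habitat, water tanks flank the channel within a kilometre,
#' and all infrastructure sits far from it — so the channel cells carry
#' the best rank in every cost layer and any off-channel route is
#' strictly worse. With necks the matrix is uniform forest and non-forest
#' is carved outside a band of the stated width along the central spine,
#' giving a constriction of known ground-truth width.
#'
#' @param scn A [landscape_scenario()].
#' @return List with `habitat` (categorical `tc_grid`), layers `streams`,
#'   `waterbodies`, `roads`, `rail`, `settlements` ([vector_layer()]s),
#'   `park_A`, `park_B`, `channel` (binary `tc_grid`s or `NULL`),
#'   `start_cells` (3 x 2), `source_cell` (1 x 2), `spec`, `scenario`.
#' @export
generate_landscape <- function(scn) {
  stopifnot(inherits(scn, "landscape_scenario"))
  W <- scn$extent_km[1] * 1000
  H <- scn$extent_km[2] * 1000
  spec <- grid_spec(round(H / scn$cell_size), round(W / scn$cell_size),
                    scn$cell_size)
  levels <- c("Teak", "Miscellaneous", "Teak Mixed", "Bamboo Mixed",
              "Mixed Bamboo", "Non-Forest")
  parkA <- rect_mask(scn$park_A, spec)
  parkB <- rect_mask(scn$park_B, spec)
  y_mid <- (scn$park_A[2] + scn$park_A[4]) / 2 * 1000
  chan_from <- c(scn$park_A[3] * 1000, y_mid)
  chan_to <- c(scn$park_B[1] * 1000, y_mid)

  engineered <- !is.null(scn$planted_channel) || !is.null(scn$necks)
  channel <- NULL

  if (!is.null(scn$planted_channel)) {
    half_w <- scn$planted_channel$width_km * 1000 / 2
    centre <- vector_layer("polyline",
      list(list(geom = rbind(chan_from, chan_to), attrs = list())))
    dch <- euclidean_distance(rasterize(centre, spec, "presence"), spec)
    chan_mask <- (dch$values <= half_w) * 1
    lab <- matrix("Non-Forest", spec$n_rows, spec$n_cols)
    lab[chan_mask == 1 | parkA == 1 | parkB == 1] <- "Bamboo Mixed"
    habitat <- categorical_grid(lab, spec, levels = levels)
    channel <- new_grid(chan_mask, spec)
  } else if (!is.null(scn$necks)) {
    lab <- matrix("Bamboo Mixed", spec$n_rows, spec$n_cols)
    cc <- cell_centres(spec)
    span <- chan_to[1] - chan_from[1]
    for (nk in scn$necks) {
      x0 <- chan_from[1] + nk$position * span - nk$length_km * 500
      x1 <- x0 + nk$length_km * 1000
      wc <- round(nk$width_km * 1000 / spec$cell_size)
      crow <- xy_to_cell(chan_from[1], y_mid, spec)[1, "row"]
      keep_rows <- (crow - (wc %/% 2 - 1)):(crow + wc %/% 2)
      cols <- which(cc$x >= x0 & cc$x <= x1)
      cut_rows <- setdiff(seq_len(spec$n_rows), keep_rows)
      lab[cut_rows, cols] <- "Non-Forest"
    }
    habitat <- categorical_grid(lab, spec, levels = levels)
  } else {
    field <- with_seed(sub_seed(scn$seed, 1), {
      noise <- matrix(stats::rnorm(spec$n_rows * spec$n_cols),
                      spec$n_rows, spec$n_cols)
      gaussian_blur(noise, scn$autocorr_km * 1000 / spec$cell_size)
    })
    fr <- scn$habitat_fractions
    cuts <- stats::quantile(field, cumsum(fr)[-length(fr)])
    cls <- findInterval(field, cuts) + 1L
    lab <- matrix(names(fr)[cls], spec$n_rows, spec$n_cols)
    # parks are managed forest: no non-forest inside
    lab[(parkA == 1 | parkB == 1) & lab == "Non-Forest"] <- "Miscellaneous"
    habitat <- categorical_grid(lab, spec, levels = levels)
  }

  # --- water ------------------------------------------------------------
  if (engineered) {
    # tanks flanking the spine every 1.5 km, one cell-row outside a
    # planted channel (so no channel cell sits on water, all within 1 km)
    off <- if (!is.null(scn$planted_channel))
      scn$planted_channel$width_km * 1000 / 2 + 2 * spec$cell_size
    else 400
    xs <- seq(chan_from[1], chan_to[1], by = 1200)
    tanks <- unlist(lapply(xs, function(x) list(
      list(geom = matrix(c(x, y_mid + off), 1, 2), attrs = list()),
      list(geom = matrix(c(x, y_mid - off), 1, 2), attrs = list()))),
      recursive = FALSE)
    waterbodies <- vector_layer("point", tanks)
    streams <- vector_layer("polyline", list())
  } else {
    streams <- with_seed(sub_seed(scn$seed, 2), {
      feats <- lapply(seq_len(scn$n_streams), function(i) {
        x0 <- stats::runif(1, 0.15 * W, 0.85 * W)
        ys <- seq(H, 0, by = -500)
        xs <- x0 + cumsum(c(0, stats::rnorm(length(ys) - 1, 0, 200)))
        list(geom = cbind(pmin(pmax(xs, 0), W), ys), attrs = list())
      })
      vector_layer("polyline", feats)
    })
    waterbodies <- with_seed(sub_seed(scn$seed, 3), {
      vector_layer("point", lapply(seq_len(scn$n_tanks), function(i)
        list(geom = matrix(stats::runif(2, 0, 1) * c(W, H), 1, 2),
             attrs = list())))
    })
  }

  # --- infrastructure ----------------------------------------------------
  if (engineered) {
    far_y <- H - 1000
    roads <- vector_layer("polyline", list(
      list(geom = rbind(c(0, far_y), c(W, far_y)), attrs = list(pcu = 12000))))
    rail <- vector_layer("polyline", list(
      list(geom = rbind(c(0, 1000), c(W, 1000)), attrs = list())))
    settlements <- vector_layer("point", list(
      list(geom = matrix(c(W / 2, far_y - 500), 1, 2),
           attrs = list(population = 1500))))
  } else {
    roads <- with_seed(sub_seed(scn$seed, 4), {
      # daily traffic in passenger car units per segment: an interstate
      # highway, a state road and a minor road
      pcus <- c(12000, 7000, 3000)
      vector_layer("polyline", lapply(seq_len(scn$n_road), function(i) {
        x <- stats::runif(1, 0.2 * W, 0.8 * W)
        list(geom = rbind(c(x, H), c(x + stats::rnorm(1, 0, 1500), 0)),
             attrs = list(pcu = pcus[(i - 1) %% 3 + 1]))
      }))
    })
    rail <- vector_layer("polyline", list(
      list(geom = rbind(c(0.55 * W, H), c(0.6 * W, 0)), attrs = list())))
    settlements <- with_seed(sub_seed(scn$seed, 5), {
      feats <- list()
      for (k in seq_len(scn$n_settlement_clusters)) {
        ctr <- stats::runif(2, 0.05, 0.95) * c(W, H)
        for (j in seq_len(scn$settlement_cluster_size)) {
          p <- ctr + stats::rnorm(2, 0, 400)
          feats[[length(feats) + 1L]] <- list(
            geom = matrix(pmin(pmax(p, 0), c(W, H)), 1, 2),
            attrs = list(population = round(stats::runif(
              1, scn$population_range[1], scn$population_range[2]))))
        }
      }
      vector_layer("point", feats)
    })
  }

  crow <- xy_to_cell(chan_from[1], y_mid, spec)[1, "row"]
  acol <- xy_to_cell(chan_from[1], y_mid, spec)[1, "col"]
  bcol <- xy_to_cell(chan_to[1], y_mid, spec)[1, "col"]
  # engineered channels are >= 0.5 km wide, so +/- 2 cells stays inside
  doff <- if (engineered) 2L else round(1000 / spec$cell_size)
  start_cells <- cbind(row = c(crow, crow - doff, crow + doff),
                       col = rep(acol, 3))
  source_cell <- cbind(row = crow, col = bcol)

  list(habitat = habitat, streams = streams, waterbodies = waterbodies,
       roads = roads, rail = rail, settlements = settlements,
       park_A = new_grid(parkA, spec), park_B = new_grid(parkB, spec),
       channel = channel, start_cells = start_cells,
       source_cell = source_cell, spec = spec, scenario = scn)
}

#' Describe a synthetic pellet survey
#'
#' Defaults reproduce the field design: 79 belt transects of five
#' 10 m x 2 m plots each (395 plots), seven ungulate species, and
#' negative-binomial pellet-group counts whose mean is a per-(habitat,
#' species) intensity. The default intensity matrix plants a strict
#' habitat preference order (bamboo-dominated forest richest, pure teak
#' poorest) shared across species, the ground truth the ranking analysis
#' must recover.
#'
#' @param seed Integer seed.
#' @param n_transects,plots_per_transect Survey design counts.
#' @param species Species names.
#' @param intensity Habitat x species matrix of mean pellet groups per
#'   plot; `NULL` for [default_survey_intensity()].
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed; `Inf` gives Poisson counts).
#' @return A `survey_scenario` list.
#' @export
survey_scenario <- function(seed = 1, n_transects = 79,
                            plots_per_transect = 5,
                            species = c("chital", "sambar", "wild_boar",
                                        "gaur", "barking_deer", "chowsingha",
                                        "nilgai"),
                            intensity = NULL, dispersion = 0.6) {
  if (is.null(intensity)) intensity <- default_survey_intensity(species)
  if (any(intensity < 0)) stop("intensities must be >= 0")
  structure(list(seed = seed, n_transects = n_transects,
                 plots_per_transect = plots_per_transect, species = species,
                 intensity = intensity, dispersion = dispersion),
            class = "survey_scenario")
}

#' @rdname survey_scenario
#' @export
default_survey_intensity <- function(species = c("chital", "sambar",
                                                 "wild_boar", "gaur",
                                                 "barking_deer", "chowsingha",
                                                 "nilgai")) {
  hab_factor <- c("Bamboo Mixed" = 2.5, "Mixed Bamboo" = 1.4,
                  "Teak Mixed" = 1.1, "Miscellaneous" = 0.6, "Teak" = 0.25)
  sp_rate <- c(chital = 1.2, sambar = 0.5, wild_boar = 0.45, gaur = 0.3,
               barking_deer = 0.04, chowsingha = 0.1, nilgai = 0.12)
  rate <- sp_rate[species]
  rate[is.na(rate)] <- 0.2
  outer(hab_factor, rate)
}

#' Generate a synthetic pellet survey
#'
#' Places transects in forest, stratified across habitat classes roughly
#' in proportion to class area (largest-remainder allocation), and draws
#' per-plot pellet-group counts from a negative-binomial with the
#' scenario's per-(habitat, species) intensity.
#'
#' @param scn A [survey_scenario()].
#' @param habitat Categorical habitat `tc_grid` supplying the class
#'   areas; only forest classes are surveyed.
#' @return Plot data.frame: `transect_id`, `plot_id`, `habitat`, one
#'   count column per species (`n_transects * plots_per_transect` rows).
#' @export
generate_survey <- function(scn, habitat) {
  stopifnot(inherits(scn, "survey_scenario"))
  lab <- grid_labels(habitat)
  areas <- table(lab[lab != "Non-Forest"])
  if (!length(areas)) stop("no forest cells to survey")
  classes <- intersect(rownames(scn$intensity), names(areas))
  if (!length(classes)) stop("no surveyed class has an intensity")
  frac <- as.numeric(areas[classes]) / sum(areas[classes])
  alloc <- floor(frac * scn$n_transects)
  rem <- scn$n_transects - sum(alloc)
  if (rem > 0) {
    extra <- order(frac * scn$n_transects - alloc, decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1L
  }
  hab_per_transect <- rep(classes, alloc)
  with_seed(sub_seed(scn$seed, 11), {
    rows <- lapply(seq_len(scn$n_transects), function(t) {
      h <- hab_per_transect[t]
      mu <- scn$intensity[h, scn$species]
      counts <- vapply(seq_along(scn$species), function(s) {
        if (is.infinite(scn$dispersion))
          as.numeric(stats::rpois(scn$plots_per_transect, mu[s]))
        else
          as.numeric(stats::rnbinom(scn$plots_per_transect, mu = mu[s],
                                    size = scn$dispersion))
      }, numeric(scn$plots_per_transect))
      storage.mode(counts) <- "integer"
      df <- data.frame(transect_id = sprintf("T%03d", t),
                       plot_id = seq_len(scn$plots_per_transect),
                       habitat = h)
      df[scn$species] <- as.data.frame(counts)
      names(df)[-(1:3)] <- scn$species
      df
    })
    do.call(rbind, rows)
  })
}
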