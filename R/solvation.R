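## Water density grids, isopleth thresholds, and radial distribution
## functions.

#' Water-occupancy density grid
#'
#' Counts water-oxygen incidences per cell of a cubic lattice over the
#' analysed frames of one replicate (one grid per replicate). Frames are
#' first superposed on `fit_selection` (onto the replicate's first analysed
#' frame) when given. The grid origin is snapped to a multiple of the spacing
#' for reproducibility. The sum of all counts equals the number of
#' (water-oxygen, frame) incidences inside the grid bounds.
#'
#' @param ens An [ensemble()].
#' @param water_selection Selection of water oxygens (e.g.
#'   `"water and name O"`).
#' @param region List with `min` and `max` (length-3 Angstrom vectors), or a
#'   selection expression whose first-frame bounding box plus `margin` is
#'   used.
#' @param spacing Cell edge, Angstrom (default 0.33).
#' @param fit_selection Optional fit selection for pre-superposition.
#' @param margin Angstrom added around a selection-derived region.
#' @param equilibration Leading fraction of frames excluded.
#' @return List of `density_grid` objects (origin, spacing, dim, counts,
#'   n_frames), one per replicate.
#' @export
density_grid <- function(ens, water_selection, region, spacing = 0.33,
                         fit_selection = NULL, margin = 3,
                         equilibration = 0) {
  if (spacing <= 0) stop("spacing must be positive")
  wat <- resolve_sel(ens, water_selection)
  if (is.list(region)) {
    lo <- region$min; hi <- region$max
  } else {
    sel <- resolve_sel(ens, region)
    fr1 <- get_frame(ens, 1, 1)
    lo <- apply(fr1[sel, , drop = FALSE], 2, min) - margin
    hi <- apply(fr1[sel, , drop = FALSE], 2, max) + margin
  }
  if (any(hi <= lo)) stop("region volume must be positive")
  lo <- floor(lo / spacing) * spacing
  dims <- pmax(ceiling((hi - lo) / spacing), 1)
  fit <- if (is.null(fit_selection)) NULL else
    resolve_sel(ens, fit_selection)

  lapply(ens$replicates, function(arr) {
    keep <- analysis_frames(dim(arr)[1], equilibration)
    counts <- array(0L, dim = dims)
    ref <- matrix(arr[keep[1], , ], ncol = 3)
    for (f in keep) {
      fr <- matrix(arr[f, , ], ncol = 3)
      if (!is.null(fit)) fr <- apply_superpose(fr, superpose(fr, ref, fit))
      w <- fr[wat, , drop = FALSE]
      cell <- floor(sweep(w, 2, lo) / spacing) + 1
      inside <- cell[, 1] >= 1 & cell[, 1] <= dims[1] &
        cell[, 2] >= 1 & cell[, 2] <= dims[2] &
        cell[, 3] >= 1 & cell[, 3] <= dims[3]
      cell <- cell[inside, , drop = FALSE]
      if (nrow(cell) > 0) {
        for (k in seq_len(nrow(cell)))
          counts[cell[k, 1], cell[k, 2], cell[k, 3]] <-
            counts[cell[k, 1], cell[k, 2], cell[k, 3]] + 1L
      }
    }
    structure(list(origin = lo, spacing = spacing, dim = dims,
                   counts = counts, n_frames = length(keep)),
              class = "density_grid")
  })
}

#' Isopleth threshold of a density grid
#'
#' Threshold at `fraction` of the maximum cell occupancy (isopleths plotted
#' to encompass 80% of the maximum occupancy use `fraction = 0.8`).
#'
#' @param grid A `density_grid`.
#' @param fraction Fraction of the maximum count, in `(0, 1]`.
#' @return List: `threshold` (count) and `mask` (logical array, cells with
#'   count >= threshold).
#' @export
isopleth_threshold <- function(grid, fraction = 0.8) {
  stopifnot(inherits(grid, "density_grid"))
  mx <- max(grid$counts)
  if (mx == 0) stop("all-zero density grid")
  thr <- fraction * mx
  list(threshold = thr, mask = grid$counts >= thr)
}

#' Write a density grid as an OpenDX scalar field
#'
#' Plain-text OpenDX regular-grid format readable by standard molecular
#' viewers.
#'
#' @param grid A `density_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  d <- grid$dim
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %.4f 0 0", grid$spacing),
    sprintf("delta 0 %.4f 0", grid$spacing),
    sprintf("delta 0 0 %.4f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  ## DX lists counts[x,y,z] with z varying fastest
  vals <- as.numeric(grid$counts[cbind(
    rep(seq_len(d[1]), each = d[2] * d[3]),
    rep(rep(seq_len(d[2]), each = d[3]), d[1]),
    rep(seq_len(d[3]), d[1] * d[2]))])
  pad <- (3 - length(vals) %% 3) %% 3
  vals3 <- matrix(c(vals, rep(NA, pad)), ncol = 3, byrow = TRUE)
  lines <- apply(vals3, 1, function(v)
    paste(format(v[!is.na(v)], trim = TRUE), collapse = " "))
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  writeLines('object "density" class field', con)
  invisible(path)
}

#' Radial distribution function of water oxygens around a center atom
#'
#' `g(r) = <n(r, r + dr)> / (rho_ref * 4 pi r^2 dr)`. For periodic systems
#' (topology carries a box) distances use the minimum image and
#' `rho_ref = N / V`; for non-periodic systems the reference density is
#' count-matched to the enclosing `r_max` sphere, frame-averaged.
#'
#' @param ens An [ensemble()].
#' @param center Selection resolving to exactly one atom.
#' @param water_oxygens Selection of water oxygen atoms.
#' @param dr Bin width, Angstrom.
#' @param r_max Maximum radius, Angstrom.
#' @param equilibration Leading fraction of frames excluded.
#' @return Object of class `rdf`: `r` (bin centers), `g` (matrix bins x
#'   replicates), `mean`, `sem`, `reference_density`.
#' @export
rdf <- function(ens, center, water_oxygens, dr = 0.1, r_max = 8,
                equilibration = 0) {
  if (dr <= 0) stop("dr must be positive")
  ctr <- resolve_sel(ens, center)
  if (length(ctr) != 1) stop("center must resolve to exactly one atom")
  wat <- resolve_sel(ens, water_oxygens)
  box <- attr(ens$topology, "box")
  breaks <- seq(0, r_max, by = dr)
  mids <- breaks[-1] - dr / 2
  shell_vol <- 4 * pi * mids^2 * dr

  per_rep <- lapply(ens$replicates, function(arr) {
    keep <- analysis_frames(dim(arr)[1], equilibration)
    counts <- numeric(length(mids))
    rho_acc <- 0
    for (f in keep) {
      fr <- matrix(arr[f, , ], ncol = 3)
      dvec <- sweep(fr[wat, , drop = FALSE], 2, fr[ctr, ])
      if (!is.null(box)) {
        for (k in 1:3) dvec[, k] <- dvec[, k] - box[k] * round(dvec[, k] / box[k])
      }
      d <- sqrt(rowSums(dvec^2))
      h <- graphics::hist(d[d < r_max], breaks = breaks, plot = FALSE)$counts
      counts <- counts + h
      rho_acc <- rho_acc + if (!is.null(box)) length(wat) / prod(box) else
        sum(d < r_max) / (4 / 3 * pi * r_max^3)
    }
    nfr <- length(keep)
    rho <- rho_acc / nfr
    list(g = (counts / nfr) / (rho * shell_vol), rho = rho)
  })
  g <- vapply(per_rep, `[[`, numeric(length(mids)), "g")
  g <- matrix(g, nrow = length(mids))
  n <- ncol(g)
  sem <- if (n >= 2) apply(g, 1, stats::sd) / sqrt(n) else
    rep(NA_real_, nrow(g))
  structure(list(r = mids, g = g, mean = rowMeans(g), sem = sem,
                 reference_density = mean(vapply(per_rep, `[[`,
                                                 numeric(1), "rho"))),
            class = "rdf")
}
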