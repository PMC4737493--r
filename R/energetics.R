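## Effective binding-energy aggregation (1-trajectory convention), drift
## diagnostics, relative binding energies with error propagation, and
## thermodynamic conversion to association-constant changes.

KCAL_COULOMB <- 332.0637   # kcal*A/(mol*e^2)
GAS_CONSTANT <- 1.9872e-3  # kcal/(mol*K)

#' Effective-energy time series container
#'
#' Per-frame effective energies with a strictly increasing ns time axis;
#' optional per-frame components (gas-phase MM, polar, nonpolar solvation)
#' must sum to the values.
#'
#' @param time_ns Time axis, ns, strictly increasing.
#' @param value Per-frame effective energies, kcal/mol.
#' @param components Optional data frame with columns `e_mm`, `g_polar`,
#'   `g_nonpolar`.
#' @return Object of class `energy_series`.
#' @export
energy_series <- function(time_ns, value, components = NULL) {
  stopifnot(length(time_ns) == length(value), all(diff(time_ns) > 0))
  if (!is.null(components)) {
    stopifnot(nrow(components) == length(value))
    recon <- rowSums(components[, c("e_mm", "g_polar", "g_nonpolar")])
    if (max(abs(recon - value)) > 1e-6)
      stop("components do not sum to the effective energies")
  }
  structure(list(time_ns = as.numeric(time_ns), value = as.numeric(value),
                 components = components),
            class = "energy_series")
}

#' @export
print.energy_series <- function(x, ...) {
  cat(sprintf("energy series: %d frames over %.3g ns, mean %.3f kcal/mol\n",
              length(x$value), max(x$time_ns) - min(x$time_ns),
              mean(x$value)))
  invisible(x)
}

## Shrake-Rupley solvent-accessible surface area (A^2) per atom
sasa <- function(coords, elements, probe = 1.4, n_points = 92) {
  radii <- vdw_radius(elements) + probe
  n <- nrow(coords)
  ## deterministic quasi-uniform sphere points (golden-section spiral)
  k <- seq_len(n_points)
  phi <- acos(1 - 2 * (k - 0.5) / n_points)
  theta <- pi * (1 + sqrt(5)) * (k - 0.5)
  sphere <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  out <- numeric(n)
  d <- pairwise_dist(coords, coords)
  for (i in seq_len(n)) {
    pts <- sweep(sphere * radii[i], 2, coords[i, ], "+")
    nb <- which(d[i, ] < radii[i] + max(radii) & seq_len(n) != i)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- sqrt(rowSums(sweep(pts, 2, coords[j, ])^2))
      exposed <- exposed & dj >= radii[j]
      if (!any(exposed)) break
    }
    out[i] <- 4 * pi * radii[i]^2 * sum(exposed) / n_points
  }
  out
}

vdw_radius <- function(elements) {
  tab <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, P = 1.8, S = 1.8,
           MG = 1.73, CL = 1.75, NA_ = 2.27)
  r <- tab[ifelse(elements == "NA", "NA_", elements)]
  r[is.na(r)] <- 1.7
  unname(r)
}

## interaction energy between two atom groups for one frame: screened
## Coulomb (uniform interior dielectric) + Lennard-Jones (when parameters
## are present)
toy_interaction <- function(coords, top, rec, lig, dielectric = 4) {
  qr <- top$charge[rec]; ql <- top$charge[lig]
  if (anyNA(qr) || anyNA(ql))
    stop("toy energy model requires partial charges on all selected atoms")
  d <- pairwise_dist(coords[rec, , drop = FALSE],
                     coords[lig, , drop = FALSE])
  e_coul <- KCAL_COULOMB * sum(outer(qr, ql) / (dielectric * d))
  e_lj <- 0
  if (!all(is.na(top$vdw_rmin[c(rec, lig)]))) {
    rm <- outer(top$vdw_rmin[rec], top$vdw_rmin[lig], "+")
    ep <- sqrt(outer(top$vdw_eps[rec], top$vdw_eps[lig]))
    ok <- is.finite(rm) & is.finite(ep)
    if (any(ok)) {
      sr6 <- (rm[ok] / d[ok])^6
      e_lj <- sum(ep[ok] * (sr6^2 - 2 * sr6))
    }
  }
  c(coul = e_coul, lj = e_lj)
}

#' Per-frame effective binding-energy series
#'
#' 1-trajectory aggregation: complex, receptor, and ligand snapshots all come
#' from the complex trajectory, so
#' `dG_frame = E(complex) - E(receptor) - E(ligand)`. Two energy models:
#'
#' * `"toy"`: screened Coulomb interaction at a uniform interior dielectric
#'   (default 4, the convention for highly charged binding sites) plus
#'   Lennard-Jones when van-der-Waals parameters are present, plus a
#'   nonpolar surface term `gamma * dSASA` with `gamma = 0.00542`
#'   kcal/mol/A^2 (the surface-area pairing conventional for Parse radii;
#'   the intercept `beta = 0.92` kcal/mol cancels nowhere in the
#'   complex-minus-parts difference and is deliberately excluded so that
#'   non-interacting separated partners score exactly zero). This is a
#'   documented toy model, not a Poisson-Boltzmann solver; solver output is
#'   ingested via `model = "table"`.
#' * `"table"`: pass-through of an external per-frame component table
#'   (columns `frame`, `time_ns`, `e_mm`, `g_polar`, `g_nonpolar`) with
#'   validation against the ensemble frame count.
#'
#' @param ens An [ensemble()] (one replicate analysed per call index) or a
#'   list; all replicates are processed.
#' @param receptor_selection,ligand_selection Disjoint selections
#'   partitioning the solute.
#' @param model `"toy"` or `"table"`.
#' @param table For `model = "table"`: data frame or path to a CSV per-frame
#'   component table (one per replicate when a list).
#' @param dielectric Interior dielectric for the toy Coulomb term.
#' @param gamma_np Nonpolar surface coefficient, kcal/mol/A^2.
#' @param include_sasa Include the `gamma * dSASA` term (default `TRUE`).
#' @return List of [energy_series()], one per replicate.
#' @export
effective_energy_series <- function(ens, receptor_selection, ligand_selection,
                                    model = c("toy", "table"), table = NULL,
                                    dielectric = 4, gamma_np = 0.00542,
                                    include_sasa = TRUE) {
  model <- match.arg(model)
  top <- ens$topology
  rec <- resolve_sel(ens, receptor_selection)
  lig <- resolve_sel(ens, ligand_selection)
  if (length(intersect(rec, lig)) > 0)
    stop("receptor and ligand selections must be disjoint")

  if (model == "table") {
    tabs <- if (is.data.frame(table)) list(table) else
      if (is.character(table)) lapply(table, utils::read.csv) else table
    if (length(tabs) != length(ens$replicates))
      stop("need one component table per replicate")
    return(lapply(seq_along(tabs), function(r) {
      tb <- tabs[[r]]
      need <- c("frame", "time_ns", "e_mm", "g_polar", "g_nonpolar")
      if (!all(need %in% names(tb)))
        stop("component table must have columns: ",
             paste(need, collapse = ", "))
      if (nrow(tb) != dim(ens$replicates[[r]])[1])
        stop("table/ensemble frame-count mismatch in replicate ", r,
             " (", nrow(tb), " vs ", dim(ens$replicates[[r]])[1], ")")
      energy_series(tb$time_ns, tb$e_mm + tb$g_polar + tb$g_nonpolar,
                    components = tb[, c("e_mm", "g_polar", "g_nonpolar")])
    }))
  }

  lapply(ens$replicates, function(arr) {
    nf <- dim(arr)[1]
    t_ns <- (seq_len(nf) - 1) * ens$frame_interval / 1000
    v <- vapply(seq_len(nf), function(f) {
      fr <- matrix(arr[f, , ], ncol = 3)
      e <- toy_interaction(fr, top, rec, lig, dielectric)
      e_np <- 0
      if (include_sasa) {
        both <- c(rec, lig)
        s_cplx <- sum(sasa(fr[both, , drop = FALSE], top$element[both]))
        s_rec <- sum(sasa(fr[rec, , drop = FALSE], top$element[rec]))
        s_lig <- sum(sasa(fr[lig, , drop = FALSE], top$element[lig]))
        e_np <- gamma_np * (s_cplx - s_rec - s_lig)
      }
      sum(e) + e_np
    }, numeric(1))
    energy_series(t_ns, v)
  })
}

#' Least-squares drift slope of an energy series
#'
#' Ordinary least-squares slope of the effective energy versus time; the
#' magnitude of the drift over the analysed interval is the standard
#' convergence diagnostic for ensemble-averaged effective energies.
#'
#' @param series An [energy_series()].
#' @return Slope, kcal/mol/ns.
#' @export
drift_slope <- function(series) {
  stopifnot(inherits(series, "energy_series"), length(series$value) >= 2)
  if (stats::var(series$time_ns) == 0) stop("constant time axis")
  unname(stats::coef(stats::lm(series$value ~ series$time_ns))[2])
}

#' Mean effective binding energy with replicate error propagation
#'
#' Per replicate: the frame mean, its SEM (block averaging over `blocks`
#' blocks by default, to respect frame autocorrelation; `estimator =
#' "naive"` uses sd/sqrt(n)), and the drift slope. Replicate SEMs are
#' combined by root-sum-square error propagation,
#' `SEM = sqrt(SEM1^2 + SEM2^2 + SEM3^2)`.
#'
#' @param series_list List of [energy_series()] (one per replicate).
#' @param blocks Number of blocks for the block-averaged SEM.
#' @param estimator `"block"` or `"naive"`.
#' @return Object of class `binding_energy`: `per_replicate` (data frame
#'   with mean, sem, slope, n_frames), `mean` (grand mean of replicate
#'   means, kcal/mol), `sem` (root-sum-square of replicate SEMs),
#'   `n_replicates`.
#' @export
mean_binding_energy <- function(series_list, blocks = 5,
                                estimator = c("block", "naive")) {
  estimator <- match.arg(estimator)
  if (inherits(series_list, "energy_series")) series_list <- list(series_list)
  per <- lapply(series_list, function(s) {
    v <- s$value
    n <- length(v)
    sem <- if (estimator == "naive" || n < 2 * blocks) {
      stats::sd(v) / sqrt(n)
    } else {
      bm <- tapply(v, cut(seq_len(n), blocks, labels = FALSE), mean)
      stats::sd(bm) / sqrt(blocks)
    }
    data.frame(mean = mean(v), sem = sem, slope = drift_slope(s),
               n_frames = n)
  })
  per <- do.call(rbind, per)
  structure(list(per_replicate = per,
                 mean = mean(per$mean),
                 sem = sqrt(sum(per$sem^2)),
                 n_replicates = nrow(per)),
            class = "binding_energy")
}

#' @export
print.binding_energy <- function(x, ...) {
  cat(sprintf("effective binding energy: %.3f +/- %.3f kcal/mol (%d replicates)\n",
              x$mean, x$sem, x$n_replicates))
  invisible(x)
}

#' Relative effective binding energy (mutant minus wild type)
#'
#' Per-replicate differences `ddG_k = dG_mutant,k - dG_wildtype,k` matched by
#' replicate index; the reported ddG is their mean,
#' `SEM_total = sqrt(SEM_mutant^2 + SEM_wildtype^2)` by error propagation,
#' and significance is a one-sample t-test of the replicate differences
#' against 0. Positive ddG means weaker binding in the mutant. Swapping the
#' labels negates ddG and preserves `sem_total` and `p`.
#'
#' @param mutant,wildtype `binding_energy` objects with equal replicate
#'   counts.
#' @param labels Character vector `c(mutant, wildtype)` used for printing.
#' @return Object of class `relative_binding_energy`: `ddg`, `sem_total`,
#'   `p`, `t`, `per_replicate_ddg`, `labels`.
#' @export
delta_delta_g <- function(mutant, wildtype,
                          labels = c("mutant", "wild type")) {
  stopifnot(inherits(mutant, "binding_energy"),
            inherits(wildtype, "binding_energy"))
  if (mutant$n_replicates != wildtype$n_replicates)
    stop("replicate count mismatch (", mutant$n_replicates, " vs ",
         wildtype$n_replicates, ")")
  d <- mutant$per_replicate$mean - wildtype$per_replicate$mean
  tt <- if (length(d) >= 2) {
    tryCatch(one_sample_t(d, 0),
             error = function(e) list(t = NA_real_, p = NA_real_))
  } else list(t = NA_real_, p = NA_real_)
  structure(list(ddg = mean(d),
                 sem_total = sqrt(mutant$sem^2 + wildtype$sem^2),
                 p = tt$p, t = tt$t,
                 per_replicate_ddg = d, labels = labels),
            class = "relative_binding_energy")
}

#' @export
print.relative_binding_energy <- function(x, ...) {
  cat(sprintf("ddG(%s - %s) = %.3f +/- %.3f kcal/mol, p = %.3g\n",
              x$labels[1], x$labels[2], x$ddg, x$sem_total, x$p))
  invisible(x)
}

#' Convert a ddG to an association-constant change
#'
#' `fold = exp(ddG / (R T))` and `log10_units = ddG / (ln 10 * R T)` with
#' `R = 1.9872e-3 kcal/(mol K)`. A positive ddG (weaker binding in the
#' mutant) gives `fold > 1`, i.e. an x-fold decrease of the association
#' constant.
#'
#' @param ddg Relative binding energy, kcal/mol (numeric or a
#'   `relative_binding_energy`).
#' @param temperature Kelvin (default 300).
#' @return List: `fold` (fold change of the association constant) and
#'   `log10_units` (the same change in log10 units).
#' @export
kassoc_change <- function(ddg, temperature = 300) {
  if (inherits(ddg, "relative_binding_energy")) ddg <- ddg$ddg
  stopifnot(temperature > 0)
  rt <- GAS_CONSTANT * temperature
  list(fold = exp(ddg / rt), log10_units = ddg / (log(10) * rt))
}
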