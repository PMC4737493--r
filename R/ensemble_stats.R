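## RMSD/RMSF/distance statistics over replicated ensembles, with the
## replicate-mean +/- SEM convention: per-replicate means are the
## observations, SEM = sd(means)/sqrt(n_replicates).

#' Replicate summary statistic
#'
#' Treats per-replicate means as the observations of a small sample, as when
#' results from three independent trajectories are expressed as mean +/- SEM.
#'
#' @param per_replicate_means Numeric vector of per-replicate means.
#' @return Object of class `replicate_stat`: `per_replicate_means`,
#'   `grand_mean`, `sem`, `n_replicates`. `sem` is `NA` for a single
#'   replicate.
#' @export
replicate_stat <- function(per_replicate_means) {
  m <- as.numeric(per_replicate_means)
  n <- length(m)
  sem <- if (n >= 2) stats::sd(m) / sqrt(n) else NA_real_
  structure(list(per_replicate_means = m, grand_mean = mean(m),
                 sem = sem, n_replicates = n),
            class = "replicate_stat")
}

#' @export
print.replicate_stat <- function(x, ...) {
  cat(sprintf("%.4g +/- %.4g (SEM, n = %d replicates)\n",
              x$grand_mean, x$sem, x$n_replicates))
  invisible(x)
}

resolve_sel <- function(ens, sel) {
  if (is.null(sel)) seq_len(nrow(ens$topology)) else
    select_atoms(ens$topology, sel)
}

#' Per-frame RMSD series
#'
#' Each frame is superposed on the reference over `fit_selection`, then the
#' RMSD is measured over `measure_selection` (they may differ, e.g. ligand
#' RMSD after a protein fit). Per-replicate means discard the equilibration
#' fraction.
#'
#' @param ens An [ensemble()].
#' @param fit_selection,measure_selection Selection expressions or index
#'   vectors; `NULL` = all atoms. `measure_selection` defaults to the fit
#'   selection.
#' @param reference `"first"` (first frame of each replicate's own series is
#'   replaced by the first frame of replicate 1) or a coordinate matrix.
#' @param equilibration Leading fraction of frames excluded from the means.
#' @return List: `series` (list of per-frame RMSD vectors per replicate),
#'   `time_ns`, `per_replicate_mean`, and `stat` (a [replicate_stat()]).
#' @export
rmsd_series <- function(ens, fit_selection = NULL, measure_selection = NULL,
                        reference = "first", equilibration = 0.2) {
  fit <- resolve_sel(ens, fit_selection)
  msel <- if (is.null(measure_selection)) fit else
    resolve_sel(ens, measure_selection)
  if (length(fit) == 0 || length(msel) == 0) stop("empty selection")
  ref <- if (is.matrix(reference)) reference else get_frame(ens, 1, 1)
  series <- lapply(ens$replicates, function(arr) {
    nf <- dim(arr)[1]
    vapply(seq_len(nf), function(f) {
      fr <- matrix(arr[f, , ], ncol = 3)
      sp <- superpose(fr, ref, fit)
      rmsd_between(apply_superpose(fr, sp)[msel, , drop = FALSE],
                   ref[msel, , drop = FALSE])
    }, numeric(1))
  })
  means <- vapply(series, function(s)
    mean(s[analysis_frames(length(s), equilibration)]), numeric(1))
  list(series = series,
       time_ns = lapply(series, function(s)
         (seq_along(s) - 1) * ens$frame_interval / 1000),
       per_replicate_mean = means,
       stat = replicate_stat(means))
}

#' Root mean-square fluctuation
#'
#' RMSF of atom i is `sqrt(<|r_i - <r_i>|^2>)` after superposing every frame
#' onto the (iterated) ensemble mean structure over `fit_selection`. Residue
#' mode averages atom RMSFs within each residue. Replicates are analysed
#' independently; the result carries mean +/- SEM across replicates.
#'
#' @param ens An [ensemble()].
#' @param selection Atoms to report (expression or indices; `NULL` = all).
#' @param per `"atom"` or `"residue"`.
#' @param fit_selection Fit atoms (default: the reported selection).
#' @param iterations Mean-structure refinement iterations (default 2).
#' @param equilibration Leading fraction of frames discarded.
#' @return List: `rmsf` (matrix, units x replicates), `mean`, `sem`,
#'   `resid` (residue serials in residue mode), `selection`.
#' @export
rmsf <- function(ens, selection = NULL, per = c("atom", "residue"),
                 fit_selection = NULL, iterations = 2, equilibration = 0.2) {
  per <- match.arg(per)
  sel <- resolve_sel(ens, selection)
  fit <- if (is.null(fit_selection)) sel else resolve_sel(ens, fit_selection)
  if (any(n_frames(ens) < 2)) stop("RMSF needs at least 2 frames")

  per_rep <- lapply(ens$replicates, function(arr) {
    nf <- dim(arr)[1]
    keep <- analysis_frames(nf, equilibration)
    frames <- lapply(keep, function(f) matrix(arr[f, , ], ncol = 3))
    ref <- frames[[1]]
    for (it in seq_len(iterations)) {
      fitted <- lapply(frames, function(fr)
        apply_superpose(fr, superpose(fr, ref, fit)))
      ref <- Reduce(`+`, fitted) / length(fitted)
    }
    fitted <- lapply(frames, function(fr)
      apply_superpose(fr, superpose(fr, ref, fit)))
    mean_xyz <- Reduce(`+`, fitted) / length(fitted)
    msd <- Reduce(`+`, lapply(fitted, function(fr)
      rowSums((fr - mean_xyz)^2))) / length(fitted)
    sqrt(msd)[sel]
  })
  rm_atom <- do.call(cbind, per_rep)

  if (per == "residue") {
    key <- paste(ens$topology$chain[sel], ens$topology$resid[sel])
    ukey <- unique(key)
    rm_res <- do.call(rbind, lapply(ukey, function(k)
      colMeans(rm_atom[key == k, , drop = FALSE])))
    resid <- ens$topology$resid[sel][match(ukey, key)]
    out <- rm_res
  } else {
    resid <- ens$topology$resid[sel]
    out <- rm_atom
  }
  n <- ncol(out)
  sem <- if (n >= 2) apply(out, 1, stats::sd) / sqrt(n) else
    rep(NA_real_, nrow(out))
  list(rmsf = out, mean = rowMeans(out), sem = sem, resid = resid,
       selection = sel, per = per)
}

#' Core-region residues (lowest-RMSF fraction)
#'
#' The core region comprises the `keep_fraction` of residues with the lowest
#' RMSF; ties are broken by ascending residue serial for determinism.
#'
#' @param rmsf_per_residue Numeric RMSF values.
#' @param resid Residue serials matching `rmsf_per_residue`.
#' @param keep_fraction Fraction in `(0, 1]` (default 0.9).
#' @return Residue serials of the core region (floor(fraction * N) of them).
#' @export
core_region <- function(rmsf_per_residue, resid = seq_along(rmsf_per_residue),
                        keep_fraction = 0.9) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  if (length(rmsf_per_residue) == 0) stop("empty RMSF input")
  k <- floor(keep_fraction * length(rmsf_per_residue))
  ord <- order(rmsf_per_residue, resid)
  sort(resid[ord[seq_len(k)]])
}

#' Distance series between two atom groups
#'
#' @param ens An [ensemble()].
#' @param group_a,group_b Selections (expressions or indices).
#' @param mode `"centroid"` (centroid-to-centroid) or `"min"` (closest pair).
#' @param equilibration Leading fraction of frames excluded from means.
#' @return List: `series` per replicate (Angstrom), `per_replicate_mean`,
#'   `stat` ([replicate_stat()]).
#' @export
distance_series <- function(ens, group_a, group_b,
                            mode = c("centroid", "min"),
                            equilibration = 0.2) {
  mode <- match.arg(mode)
  a <- resolve_sel(ens, group_a)
  b <- resolve_sel(ens, group_b)
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  if (length(intersect(a, b)) > 0)
    warning("groups overlap; distance still computed")
  series <- lapply(ens$replicates, function(arr) {
    nf <- dim(arr)[1]
    vapply(seq_len(nf), function(f) {
      fr <- matrix(arr[f, , ], ncol = 3)
      if (mode == "centroid") {
        sqrt(sum((colMeans(fr[a, , drop = FALSE]) -
                    colMeans(fr[b, , drop = FALSE]))^2))
      } else {
        min(pairwise_dist(fr[a, , drop = FALSE], fr[b, , drop = FALSE]))
      }
    }, numeric(1))
  })
  means <- vapply(series, function(s)
    mean(s[analysis_frames(length(s), equilibration)]), numeric(1))
  list(series = series, per_replicate_mean = means,
       stat = replicate_stat(means))
}

pairwise_dist <- function(A, B) {
  ## |a-b| for all pairs; A is n x 3, B is m x 3
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}
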