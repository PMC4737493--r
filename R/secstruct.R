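## Secondary-structure assignment restricted to helix classes.
##
## Backbone hydrogen bonds are scored with the Kabsch-Sander electrostatic
## energy E = 0.084 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) * 332 kcal/mol,
## bond present iff E < -0.5 kcal/mol. A residue is labelled:
##   H  if its carbonyl accepts the i -> i+4 turn bond,
##   G  if (no 4-turn) its carbonyl accepts the i -> i+3 bond,
##   L  otherwise.
## Strand/bridge classes are not assigned; the analysis contrasts helix
## against loop only. Amide hydrogens are reconstructed geometrically when
## absent (N-H along the bisector opposite the preceding carbonyl).

ks_energy <- function(C, O, N, H) {
  r <- function(a, b) sqrt(sum((a - b)^2))
  0.084 * (1 / r(O, N) + 1 / r(C, H) - 1 / r(O, H) - 1 / r(C, N)) * 332
}

#' Assign secondary structure for one frame
#'
#' @param top A [topology()] with backbone N, CA, C, O atoms.
#' @param coords Coordinate matrix matching `top`.
#' @param chain Chain to assign (default: first protein chain).
#' @param energy_cut Hydrogen-bond energy threshold, kcal/mol (bond iff
#'   E < `energy_cut`).
#' @return Character vector, one class in `{H, G, L}` per residue of the
#'   chain; names are residue serials. Residues with missing backbone atoms
#'   are forced to `L` with a warning.
#' @export
assign_ss <- function(top, coords, chain = NULL, energy_cut = -0.5) {
  if (is.null(chain)) chain <- top$chain[which(top$name == "CA")[1]]
  in_ch <- top$chain == chain
  resids <- sort(unique(top$resid[in_ch & top$name == "CA"]))
  n <- length(resids)
  idx_of <- function(resid, name) {
    w <- which(in_ch & top$resid == resid & top$name == name)
    if (length(w) == 0) NA_integer_ else w[1]
  }
  Ni <- vapply(resids, idx_of, integer(1), name = "N")
  CAi <- vapply(resids, idx_of, integer(1), name = "CA")
  Ci <- vapply(resids, idx_of, integer(1), name = "C")
  Oi <- vapply(resids, idx_of, integer(1), name = "O")
  Hi <- vapply(resids, idx_of, integer(1), name = "H")

  missing_bb <- is.na(Ni) | is.na(CAi) | is.na(Ci) | is.na(Oi)
  if (any(missing_bb))
    warning("residues with missing backbone atoms forced to L: ",
            paste(resids[missing_bb], collapse = ", "))

  Hxyz <- matrix(NA_real_, n, 3)
  for (k in 2:n) {
    if (!is.na(Hi[k])) {
      Hxyz[k, ] <- coords[Hi[k], ]
    } else if (!missing_bb[k] && !missing_bb[k - 1]) {
      Nk <- coords[Ni[k], ]
      Hxyz[k, ] <- Nk + 0.98 * unitv(unitv(Nk - coords[Ci[k - 1], ]) +
                                       unitv(Nk - coords[CAi[k], ]))
    }
  }

  turn_bond <- function(i, delta) {
    j <- i + delta
    if (j > n || missing_bb[i] || missing_bb[j] || anyNA(Hxyz[j, ]))
      return(FALSE)
    ks_energy(coords[Ci[i], ], coords[Oi[i], ], coords[Ni[j], ],
              Hxyz[j, ]) < energy_cut
  }

  cls <- rep("L", n)
  for (i in seq_len(n)) {
    if (missing_bb[i]) next
    if (turn_bond(i, 4L)) cls[i] <- "H"
    else if (turn_bond(i, 3L)) cls[i] <- "G"
  }
  names(cls) <- resids
  cls
}

#' Per-residue loop probability across an ensemble
#'
#' Fraction of analysed frames in which a residue is assigned class `L`
#' (optionally counting 3-10 helix `G` as loop), with SEM across replicates.
#'
#' @param ens An [ensemble()].
#' @param residues Residue serials to report (default: all assignable).
#' @param chain Chain to analyse.
#' @param count_310_as_loop Whether `G` counts as loop (default `FALSE`).
#' @param equilibration Leading fraction of frames excluded.
#' @return List: `resid`, `loop_prob` (matrix residues x replicates), `mean`,
#'   `sem`, plus `class_fractions` (per-residue mean H/G/L fractions).
#' @export
loop_probability <- function(ens, residues = NULL, chain = NULL,
                             count_310_as_loop = FALSE, equilibration = 0) {
  top <- ens$topology
  per_rep <- lapply(ens$replicates, function(arr) {
    nf <- dim(arr)[1]
    keep <- analysis_frames(nf, equilibration)
    cls <- vapply(keep, function(f)
      assign_ss(top, matrix(arr[f, , ], ncol = 3), chain = chain),
      character(length(unique(top$resid[top$name == "CA"]))))
    cls   # residues x frames
  })
  resids <- as.integer(rownames(per_rep[[1]]) %||%
                         names(assign_ss(top, get_frame(ens, 1, 1),
                                         chain = chain)))
  loop_classes <- if (count_310_as_loop) c("L", "G") else "L"
  lp <- vapply(per_rep, function(m) rowMeans(matrix(m %in% loop_classes,
                                                    nrow = nrow(m))),
               numeric(length(resids)))
  lp <- matrix(lp, nrow = length(resids))
  rownames(lp) <- resids
  frac <- function(code) rowMeans(vapply(per_rep, function(m)
    rowMeans(matrix(m == code, nrow = nrow(m))), numeric(length(resids))))
  if (!is.null(residues)) {
    keep <- resids %in% residues
  } else keep <- rep(TRUE, length(resids))
  n <- ncol(lp)
  sem <- if (n >= 2) apply(lp, 1, stats::sd) / sqrt(n) else
    rep(NA_real_, nrow(lp))
  list(resid = resids[keep],
       loop_prob = lp[keep, , drop = FALSE],
       mean = rowMeans(lp)[keep],
       sem = sem[keep],
       class_fractions = cbind(H = frac("H"), G = frac("G"),
                               L = frac("L"))[keep, , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
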