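#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference` over the selected
#' atoms, via the SVD construction. The returned RMSD is the global minimum
#' over rigid motions; `det(rotation) = +1` (proper rotation).
#'
#' @param mobile,reference Coordinate matrices `n_atoms x 3`.
#' @param selection Atom indices used for the fit (default: all). At least 3
#'   non-collinear atoms are required.
#' @return Object of class `superpose`: list with `rotation` (3x3),
#'   `translation` (length 3; the fitted coordinates are
#'   `coords %*% t(rotation) + translation`), and `rmsd` (Angstrom, over the
#'   fit selection).
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3) stop("need at least 3 atoms to superpose")
  P <- mobile[selection, , drop = FALSE]
  Q <- reference[selection, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  ## collinearity check: rank of the centered selection must be >= 2
  sv_p <- svd(Pc)$d
  if (sv_p[2] < 1e-8 * max(sv_p[1], 1))
    stop("selected atoms are collinear; superposition is degenerate")
  C <- crossprod(Pc, Qc)
  sv <- svd(C)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cq - as.numeric(R %*% cp)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "superpose")
}

#' Apply a superposition to a coordinate matrix
#' @param coords Matrix `n x 3`.
#' @param sp A `superpose` object.
#' @return Transformed matrix.
#' @export
apply_superpose <- function(coords, sp) {
  sweep(coords %*% t(sp$rotation), 2, sp$translation, "+")
}

#' @export
print.superpose <- function(x, ...) {
  cat(sprintf("superposition: rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

rmsd_between <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
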