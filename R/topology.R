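#' @keywords internal
"_PACKAGE"

#' Residue names recognized as water
#'
#' Waters are recognized by residue name. The default set covers the common
#' crystallographic and force-field conventions and can be extended via
#' `options(gsdyn.water_resnames = ...)`.
#'
#' @return Character vector of residue names.
#' @export
water_resnames <- function() {
  getOption("gsdyn.water_resnames", c("HOH", "WAT", "TIP3", "SOL"))
}

#' Construct a topology
#'
#' A topology is the per-atom bookkeeping shared by all frames of an ensemble:
#' atom names, elements, 1-based residue serials, residue names, chain
#' identifiers, and optional partial charges (e) and Lennard-Jones parameters
#' (rmin in Angstrom, epsilon in kcal/mol).
#'
#' @param name Atom names (character).
#' @param element Element symbols; missing entries are inferred from atom
#'   names via [infer_element()].
#' @param resid 1-based residue serials (integer).
#' @param resname Residue names.
#' @param chain Chain identifiers (single characters).
#' @param charge Optional partial charges in units of e.
#' @param vdw_rmin,vdw_eps Optional Lennard-Jones parameters per atom.
#' @param box Optional orthorhombic box lengths (Angstrom, length 3);
#'   `NULL` marks a non-periodic system.
#' @return Object of class `topology` (a data frame, one row per atom).
#' @export
topology <- function(name, element = NULL, resid, resname, chain = "A",
                     charge = NA_real_, vdw_rmin = NA_real_,
                     vdw_eps = NA_real_, box = NULL) {
  n <- length(name)
  if (is.null(element)) element <- rep(NA_character_, n)
  element <- ifelse(is.na(element) | element == "",
                    vapply(name, infer_element, ""), toupper(element))
  top <- data.frame(
    name = as.character(name),
    element = as.character(element),
    resid = as.integer(resid),
    resname = as.character(resname),
    chain = rep_len(as.character(chain), n),
    charge = rep_len(as.numeric(charge), n),
    vdw_rmin = rep_len(as.numeric(vdw_rmin), n),
    vdw_eps = rep_len(as.numeric(vdw_eps), n),
    stringsAsFactors = FALSE
  )
  if (!is.null(box)) {
    stopifnot(length(box) == 3, all(box > 0))
    attr(top, "box") <- as.numeric(box)
  }
  class(top) <- c("topology", "data.frame")
  validate_topology(top)
  top
}

validate_topology <- function(top) {
  stopifnot(inherits(top, "topology"), nrow(top) >= 1)
  if (anyNA(top$element) || any(top$element == ""))
    stop("element could not be determined for every atom")
  ## residue serials must be unique within a chain (per residue, not per atom)
  key <- paste(top$chain, top$resid)
  per_res <- tapply(top$resname, key, function(x) length(unique(x)))
  if (any(per_res > 1))
    stop("residue serial reused for different residue names within a chain")
  invisible(top)
}

#' Infer an element symbol from a PDB atom name
#'
#' Fallback used when columns 77-78 of a PDB file are blank: leading digits
#' are stripped and the first alphabetic character is taken, except that
#' trimmed names matching a known two-letter element (ions, halogens) are
#' used whole.
#'
#' @param name Atom name (character scalar).
#' @return Element symbol, upper case.
#' @export
infer_element <- function(name) {
  two_letter <- c("CL", "BR", "NA", "MG", "MN", "ZN", "FE", "CA2", "SE")
  nm <- toupper(trimws(name))
  if (nm %in% two_letter) return(nm)
  stripped <- sub("^[0-9']+", "", nm)
  if (nchar(stripped) == 0)
    stop("cannot infer element from atom name '", name, "'")
  substr(stripped, 1, 1)
}

#' Number of atoms in a topology or ensemble
#' @param x A `topology` or `ensemble`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "ensemble")) x <- x$topology
  nrow(x)
}

#' Construct an ensemble
#'
#' An ensemble groups one topology with one or more replicate trajectories.
#' Each replicate is an array of per-frame coordinates; replicates typically
#' correspond to independent simulations and drive the SEM statistics.
#'
#' @param topology A [topology()].
#' @param replicates List of coordinate arrays, each of dimension
#'   `c(n_frames, n_atoms, 3)` in Angstrom. A single matrix
#'   (`n_atoms x 3`) is promoted to a one-frame replicate.
#' @param frame_interval Time between saved frames, ps.
#' @return Object of class `ensemble`.
#' @export
ensemble <- function(topology, replicates, frame_interval = 20) {
  if (!is.list(replicates)) replicates <- list(replicates)
  replicates <- lapply(replicates, function(r) {
    if (is.matrix(r)) r <- array(r, dim = c(1L, nrow(r), 3L))
    stopifnot(length(dim(r)) == 3, dim(r)[3] == 3)
    r
  })
  na <- nrow(topology)
  for (k in seq_along(replicates)) {
    if (dim(replicates[[k]])[2] != na)
      stop("replicate ", k, " atom count (", dim(replicates[[k]])[2],
           ") does not match topology (", na, ")")
    if (!all(is.finite(replicates[[k]])))
      stop("replicate ", k, " contains non-finite coordinates")
  }
  if (is.null(names(replicates)))
    names(replicates) <- paste0("rep", seq_along(replicates))
  structure(list(topology = topology, replicates = replicates,
                 frame_interval = as.numeric(frame_interval)),
            class = "ensemble")
}

#' Number of frames per replicate
#' @param ens An `ensemble`.
#' @return Integer vector, one count per replicate.
#' @export
n_frames <- function(ens) {
  vapply(ens$replicates, function(r) dim(r)[1], integer(1))
}

#' Extract one frame as a coordinate matrix
#' @param ens An `ensemble`.
#' @param replicate Replicate index or name.
#' @param frame Frame index (1-based).
#' @return Numeric matrix `n_atoms x 3` (Angstrom).
#' @export
get_frame <- function(ens, replicate = 1, frame = 1) {
  r <- ens$replicates[[replicate]]
  matrix(r[frame, , ], ncol = 3)
}

#' @export
print.ensemble <- function(x, ...) {
  nf <- n_frames(x)
  cat("ensemble:", nrow(x$topology), "atoms,",
      length(x$replicates), "replicate(s) [",
      paste(nf, collapse = ", "), "frames ],",
      x$frame_interval, "ps/frame\n")
  res <- unique(paste(x$topology$chain, x$topology$resid))
  cat("  residues:", length(res), " waters:",
      sum(x$topology$resname %in% water_resnames()), "atoms\n")
  invisible(x)
}

#' Indices of frames retained after equilibration discard
#'
#' Analyses by default drop the first 20% of each replicate, mirroring the
#' convention of analysing the 20-100 ns interval of a 100 ns run.
#'
#' @param nf Number of frames.
#' @param equilibration Fraction of leading frames to discard, in `[0, 1)`.
#' @return Integer vector of retained frame indices.
#' @export
analysis_frames <- function(nf, equilibration = 0.2) {
  stopifnot(equilibration >= 0, equilibration < 1)
  start <- floor(nf * equilibration) + 1L
  seq.int(start, nf)
}
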