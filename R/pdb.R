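## Fixed-width multi-model PDB (v3.3) input/output.
## Only ATOM/HETATM/MODEL/ENDMDL/CRYST1/TER/END records are interpreted.

#' Read a (multi-model) PDB file into an ensemble
#'
#' ATOM and HETATM records are parsed at fixed columns; each MODEL block
#' becomes one frame of a single replicate (a file without MODEL records
#' yields one frame). The topology is built from the first model; waters and
#' hetero groups are retained. Alternate locations: altloc A (or blank) is
#' kept, others are dropped with a warning. Elements come from columns 77-78
#' with a fallback to [infer_element()].
#'
#' @param path Path to a PDB file.
#' @param model_policy `"all"` (every MODEL becomes a frame) or `"first"`.
#' @param frame_interval Frame spacing in ps recorded on the ensemble.
#' @return An [ensemble()] with one replicate.
#' @export
read_pdb <- function(path, model_policy = c("all", "first"),
                     frame_interval = 20) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  box <- NULL
  cr <- which(startsWith(lines, "CRYST1"))
  if (length(cr) >= 1) {
    b <- suppressWarnings(as.numeric(c(substr(lines[cr[1]], 7, 15),
                                       substr(lines[cr[1]], 16, 24),
                                       substr(lines[cr[1]], 25, 33))))
    if (all(is.finite(b)) && all(b > 1)) box <- b
  }

  ## split into model blocks by MODEL records; atoms before any MODEL (or in
  ## a file without MODEL) form model 1
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0) {
    blocks <- list(which(is_atom))
  } else {
    bounds <- c(model_starts, length(lines) + 1L)
    blocks <- lapply(seq_along(model_starts), function(k) {
      idx <- seq.int(bounds[k] + 1L, bounds[k + 1L] - 1L)
      idx[is_atom[idx]]
    })
    blocks <- blocks[vapply(blocks, length, 1L) > 0]
  }
  if (model_policy == "first") blocks <- blocks[1]

  parse_block <- function(idx) {
    ln <- lines[idx]
    altloc <- substr(ln, 17, 17)
    keep <- altloc == " " | altloc == "" | altloc == "A"
    if (!all(keep)) {
      warning("dropping ", sum(!keep),
              " alternate-location atoms (keeping altloc A)")
      ln <- ln[keep]
    }
    list(
      name = trimws(substr(ln, 13, 16)),
      resname = trimws(substr(ln, 18, 20)),
      chain = substr(ln, 22, 22),
      resid = as.integer(substr(ln, 23, 26)),
      x = as.numeric(substr(ln, 31, 38)),
      y = as.numeric(substr(ln, 39, 46)),
      z = as.numeric(substr(ln, 47, 54)),
      element = trimws(substr(ln, 77, 78))
    )
  }

  first <- parse_block(blocks[[1]])
  na <- length(first$name)
  elem <- ifelse(first$element == "", NA_character_, toupper(first$element))
  top <- topology(name = first$name, element = elem, resid = first$resid,
                  resname = first$resname, chain = first$chain, box = box)

  nfr <- length(blocks)
  coords <- array(NA_real_, dim = c(nfr, na, 3))
  coords[1, , ] <- cbind(first$x, first$y, first$z)
  if (nfr > 1) {
    for (m in 2:nfr) {
      b <- parse_block(blocks[[m]])
      if (length(b$name) != na)
        stop("model ", m, " has ", length(b$name),
             " atoms; model 1 has ", na)
      coords[m, , ] <- cbind(b$x, b$y, b$z)
    }
  }
  if (!all(is.finite(coords))) stop("non-numeric coordinates in ", path)
  ensemble(top, list(coords), frame_interval = frame_interval)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Coordinates are written at fixed-width %8.3f precision, so a round trip
#' through [read_pdb()] reproduces them to 1e-3 Angstrom. Atom serials wrap
#' modulo 100000 for systems beyond the PDB serial field width.
#'
#' @param ens An [ensemble()]; all replicates are concatenated as MODELs in
#'   replicate order.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(ens, path) {
  stopifnot(inherits(ens, "ensemble"))
  top <- ens$topology
  na <- nrow(top)
  if (na == 0 || sum(n_frames(ens)) == 0) stop("empty ensemble")
  con <- file(path, open = "wt")
  on.exit(close(con))

  box <- attr(top, "box")
  if (!is.null(box))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       box[1], box[2], box[3]), con)

  serial <- (seq_len(na) - 1L) %% 99999L + 1L
  is_het <- top$resname %in% c(water_resnames(), "PO4", "ADP", "ATP", "MG", "MN")
  recname <- ifelse(is_het, "HETATM", "ATOM  ")
  ## PDB atom-name column convention: 1-3 char names start in column 14
  aname <- ifelse(nchar(top$name) <= 3, sprintf(" %-3s", top$name),
                  sprintf("%-4s", top$name))
  elem <- sprintf("%2s", substr(top$element, 1, 2))
  pre <- sprintf("%s%5d %s %-3s %1s%4d    ", recname, serial, aname,
                 top$resname, top$chain, top$resid %% 10000L)
  post <- sprintf("  1.00  0.00          %s", elem)

  model_no <- 0L
  for (r in seq_along(ens$replicates)) {
    arr <- ens$replicates[[r]]
    for (f in seq_len(dim(arr)[1])) {
      model_no <- model_no + 1L
      writeLines(sprintf("MODEL     %4d", model_no), con)
      xyz <- matrix(arr[f, , ], ncol = 3)
      writeLines(paste0(pre, sprintf("%8.3f%8.3f%8.3f",
                                     xyz[, 1], xyz[, 2], xyz[, 3]), post), con)
      writeLines("ENDMDL", con)
    }
  }
  writeLines("END", con)
  invisible(path)
}
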