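## Water-mediated hydrogen-bond bridge detection.
##
## A bridge is an alternating solute-water-...-water-solute chain in which
## every link satisfies the hydrogen-bond criteria of the requested class
## (strong links nest inside weak). Chains are simple paths over water
## oxygens (no repeated water), depth-bounded by max_waters; a frame "has a
## bridge" iff at least one chain exists. Donor/acceptor roles per link are
## decided by attached hydrogens: a link qualifies if either side can donate
## with a valid angle (or via the distance-only fallback when neither side
## carries hydrogens).

## class of the link between heavy atoms p, q (either may donate); falls back
## to the distance-only test only when neither side carries a hydrogen
link_class <- function(coords, p, q, hmap, criteria) {
  d <- sqrt(sum((coords[p, ] - coords[q, ])^2))
  if (d > criteria$d_weak) return(NA_character_)
  hp <- hmap$h[hmap$heavy == p]
  hq <- hmap$h[hmap$heavy == q]
  if (length(hp) + length(hq) > 0) {
    angs <- c(
      vapply(hp, function(h) angle_deg(coords[p, ], coords[h, ], coords[q, ]),
             numeric(1)),
      vapply(hq, function(h) angle_deg(coords[q, ], coords[h, ], coords[p, ]),
             numeric(1)))
    if (max(angs) < criteria$angle_min) return(NA_character_)
  }
  if (d <= criteria$d_strong) "strong" else "weak"
}

#' Find water-mediated bridges in one frame
#'
#' Depth-first search over the hydrogen-bond graph whose nodes are the
#' endpoint heavy atoms and water oxygens; returns all simple chains
#' `endpoint_a -> water(s) -> endpoint_b` with 1..`max_waters` waters whose
#' links all satisfy the requested class.
#'
#' @param top A [topology()].
#' @param coords Coordinate matrix for the frame.
#' @param endpoint_a,endpoint_b Heavy-atom index vectors (disjoint).
#' @param criteria An [hbond_criteria()].
#' @param class_level `"strong"` or `"weak"` (strong chains also qualify as
#'   weak).
#' @param max_waters Maximum waters per chain (default 3).
#' @param water_oxygens Indices of water oxygen atoms (default: oxygens of
#'   residues named in [water_resnames()]).
#' @return List of chains; each chain is a list with `atoms` (index vector
#'   endpoint, waters..., endpoint) and `n_waters`.
#' @export
find_bridges <- function(top, coords, endpoint_a, endpoint_b,
                         criteria = hbond_criteria(),
                         class_level = c("strong", "weak"), max_waters = 3,
                         water_oxygens = NULL) {
  class_level <- match.arg(class_level)
  if (max_waters < 1) stop("max_waters must be >= 1")
  if (length(intersect(endpoint_a, endpoint_b)) > 0)
    stop("endpoints must be disjoint")
  if (is.null(water_oxygens))
    water_oxygens <- which(top$resname %in% water_resnames() &
                             top$element == "O")
  hmap <- attached_hydrogens(top, coords)
  ok_class <- function(cl) !is.na(cl) &&
    (class_level == "weak" || cl == "strong")

  ## adjacency among candidate nodes, computed lazily via distance prefilter
  nodes <- c(endpoint_a, water_oxygens, endpoint_b)
  near <- pairwise_dist(coords[nodes, , drop = FALSE],
                        coords[nodes, , drop = FALSE]) <= criteria$d_weak

  nw <- length(water_oxygens)
  na_ <- length(endpoint_a)
  wslot <- function(w) na_ + match(w, water_oxygens)
  bslot <- function(b) na_ + nw + match(b, endpoint_b)
  chains <- list()
  dfs <- function(start, path_waters) {
    last <- path_waters[length(path_waters)]
    for (b in endpoint_b) {
      if (!near[wslot(last), bslot(b)]) next
      if (ok_class(link_class(coords, last, b, hmap, criteria))) {
        chains[[length(chains) + 1]] <<- list(
          atoms = c(start, path_waters, b),
          n_waters = length(path_waters))
      }
    }
    if (length(path_waters) >= max_waters) return(invisible())
    for (w in water_oxygens) {
      if (w %in% path_waters) next
      if (!near[wslot(last), wslot(w)]) next
      if (ok_class(link_class(coords, last, w, hmap, criteria)))
        dfs(start, c(path_waters, w))
    }
  }
  for (a in endpoint_a) {
    for (w in water_oxygens) {
      if (!near[match(a, endpoint_a), wslot(w)]) next
      if (ok_class(link_class(coords, a, w, hmap, criteria)))
        dfs(a, w)
    }
  }
  chains
}

#' Bridge frequency across an ensemble
#'
#' Fraction of analysed frames containing at least one water-mediated bridge
#' between the endpoint groups (multiple chains in a frame count once), with
#' SEM across replicates. Strong and weak frequencies are typically reported
#' side by side; by link nesting, the strong frequency never exceeds the weak
#' one.
#'
#' @param ens An [ensemble()].
#' @param endpoint_a,endpoint_b Selections.
#' @param criteria An [hbond_criteria()].
#' @param class_level `"strong"` or `"weak"`.
#' @param max_waters Maximum waters per chain.
#' @param equilibration Leading fraction of frames excluded.
#' @return A [replicate_stat()] of per-replicate bridge frequencies, with the
#'   per-frame logical series attached as attribute `frames`.
#' @export
bridge_frequency <- function(ens, endpoint_a, endpoint_b,
                             criteria = hbond_criteria(),
                             class_level = c("strong", "weak"),
                             max_waters = 3, equilibration = 0) {
  class_level <- match.arg(class_level)
  a <- resolve_sel(ens, endpoint_a)
  b <- resolve_sel(ens, endpoint_b)
  top <- ens$topology
  series <- lapply(ens$replicates, function(arr) {
    keep <- analysis_frames(dim(arr)[1], equilibration)
    vapply(keep, function(f) {
      length(find_bridges(top, matrix(arr[f, , ], ncol = 3), a, b,
                          criteria, class_level, max_waters)) > 0
    }, logical(1))
  })
  st <- replicate_stat(vapply(series, mean, numeric(1)))
  attr(st, "frames") <- series
  st
}
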