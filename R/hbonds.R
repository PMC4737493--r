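## Hydrogen-bond and salt-bridge occupancy analysis.
##
## Criteria follow the heavy-atom convention: the distance is measured
## between the donor and acceptor heavy atoms (<= 2.8 A strong, <= 3.2 A
## weak, inclusive), the angle at the hydrogen (donor atom, H, acceptor
## atom) must be >= 120 degrees (inclusive). Salt bridges use a strict
## distance-only criterion d < 4.0 A.

#' Hydrogen-bond criteria
#'
#' @param d_strong Heavy-atom donor-acceptor cutoff for strong bonds (A).
#' @param d_weak Cutoff for weak bonds (A); strong bonds nest inside weak.
#' @param angle_min Minimum donor-H-acceptor angle at the hydrogen (degrees).
#' @param salt_bridge_cut Salt-bridge distance cutoff (A, strict `<`).
#' @return Object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(d_strong = 2.8, d_weak = 3.2, angle_min = 120,
                           salt_bridge_cut = 4.0) {
  stopifnot(d_strong > 0, d_strong <= d_weak,
            angle_min >= 0, angle_min <= 180)
  structure(list(d_strong = d_strong, d_weak = d_weak,
                 angle_min = angle_min, salt_bridge_cut = salt_bridge_cut),
            class = "hbond_criteria")
}

## map each hydrogen to its bonded heavy atom (nearest heavy within 1.25 A)
attached_hydrogens <- function(top, coords) {
  h_idx <- which(top$element == "H")
  heavy <- which(top$element != "H")
  if (length(h_idx) == 0 || length(heavy) == 0)
    return(data.frame(h = integer(0), heavy = integer(0)))
  d <- pairwise_dist(coords[h_idx, , drop = FALSE],
                     coords[heavy, , drop = FALSE])
  nearest <- apply(d, 1, which.min)
  ok <- d[cbind(seq_along(h_idx), nearest)] <= 1.25
  data.frame(h = h_idx[ok], heavy = heavy[nearest[ok]])
}

angle_deg <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

## single-frame donor/acceptor H-bond test; returns "strong", "weak" or NA.
## hmap: attached_hydrogens() table for this frame's topology.
hbond_class_pair <- function(coords, donor, acceptor, hmap, criteria,
                             warn_env = NULL) {
  d <- sqrt(sum((coords[donor, ] - coords[acceptor, ])^2))
  if (d > criteria$d_weak) return(list(class = NA_character_, h = NA_integer_))
  hs <- hmap$h[hmap$heavy == donor]
  if (length(hs) == 0) {
    if (!is.null(warn_env) && !isTRUE(warn_env$warned)) {
      warning("donor without attached hydrogen; using distance-only test")
      warn_env$warned <- TRUE
    }
    cls <- if (d <= criteria$d_strong) "strong" else "weak"
    return(list(class = cls, h = NA_integer_))
  }
  angles <- vapply(hs, function(h)
    angle_deg(coords[donor, ], coords[h, ], coords[acceptor, ]), numeric(1))
  if (max(angles) < criteria$angle_min)
    return(list(class = NA_character_, h = NA_integer_))
  cls <- if (d <= criteria$d_strong) "strong" else "weak"
  list(class = cls, h = hs[which.max(angles)])
}

#' Enumerate hydrogen-bond events in an ensemble
#'
#' Emits one event per qualifying donor-acceptor pair and frame. An event is
#' classed `strong` if it meets the strong criteria, else `weak`; strong
#' events satisfy the weak criteria by construction (nesting). Donors lacking
#' an attached hydrogen fall back to the distance-only test with one warning.
#'
#' @param ens An [ensemble()].
#' @param donors,acceptors Selections of heavy atoms.
#' @param criteria An [hbond_criteria()].
#' @return Data frame: `replicate`, `frame`, `donor`, `hydrogen`, `acceptor`,
#'   `class`.
#' @export
hbond_events <- function(ens, donors, acceptors,
                         criteria = hbond_criteria()) {
  don <- resolve_sel(ens, donors)
  acc <- resolve_sel(ens, acceptors)
  top <- ens$topology
  warn_env <- new.env(); warn_env$warned <- FALSE
  out <- list()
  for (r in seq_along(ens$replicates)) {
    arr <- ens$replicates[[r]]
    hmap <- attached_hydrogens(top, matrix(arr[1, , ], ncol = 3))
    for (f in seq_len(dim(arr)[1])) {
      fr <- matrix(arr[f, , ], ncol = 3)
      for (d_i in don) for (a_i in acc) {
        if (d_i == a_i) next
        hb <- hbond_class_pair(fr, d_i, a_i, hmap, criteria, warn_env)
        if (!is.na(hb$class)) {
          out[[length(out) + 1]] <- data.frame(
            replicate = r, frame = f, donor = d_i, hydrogen = hb$h,
            acceptor = a_i, class = hb$class, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(replicate = integer(0), frame = integer(0),
                      donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), class = character(0)))
  do.call(rbind, out)
}

#' Interaction occupancy across frames and replicates
#'
#' Fraction of analysed frames in which at least one qualifying event occurs,
#' with SEM across replicates. `x` may be an event table from
#' [hbond_events()] (filtered to `class_level`: `"strong"` counts strong
#' events only; `"weak"` counts weak and strong, by nesting) or a list of
#' per-replicate logical frame vectors.
#'
#' @param x Event data frame or list of logical vectors.
#' @param n_frames Frames per replicate (integer vector or scalar); required
#'   for event tables.
#' @param class_level `"weak"` or `"strong"`.
#' @param equilibration Leading fraction of frames excluded.
#' @return A [replicate_stat()] of per-replicate occupancy fractions.
#' @export
occupancy <- function(x, n_frames = NULL, class_level = c("weak", "strong"),
                      equilibration = 0) {
  class_level <- match.arg(class_level)
  if (is.data.frame(x)) {
    stopifnot(!is.null(n_frames))
    n_rep <- max(c(x$replicate, 1))
    if (length(n_frames) == 1) n_frames <- rep(n_frames, n_rep)
    keep_class <- if (class_level == "strong") "strong" else
      c("strong", "weak")
    x <- lapply(seq_len(n_rep), function(r) {
      present <- rep(FALSE, n_frames[r])
      ev <- x[x$replicate == r & x$class %in% keep_class, ]
      present[unique(ev$frame)] <- TRUE
      present
    })
  }
  fractions <- vapply(x, function(v) {
    keep <- analysis_frames(length(v), equilibration)
    mean(v[keep])
  }, numeric(1))
  replicate_stat(fractions)
}

#' Salt-bridge occupancy (distance-only, strict cutoff)
#'
#' A salt bridge is counted in a frame when the minimum distance between the
#' basic and acidic groups is strictly below `cutoff` (d < 4.0 A by default).
#'
#' @param ens An [ensemble()].
#' @param basic_group,acidic_group Selections.
#' @param cutoff Angstrom, strict `<`.
#' @param equilibration Leading fraction of frames excluded.
#' @return A [replicate_stat()] of per-replicate occupancies.
#' @export
salt_bridge_occupancy <- function(ens, basic_group, acidic_group,
                                  cutoff = 4.0, equilibration = 0) {
  a <- resolve_sel(ens, basic_group)
  b <- resolve_sel(ens, acidic_group)
  present <- lapply(ens$replicates, function(arr) {
    vapply(seq_len(dim(arr)[1]), function(f) {
      fr <- matrix(arr[f, , ], ncol = 3)
      min(pairwise_dist(fr[a, , drop = FALSE], fr[b, , drop = FALSE])) <
        cutoff
    }, logical(1))
  })
  occupancy(present, equilibration = equilibration)
}
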