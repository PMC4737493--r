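## Body-bar rigidity analysis.
##
## A molecular framework is modelled as rigid bodies joined by bars:
## rotatable covalent bonds contribute 5 bars, locked (peptide/double) bonds
## 6, hydrogen bonds and salt bridges 5 bars labelled with an energy, and
## hydrophobic tethers 2. Generic rigidity of the resulting multigraph is
## decided by the (6,6) pebble game; correctness is pinned to the generic
## rigidity-matrix rank oracle in the test suite.

#' Construct a body-bar constraint network
#'
#' @param n_bodies Number of rigid bodies.
#' @param bars Data frame with columns `i`, `j` (1-based body indices,
#'   `i != j`), `mult` (1-6), `origin` (`covalent`, `hbond`, `hydrophobic`),
#'   `energy` (kcal/mol, finite and <= 0 for `hbond` bars, `NA` otherwise),
#'   and optional attachment coordinates `ax, ay, az, bx, by, bz`.
#' @param body_resid Optional residue serial per body (for residue-level
#'   maps).
#' @return Object of class `constraint_network`.
#' @export
constraint_network <- function(n_bodies, bars, body_resid = NULL) {
  bars <- as.data.frame(bars)
  if (nrow(bars) > 0) {
    if (is.null(bars$origin)) bars$origin <- "covalent"
    if (is.null(bars$energy)) bars$energy <- NA_real_
    if (is.null(bars$mult)) bars$mult <- 1L
    stopifnot(all(bars$i >= 1), all(bars$j >= 1),
              all(bars$i <= n_bodies), all(bars$j <= n_bodies))
    if (any(bars$i == bars$j)) stop("self-bars are not allowed")
    if (any(bars$mult < 1 | bars$mult > 6))
      stop("bar multiplicity must be in 1..6")
    hb <- bars$origin == "hbond"
    if (any(hb & (!is.finite(bars$energy) | bars$energy > 0)))
      stop("hbond bars must carry finite energy <= 0")
  }
  structure(list(n_bodies = as.integer(n_bodies), bars = bars,
                 body_resid = body_resid),
            class = "constraint_network")
}

#' @export
print.constraint_network <- function(x, ...) {
  cat("constraint network:", x$n_bodies, "bodies,",
      if (nrow(x$bars)) sum(x$bars$mult) else 0, "bars\n")
  if (nrow(x$bars))
    print(table(x$bars$origin))
  invisible(x)
}

## ---- (6,6) body-bar pebble game ---------------------------------------------

## State: 6 pebbles per body; a directed multigraph adjacency count matrix.
## An inserted bar is independent iff 7 pebbles can be gathered on its two
## endpoints (pebble searches with path reversal); it then consumes one
## pebble of its tail.

pg_new <- function(n) list(pebbles = rep(6L, n),
                           adj = matrix(0L, n, n))

## depth-first pebble search: try to move one pebble to `u`, never taking
## one from `forbid`; returns updated state or NULL
pg_fetch <- function(st, u, forbid) {
  n <- length(st$pebbles)
  seen <- rep(FALSE, n)
  parent <- rep(NA_integer_, n)
  stack <- u
  seen[u] <- TRUE
  found <- NA_integer_
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ws <- which(st$adj[v, ] > 0 & !seen)
    for (w in ws) {
      seen[w] <- TRUE
      parent[w] <- v
      if (w != forbid && st$pebbles[w] > 0) { found <- w; break }
      stack <- c(stack, w)
    }
    if (!is.na(found)) break
  }
  if (is.na(found)) return(NULL)
  ## reverse the path u -> ... -> found; pebble moves to u
  w <- found
  while (!is.na(parent[w])) {
    v <- parent[w]
    st$adj[v, w] <- st$adj[v, w] - 1L
    st$adj[w, v] <- st$adj[w, v] + 1L
    w <- v
  }
  st$pebbles[found] <- st$pebbles[found] - 1L
  st$pebbles[u] <- st$pebbles[u] + 1L
  st
}

## gather pebbles until u+v hold `need`; returns list(st, ok)
pg_gather <- function(st, u, v, need = 7L) {
  repeat {
    if (st$pebbles[u] + st$pebbles[v] >= need) return(list(st = st, ok = TRUE))
    nxt <- pg_fetch(st, u, v)
    if (is.null(nxt)) nxt <- pg_fetch(st, v, u)
    if (is.null(nxt)) return(list(st = st, ok = FALSE))
    st <- nxt
  }
}

#' Rigid-cluster decomposition by the (6,6) body-bar pebble game
#'
#' Bars are inserted in a sorted canonical order (so the result is invariant
#' to input order); a bar is independent iff 7 pebbles can be gathered on its
#' endpoints. Two bodies are mutually rigid iff, after the game, a virtual
#' extra bar between them would be redundant; rigid clusters are the
#' equivalence classes of that relation.
#'
#' @param network A [constraint_network()].
#' @return Object of class `rigid_decomposition`: `cluster` (label per body),
#'   `dof` (internal degrees of freedom,
#'   `6 B - 6 * n_components - independent bars`), `n_independent`,
#'   `n_redundant`, `n_components`.
#' @export
pebble_game <- function(network) {
  n <- network$n_bodies
  bars <- network$bars
  ## expand multiplicity and sort canonically
  if (nrow(bars) > 0) {
    i <- rep(pmin(bars$i, bars$j), bars$mult)
    j <- rep(pmax(bars$i, bars$j), bars$mult)
    ord <- order(i, j)
    i <- i[ord]; j <- j[ord]
  } else i <- j <- integer(0)

  st <- pg_new(n)
  indep <- 0L
  i <- as.integer(i); j <- as.integer(j)
  parent_uf <- seq_len(n)
  uf_find <- function(x) { while (parent_uf[x] != x) x <- parent_uf[x]; x }
  for (k in seq_along(i)) {
    g <- pg_gather(st, i[k], j[k], 7L)
    st <- g$st
    if (g$ok) {
      st$pebbles[i[k]] <- st$pebbles[i[k]] - 1L
      st$adj[i[k], j[k]] <- st$adj[i[k], j[k]] + 1L
      indep <- indep + 1L
    }
    parent_uf[uf_find(i[k])] <- uf_find(j[k])
  }
  comp <- vapply(seq_len(n), uf_find, integer(1))
  n_comp <- length(unique(comp))
  dof <- sum(st$pebbles) - 6L * n_comp

  ## pairwise mutual-rigidity within components (state copied per test)
  cl_parent <- seq_len(n)
  cl_find <- function(x) { while (cl_parent[x] != x) x <- cl_parent[x]; x }
  for (u in seq_len(n - 1)) for (v in (u + 1):n) {
    if (n < 2) break
    if (comp[u] != comp[v]) next
    if (cl_find(u) == cl_find(v)) next
    g <- pg_gather(st, u, v, 7L)   # discard mutated copy: st unchanged below
    if (!g$ok) cl_parent[cl_find(u)] <- cl_find(v)
  }
  cl <- vapply(seq_len(n), cl_find, integer(1))
  cluster <- as.integer(factor(cl, levels = unique(cl)))
  structure(list(cluster = cluster, dof = as.integer(dof),
                 n_independent = indep,
                 n_redundant = length(i) - indep,
                 n_components = n_comp),
            class = "rigid_decomposition")
}

#' @export
print.rigid_decomposition <- function(x, ...) {
  cat("rigid decomposition:", max(x$cluster), "cluster(s),",
      x$dof, "internal DOF,", x$n_independent, "independent /",
      x$n_redundant, "redundant bars\n")
  invisible(x)
}

## ---- hydrogen-bond energy (Mayo-style potential) ---------------------------

#' Distance/angle-modulated hydrogen-bond energy
#'
#' Mayo-style 12-10 potential with a well depth of -8 kcal/mol at the ideal
#' geometry: `E = -8 * (5 (R0/R)^12 - 6 (R0/R)^10) * cos^2(theta)` with
#' `R0 = 2.8` A and `theta` the deviation of the donor-H-acceptor angle from
#' linearity. Energies above 0 are clamped to 0 (no bond).
#'
#' @param r Donor-acceptor heavy-atom distance, A.
#' @param angle Donor-H-acceptor angle, degrees (180 = linear).
#' @param r0 Ideal distance (default 2.8 A).
#' @param well Well depth, kcal/mol (default 8; energy at optimum = -8).
#' @return Energy, kcal/mol (<= 0).
#' @export
hbond_energy_mayo <- function(r, angle = 180, r0 = 2.8, well = 8) {
  rad <- (180 - angle) * pi / 180
  e <- well * (5 * (r0 / r)^12 - 6 * (r0 / r)^10) * cos(rad)^2
  pmin(e, 0)
}

## ---- network construction from structures -----------------------------------

covalent_radius <- function(elements) {
  tab <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, P = 1.07, S = 1.05,
           MG = 1.41)
  r <- tab[elements]
  r[is.na(r)] <- 0.77
  unname(r)
}

#' Build a constraint network from a structure
#'
#' Residue-level coarse mode: one body per residue; consecutive residues in a
#' chain are joined by 5 bars (one effective backbone degree of freedom per
#' peptide linkage); hydrogen bonds between residues contribute 5 bars
#' labelled with a Mayo-potential energy (or energies supplied via
#' `hbond_table`); hydrophobic tethers (side-chain C/S pairs within the sum
#' of van-der-Waals radii + 0.25 A) contribute 2 bars. Atom mode: one body
#' per heavy atom, covalent bonds detected by covalent-radius distance (5
#' bars; peptide C-N and carbonyl C=O locked at 6).
#'
#' @param top A [topology()].
#' @param coords Coordinate matrix.
#' @param mode `"residue"` or `"atom"`.
#' @param criteria [hbond_criteria()] for hydrogen-bond detection.
#' @param hbond_table Optional precomputed H-bond energies: data frame with
#'   columns `donor`, `acceptor` (atom indices), `energy` (kcal/mol <= 0).
#' @param min_seq_sep Minimum residue separation for an H-bond bar in
#'   residue mode (default 2).
#' @return A [constraint_network()] with `body_resid` set in residue mode.
#' @export
build_network <- function(top, coords, mode = c("residue", "atom"),
                          criteria = hbond_criteria(), hbond_table = NULL,
                          min_seq_sep = 2) {
  mode <- match.arg(mode)
  protein <- !(top$resname %in% water_resnames())

  ## hydrogen bonds: donors = N/O/S with attached H, acceptors = N/O/S
  hmap <- attached_hydrogens(top, coords)
  if (is.null(hbond_table)) {
    don <- intersect(which(top$element %in% c("N", "O", "S") & protein),
                     unique(hmap$heavy))
    acc <- which(top$element %in% c("N", "O", "S") & protein)
    hb <- list()
    if (length(don) > 0 && length(acc) > 0) {
      d <- pairwise_dist(coords[don, , drop = FALSE],
                         coords[acc, , drop = FALSE])
      cand <- which(d <= criteria$d_weak, arr.ind = TRUE)
      for (k in seq_len(nrow(cand))) {
        di <- don[cand[k, 1]]; ai <- acc[cand[k, 2]]
        if (di == ai) next
        if (top$resid[di] == top$resid[ai] && top$chain[di] == top$chain[ai])
          next
        hs <- hmap$h[hmap$heavy == di]
        angs <- vapply(hs, function(h)
          angle_deg(coords[di, ], coords[h, ], coords[ai, ]), numeric(1))
        if (max(angs) < criteria$angle_min) next
        e <- hbond_energy_mayo(d[cand[k, 1], cand[k, 2]], max(angs))
        if (e < 0)
          hb[[length(hb) + 1]] <- data.frame(donor = di, acceptor = ai,
                                             energy = e)
      }
    }
    hbond_table <- if (length(hb)) do.call(rbind, hb) else
      data.frame(donor = integer(0), acceptor = integer(0),
                 energy = numeric(0))
  } else if (nrow(hbond_table) > 0 && is.null(hbond_table$energy)) {
    stop("hbond_table must carry energies")
  }

  if (mode == "residue") {
    key <- paste(top$chain, top$resid)
    ukey <- unique(key[protein])
    body_of <- match(key, ukey)           # NA for non-protein atoms
    nb <- length(ukey)
    resid_of <- top$resid[match(ukey, key)]
    chain_of <- top$chain[match(ukey, key)]
    bars <- list()
    ## backbone: consecutive residues within a chain
    for (b in seq_len(nb - 1)) {
      if (nb < 2) break
      if (chain_of[b] == chain_of[b + 1] &&
          resid_of[b + 1] == resid_of[b] + 1)
        bars[[length(bars) + 1]] <- data.frame(
          i = b, j = b + 1, mult = 5L, origin = "covalent",
          energy = NA_real_)
    }
    ## hydrogen bonds (aggregate per residue pair: strongest energy, 5 bars)
    if (nrow(hbond_table) > 0) {
      bi <- body_of[hbond_table$donor]
      bj <- body_of[hbond_table$acceptor]
      ok <- !is.na(bi) & !is.na(bj) & abs(bi - bj) >= min_seq_sep
      if (any(ok)) {
        key2 <- paste(pmin(bi, bj)[ok], pmax(bi, bj)[ok])
        emin <- tapply(hbond_table$energy[ok], key2, min)
        ij <- do.call(rbind, strsplit(names(emin), " "))
        bars[[length(bars) + 1]] <- data.frame(
          i = as.integer(ij[, 1]), j = as.integer(ij[, 2]), mult = 5L,
          origin = "hbond", energy = as.numeric(emin))
      }
    }
    ## hydrophobic tethers between side-chain carbons/sulfurs
    side <- which(protein & top$element %in% c("C", "S") &
                    !(top$name %in% c("C", "CA")))
    if (length(side) > 1) {
      d <- pairwise_dist(coords[side, , drop = FALSE],
                         coords[side, , drop = FALSE])
      lim <- outer(vdw_radius(top$element[side]),
                   vdw_radius(top$element[side]), "+") + 0.25
      cand <- which(d <= lim & upper.tri(d), arr.ind = TRUE)
      if (nrow(cand) > 0) {
        bi <- body_of[side[cand[, 1]]]
        bj <- body_of[side[cand[, 2]]]
        ok <- abs(bi - bj) >= min_seq_sep
        if (any(ok)) {
          key2 <- unique(paste(pmin(bi, bj)[ok], pmax(bi, bj)[ok]))
          ij <- do.call(rbind, strsplit(key2, " "))
          bars[[length(bars) + 1]] <- data.frame(
            i = as.integer(ij[, 1]), j = as.integer(ij[, 2]), mult = 2L,
            origin = "hydrophobic", energy = NA_real_)
        }
      }
    }
    bars <- if (length(bars)) do.call(rbind, bars) else
      data.frame(i = integer(0), j = integer(0), mult = integer(0),
                 origin = character(0), energy = numeric(0))
    return(constraint_network(nb, bars, body_resid = resid_of))
  }

  ## atom mode: bodies = heavy atoms
  heavy <- which(top$element != "H")
  nb <- length(heavy)
  pos <- coords[heavy, , drop = FALSE]
  d <- pairwise_dist(pos, pos)
  lim <- outer(covalent_radius(top$element[heavy]),
               covalent_radius(top$element[heavy]), "+") * 1.3
  cand <- which(d <= lim & d > 0.1 & upper.tri(d), arr.ind = TRUE)
  bars <- list()
  for (k in seq_len(nrow(cand))) {
    u <- cand[k, 1]; v <- cand[k, 2]
    nm <- sort(c(top$name[heavy[u]], top$name[heavy[v]]))
    locked <- identical(nm, c("C", "N")) || identical(nm, c("C", "O"))
    bars[[length(bars) + 1]] <- data.frame(
      i = u, j = v, mult = if (locked) 6L else 5L, origin = "covalent",
      energy = NA_real_)
  }
  if (nrow(hbond_table) > 0) {
    bi <- match(hbond_table$donor, heavy)
    bj <- match(hbond_table$acceptor, heavy)
    ok <- !is.na(bi) & !is.na(bj)
    if (any(ok))
      bars[[length(bars) + 1]] <- data.frame(
        i = pmin(bi, bj)[ok], j = pmax(bi, bj)[ok], mult = 5L,
        origin = "hbond", energy = hbond_table$energy[ok])
  }
  bars <- if (length(bars)) do.call(rbind, bars) else
    data.frame(i = integer(0), j = integer(0), mult = integer(0),
               origin = character(0), energy = numeric(0))
  constraint_network(nb, bars,
                     body_resid = top$resid[heavy])
}

## ---- thermal unfolding and stability maps -----------------------------------

#' Thermal unfolding over a hydrogen-bond energy-cutoff ladder
#'
#' At cutoff `c` (kcal/mol, magnitude scale), hydrogen-bond bars are retained
#' iff `|energy| >= c`; covalent and hydrophobic bars are always retained.
#' The rigid-cluster decomposition is recomputed per cutoff, and the
#' stability-map entry `rc_ij` is the largest cutoff at which bodies i and j
#' still share a rigid cluster; pairs never co-rigid at `c = 0` get the `NA`
#' sentinel, and `rc_ii` equals the top of the ladder by convention.
#'
#' @param network A [constraint_network()] with energies on its `hbond` bars.
#' @param cutoffs Cutoff ladder, kcal/mol (default `seq(0, 6, by = 0.1)`).
#' @return Object of class `stability_map`: `rc` (symmetric matrix, `NA`
#'   sentinel), `cutoffs`, `decompositions` (list of cluster label vectors
#'   per cutoff), `body_resid`.
#' @export
thermal_unfolding <- function(network, cutoffs = seq(0, 6, by = 0.1)) {
  bars <- network$bars
  hb <- bars$origin == "hbond"
  if (any(hb & !is.finite(bars$energy)))
    stop("hbond bars must carry energies for thermal unfolding")
  n <- network$n_bodies
  rc <- matrix(NA_real_, n, n)
  decomps <- vector("list", length(cutoffs))
  for (k in seq_along(cutoffs)) {
    keep <- !hb | abs(bars$energy) >= cutoffs[k]
    sub <- constraint_network(n, bars[keep, , drop = FALSE],
                              body_resid = network$body_resid)
    dec <- pebble_game(sub)
    decomps[[k]] <- dec$cluster
    same <- outer(dec$cluster, dec$cluster, "==")
    rc[same] <- cutoffs[k]
  }
  diag(rc) <- max(cutoffs)
  structure(list(rc = rc, cutoffs = cutoffs, decompositions = decomps,
                 body_resid = network$body_resid),
            class = "stability_map")
}

#' @export
print.stability_map <- function(x, ...) {
  off <- x$rc[upper.tri(x$rc)]
  cat(sprintf("stability map: %d bodies, rc range [%.1f, %.1f], %d never-rigid pairs\n",
              nrow(x$rc), suppressWarnings(min(off, na.rm = TRUE)),
              suppressWarnings(max(off, na.rm = TRUE)), sum(is.na(off))))
  invisible(x)
}

#' Ensemble-averaged stability map
#'
#' Builds a constraint network and runs a thermal unfolding for each
#' structure, then averages `rc_ij` element-wise; sentinel (`NA`) entries are
#' excluded from the mean with count bookkeeping.
#'
#' @param structures List of coordinate matrices (one per structure), or an
#'   [ensemble()] whose frames are used.
#' @param top A [topology()] (ignored when `structures` is an ensemble).
#' @param cutoffs Cutoff ladder.
#' @param mode,criteria,hbond_table Passed to [build_network()]; when
#'   `hbond_table` is a function it is called with the structure index to
#'   supply per-structure energies.
#' @param max_structures Optional subsampling cap (equally spaced).
#' @return List: `mean_rc`, `n_ok` (per-pair non-sentinel counts), `maps`
#'   (per-structure `rc` matrices as a 3D array), `body_resid`.
#' @export
ensemble_stability_map <- function(structures, top = NULL,
                                   cutoffs = seq(0, 6, by = 0.1),
                                   mode = "residue",
                                   criteria = hbond_criteria(),
                                   hbond_table = NULL,
                                   max_structures = NULL) {
  if (inherits(structures, "ensemble")) {
    ens <- structures
    top <- ens$topology
    structures <- list()
    for (r in seq_along(ens$replicates)) {
      arr <- ens$replicates[[r]]
      for (f in seq_len(dim(arr)[1]))
        structures[[length(structures) + 1]] <- matrix(arr[f, , ], ncol = 3)
    }
  }
  if (!is.null(max_structures) && length(structures) > max_structures) {
    idx <- unique(round(seq(1, length(structures),
                            length.out = max_structures)))
    structures <- structures[idx]
  }
  if (length(structures) < 2)
    stop("need >= 2 structures for ensemble statistics")
  maps <- lapply(seq_along(structures), function(s) {
    ht <- if (is.function(hbond_table)) hbond_table(s) else hbond_table
    net <- build_network(top, structures[[s]], mode = mode,
                         criteria = criteria, hbond_table = ht)
    thermal_unfolding(net, cutoffs)
  })
  n <- nrow(maps[[1]]$rc)
  arr <- array(NA_real_, dim = c(n, n, length(maps)))
  for (s in seq_along(maps)) arr[, , s] <- maps[[s]]$rc
  n_ok <- apply(!is.na(arr), c(1, 2), sum)
  mean_rc <- apply(arr, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  list(mean_rc = mean_rc, n_ok = n_ok, maps = arr,
       body_resid = maps[[1]]$body_resid, cutoffs = cutoffs)
}

#' Difference stability map with per-pair Welch tests
#'
#' `Delta rc_ij = mean rc_ij(reference) - mean rc_ij(perturbed)` (the
#' wild-type-minus-mutant orientation: positive means the pair is more stable
#' in the reference), Welch-tested per pair across structures at level
#' `alpha`. Pairs with the sentinel on either side in more than half the
#' structures are masked, not tested.
#'
#' @param reference,perturbed Results of [ensemble_stability_map()] on the
#'   same residue universe.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `difference_map`: `delta`, `p`, `significant`
#'   (logical mask), `masked`.
#' @export
difference_map <- function(reference, perturbed, alpha = 0.05) {
  if (nrow(reference$mean_rc) != nrow(perturbed$mean_rc))
    stop("residue universe mismatch")
  n <- nrow(reference$mean_rc)
  ns_ref <- dim(reference$maps)[3]
  ns_per <- dim(perturbed$maps)[3]
  delta <- reference$mean_rc - perturbed$mean_rc
  p <- matrix(NA_real_, n, n)
  masked <- matrix(FALSE, n, n)
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (v < u) { p[u, v] <- p[v, u]; masked[u, v] <- masked[v, u]; next }
    a <- reference$maps[u, v, ]
    b <- perturbed$maps[u, v, ]
    if (mean(is.na(a)) > 0.5 || mean(is.na(b)) > 0.5) {
      masked[u, v] <- TRUE
      next
    }
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) { masked[u, v] <- TRUE; next }
    p[u, v] <- welch_test(a, b)$p
  }
  structure(list(delta = delta, p = p,
                 significant = !is.na(p) & p < alpha & !masked,
                 masked = masked, alpha = alpha,
                 body_resid = reference$body_resid),
            class = "difference_map")
}

#' @export
print.difference_map <- function(x, ...) {
  cat(sprintf("difference stability map: %d significant pairs (alpha = %.2f), %d masked\n",
              sum(x$significant[upper.tri(x$significant)]), x$alpha,
              sum(x$masked[upper.tri(x$masked)])))
  invisible(x)
}
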