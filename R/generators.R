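## Synthetic-ensemble generators with machine-readable ground truth.
##
## All randomness flows from one integer seed. Per-generator, per-replicate
## streams are derived by a stable string hash of (seed, generator name,
## replicate index), so adding a generator never perturbs another's stream.

#' Derive a deterministic sub-seed
#'
#' Stable 31-bit polynomial string hash of `(seed, name, replicate)`. Used
#' internally by every generator; exported so external code can reproduce a
#' generator's stream.
#'
#' @param seed Global integer seed.
#' @param name Generator name.
#' @param replicate Replicate index.
#' @return Integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, name, replicate = 1L) {
  key <- paste(seed, name, replicate, sep = "/")
  h <- 17
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

#' Harmonic (Gaussian-fluctuation) ensemble generator
#'
#' Every frame is the reference structure plus i.i.d. isotropic Gaussian
#' displacements with per-coordinate standard deviation `sigma[i]` for atom
#' i, so the expected RMSF of atom i is `sigma[i] * sqrt(3)`.
#'
#' @param reference_top A [topology()].
#' @param reference_coords Matrix `n_atoms x 3`, the mean structure.
#' @param sigma Per-atom displacement SD (Angstrom); scalar is recycled.
#' @param n_frames Frames per replicate.
#' @param n_replicates Number of replicates.
#' @param seed Global seed.
#' @param frame_interval ps between frames.
#' @return An [ensemble()].
#' @export
gen_harmonic_ensemble <- function(reference_top, reference_coords, sigma,
                                  n_frames = 2000, n_replicates = 3,
                                  seed = 1, frame_interval = 20) {
  na <- nrow(reference_coords)
  sigma <- rep_len(sigma, na)
  if (any(sigma < 0)) stop("sigma must be nonnegative")
  reps <- lapply(seq_len(n_replicates), function(r) {
    set.seed(derive_seed(seed, "harmonic", r))
    arr <- array(0, dim = c(n_frames, na, 3))
    for (f in seq_len(n_frames)) {
      arr[f, , ] <- reference_coords +
        matrix(stats::rnorm(3 * na, sd = rep(sigma, 3)), ncol = 3)
    }
    arr
  })
  ensemble(reference_top, reps, frame_interval = frame_interval)
}

## unit vector helper
unitv <- function(v) v / sqrt(sum(v^2))

## minimal bridge-site solute: a donor-capable hydroxyl endpoint (pseudo-SER;
## CB-OG-HG) and a phosphate-like acceptor triad (PO4: P,O1,O2,O3), `gap`
## Angstrom between OG and O1 along +x.
bridge_site_topology <- function(n_waters_total) {
  nm <- c("CB", "OG", "HG", "P", "O1", "O2", "O3")
  el <- c("C", "O", "H", "P", "O", "O", "O")
  rid <- c(1, 1, 1, 2, 2, 2, 2)
  rnm <- c(rep("SER", 3), rep("PO4", 4))
  ch <- rep("A", 7)
  for (w in seq_len(n_waters_total)) {
    nm <- c(nm, "O", "H1", "H2")
    el <- c(el, "O", "H", "H")
    rid <- c(rid, rep(2 + w, 3))
    rnm <- c(rnm, rep("HOH", 3))
    ch <- c(ch, rep("W", 3))
  }
  topology(name = nm, element = el, resid = rid, resname = rnm, chain = ch)
}

#' Binding-site water-bridge generator
#'
#' Builds a minimal two-endpoint solute (donor hydroxyl vs phosphate acceptor
#' triad) with the endpoints `gap` Angstrom apart, and explicit waters. In a
#' Bernoulli(`occupancy`) subset of frames, exactly `n_bridge_waters` waters
#' are placed on the donor-acceptor axis so that every link of the chain
#' satisfies the strong hydrogen-bond criteria (O-O spacing `gap/(k+1)`,
#' near-linear donor-H-acceptor angles); otherwise the bridge waters sit far
#' off-site. Decoy waters violating the chain criteria are present in all
#' frames. Ground-truth per-frame bridge labels are returned.
#'
#' @param gap Donor-acceptor O...O distance, Angstrom (7-8.5 is the
#'   catalytic-site regime; 2-3 waters can bridge it).
#' @param occupancy Designed fraction of bridged frames, in `[0, 1]`.
#' @param n_bridge_waters Waters in the designed chain.
#' @param decoy_waters Number of non-bridging waters.
#' @param n_frames,n_replicates,seed,frame_interval As in
#'   [gen_harmonic_ensemble()].
#' @param d_strong Strong H-bond heavy-atom cutoff used for the feasibility
#'   check (Angstrom).
#' @param jitter SD of the Gaussian positional noise added to every atom.
#' @return List with `ensemble` and `truth` (list of logical per-frame
#'   bridge labels, one vector per replicate).
#' @export
gen_bridge_site <- function(gap = 7.5, occupancy = 0.31, n_bridge_waters = 2,
                            decoy_waters = 4, n_frames = 2000,
                            n_replicates = 3, seed = 1, frame_interval = 20,
                            d_strong = 2.8, jitter = 0.01) {
  stopifnot(occupancy >= 0, occupancy <= 1, n_bridge_waters >= 1)
  link <- gap / (n_bridge_waters + 1)
  if (link > d_strong - 0.05)
    stop("infeasible geometry: gap ", gap, " A cannot be bridged by ",
         n_bridge_waters, " water(s) under d_strong = ", d_strong, " A")
  nw <- n_bridge_waters + decoy_waters
  top <- bridge_site_topology(nw)
  na <- nrow(top)

  base <- matrix(0, na, 3)
  base[1, ] <- c(-1.4, 0, 0)                       # CB
  base[2, ] <- c(0, 0, 0)                          # OG (donor endpoint)
  base[3, ] <- c(0.98, 0, 0)                       # HG on the chain axis
  base[5, ] <- c(gap, 0, 0)                        # O1 (acceptor endpoint)
  base[4, ] <- c(gap + 1.6, 0, 0)                  # P
  base[6, ] <- c(gap + 2.1, 1.3, 0)                # O2
  base[7, ] <- c(gap + 2.1, -1.3, 0)               # O3
  widx <- function(w) 7 + (w - 1) * 3 + 1:3        # O,H1,H2 of water w
  bridged_water_pos <- function(w) {
    o <- c(link * w, 0, 0)
    rbind(o, o + c(0.96, 0, 0), o + c(0, 0.96, 0)) # H1 toward next O
  }
  parked_water_pos <- function(w) {
    o <- c(link * w, 12 + 4 * w, 0)
    rbind(o, o + c(0.96, 0, 0), o + c(0, 0.96, 0))
  }
  for (d in seq_len(decoy_waters)) {
    ## decoys: >= 4 A apart, >= 6 A from the axis -> no qualifying links
    o <- c(-2 + 4 * d, -6, 3)
    base[widx(n_bridge_waters + d), ] <- rbind(o, o + c(0.96, 0, 0),
                                               o + c(0, 0.96, 0))
  }

  truth <- vector("list", n_replicates)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(derive_seed(seed, "bridge_site", r))
    lab <- stats::runif(n_frames) < occupancy
    arr <- array(0, dim = c(n_frames, na, 3))
    for (f in seq_len(n_frames)) {
      fr <- base
      for (w in seq_len(n_bridge_waters)) {
        fr[widx(w), ] <- if (lab[f]) bridged_water_pos(w) else
          parked_water_pos(w)
      }
      arr[f, , ] <- fr + matrix(stats::rnorm(3 * na, sd = jitter), ncol = 3)
    }
    truth[[r]] <- lab
    reps[[r]] <- arr
  }
  list(ensemble = ensemble(top, reps, frame_interval = frame_interval),
       truth = truth)
}

## ---- ideal-helix backbone construction -------------------------------------

## place atom d given positions a,b,c, bond length |cd|, angle b-c-d (deg),
## and dihedral a-b-c-d (deg): standard internal-coordinate (NeRF) placement
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unitv(c - b)
  n <- unitv(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

## build an n-residue poly-ALA backbone (N, CA, C per residue) from phi/psi
build_backbone <- function(n_res, phi, psi, omega = 180) {
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  b_NCa <- 1.458; b_CaC <- 1.525; b_CN <- 1.329
  a_NCaC <- 111.2; a_CaCN <- 116.2; a_CNCa <- 121.7
  xyz <- matrix(NA_real_, 3 * n_res, 3)
  xyz[1, ] <- c(0, 0, 0)
  xyz[2, ] <- c(b_NCa, 0, 0)
  xyz[3, ] <- place_atom(c(0, 1, 0), xyz[1, ], xyz[2, ], b_CaC, a_NCaC,
                         phi[1])
  for (i in 2:n_res) {
    Np <- xyz[3 * (i - 2) + 1, ]; CAp <- xyz[3 * (i - 2) + 2, ]
    Cp <- xyz[3 * (i - 2) + 3, ]
    N <- place_atom(Np, CAp, Cp, b_CN, a_CaCN, psi[i - 1])
    CA <- place_atom(CAp, Cp, N, b_NCa, a_CNCa, omega)
    C <- place_atom(Cp, N, CA, b_CaC, a_NCaC, phi[i])
    xyz[3 * (i - 1) + 1:3, ] <- rbind(N, CA, C)
  }
  xyz
}

#' Helix/coil switching ensemble generator
#'
#' Builds an ideal alpha-helical backbone (phi = -57, psi = -47 degrees;
#' atoms N, CA, C, O, amide H). Independently per residue and frame, with
#' probability `loop_prob[i]`, the residue is toggled to a coil state whose
#' carbonyl oxygen is reoriented away from the helix axis, destroying the
#' i -> i+4 (and i -> i+3) backbone hydrogen bond that residue accepts while
#' leaving every other residue's geometry untouched. Ground-truth loop labels
#' are returned per frame and residue.
#'
#' @param n_res Number of residues (>= 6).
#' @param loop_prob Per-residue loop probability in `[0, 1]`; scalar recycled.
#' @param n_frames,n_replicates,seed,frame_interval As in
#'   [gen_harmonic_ensemble()].
#' @return List with `ensemble` and `truth` (list of `n_frames x n_res`
#'   logical matrices).
#' @export
gen_helix_coil_ensemble <- function(n_res, loop_prob = 0, n_frames = 1000,
                                    n_replicates = 3, seed = 1,
                                    frame_interval = 20) {
  if (n_res < 6) stop("n_res must be >= 6 (helix assignment needs i+4)")
  loop_prob <- rep_len(loop_prob, n_res)
  stopifnot(all(loop_prob >= 0), all(loop_prob <= 1))

  bb <- build_backbone(n_res, phi = -57, psi = -47)
  Nx <- bb[3 * (seq_len(n_res) - 1) + 1, , drop = FALSE]
  CAx <- bb[3 * (seq_len(n_res) - 1) + 2, , drop = FALSE]
  Cx <- bb[3 * (seq_len(n_res) - 1) + 3, , drop = FALSE]

  ## helix-state carbonyl O: in-plane, opposite the next N
  O_helix <- matrix(NA_real_, n_res, 3)
  for (i in seq_len(n_res)) {
    if (i < n_res) {
      d <- unitv(unitv(Cx[i, ] - CAx[i, ]) + unitv(Cx[i, ] - Nx[i + 1, ]))
    } else {
      d <- unitv(Cx[i, ] - CAx[i, ])
    }
    O_helix[i, ] <- Cx[i, ] + 1.229 * d
  }
  ## coil-state carbonyl O: flipped through C, pointing into the helix core;
  ## removes the acceptor geometry without moving N, CA, C, or H
  O_coil <- Cx - (O_helix - Cx)

  ## amide H (none on residue 1)
  H <- matrix(NA_real_, n_res, 3)
  for (i in 2:n_res) {
    H[i, ] <- Nx[i, ] + 0.98 * unitv(unitv(Nx[i, ] - Cx[i - 1, ]) +
                                       unitv(Nx[i, ] - CAx[i, ]))
  }

  nm <- c(); el <- c(); rid <- c()
  rows <- list()
  for (i in seq_len(n_res)) {
    atoms <- rbind(Nx[i, ], CAx[i, ], Cx[i, ], O_helix[i, ])
    names_i <- c("N", "CA", "C", "O")
    if (i > 1) { atoms <- rbind(atoms, H[i, ]); names_i <- c(names_i, "H") }
    rows[[i]] <- atoms
    nm <- c(nm, names_i)
    el <- c(el, substr(names_i, 1, 1))
    rid <- c(rid, rep(i, length(names_i)))
  }
  base <- do.call(rbind, rows)
  top <- topology(name = nm, element = el, resid = rid, resname = "ALA",
                  chain = "A")
  o_row <- which(top$name == "O")           # row of O for residue i

  truth <- vector("list", n_replicates)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(derive_seed(seed, "helix_coil", r))
    lab <- matrix(stats::runif(n_frames * n_res) <
                    rep(loop_prob, each = n_frames), n_frames, n_res)
    arr <- array(0, dim = c(n_frames, nrow(base), 3))
    for (f in seq_len(n_frames)) {
      fr <- base
      coil <- which(lab[f, ])
      if (length(coil) > 0) fr[o_row[coil], ] <- O_coil[coil, , drop = FALSE]
      arr[f, , ] <- fr
    }
    truth[[r]] <- lab
    reps[[r]] <- arr
  }
  list(ensemble = ensemble(top, reps, frame_interval = frame_interval),
       truth = truth)
}

#' Effective-energy time-series generator
#'
#' `value(t) = mean + slope * t + N(0, noise_sd)` with t in ns on a grid of
#' `frame_interval` ps.
#'
#' @param mean Mean effective energy, kcal/mol.
#' @param slope Drift, kcal/mol/ns.
#' @param noise_sd Gaussian noise SD, kcal/mol.
#' @param n_frames Frames per replicate (>= 2).
#' @param n_replicates,seed As in [gen_harmonic_ensemble()].
#' @param frame_interval ps between snapshots (default 20, i.e. 4000
#'   snapshots cover 80 ns).
#' @return List of [energy_series()] objects, one per replicate.
#' @export
gen_energy_series <- function(mean = -20, slope = 0, noise_sd = 0,
                              n_frames = 4000, n_replicates = 3, seed = 1,
                              frame_interval = 20) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  t_ns <- (seq_len(n_frames) - 1) * frame_interval / 1000
  lapply(seq_len(n_replicates), function(r) {
    set.seed(derive_seed(seed, "energy_series", r))
    v <- mean + slope * t_ns + stats::rnorm(n_frames, sd = noise_sd)
    energy_series(t_ns, v)
  })
}

#' Random body-bar constraint-network generator
#'
#' Bodies carry generic (seeded uniform) attachment points so the framework
#' is generic; the rigid-cluster decomposition is therefore computable by the
#' rigidity-matrix rank oracle used in the test suite.
#'
#' @param n_bodies Number of rigid bodies.
#' @param bars Data frame with columns `i`, `j`, `mult` (multiplicity 1-6);
#'   or `NULL` to draw `n_bars` random bars.
#' @param n_bars Number of random bars when `bars` is `NULL`.
#' @param seed Global seed.
#' @return A [constraint_network()].
#' @export
gen_bar_network <- function(n_bodies, bars = NULL, n_bars = NULL, seed = 1) {
  set.seed(derive_seed(seed, "bar_network", 1L))
  if (is.null(bars)) {
    if (is.null(n_bars)) n_bars <- 2 * n_bodies
    i <- sample.int(n_bodies, n_bars, replace = TRUE)
    j <- sample.int(n_bodies, n_bars, replace = TRUE)
    ok <- i != j
    bars <- data.frame(i = pmin(i, j)[ok], j = pmax(i, j)[ok], mult = 1L)
  } else {
    bars <- as.data.frame(bars)
    if (is.null(bars$mult)) bars$mult <- 1L
  }
  if (any(bars$i == bars$j)) stop("self-loop bars are not allowed")
  if (any(bars$mult < 1 | bars$mult > 6)) stop("multiplicity must be 1..6")
  ## expand multiplicity into individual bars with their own attachments
  i <- rep(bars$i, bars$mult)
  j <- rep(bars$j, bars$mult)
  nb <- length(i)
  att <- matrix(stats::runif(6 * nb, -1, 1), nb, 6)
  constraint_network(
    n_bodies = n_bodies,
    bars = data.frame(i = i, j = j, mult = 1L, origin = "covalent",
                      energy = NA_real_,
                      ax = att[, 1], ay = att[, 2], az = att[, 3],
                      bx = att[, 4], by = att[, 5], bz = att[, 6])
  )
}
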