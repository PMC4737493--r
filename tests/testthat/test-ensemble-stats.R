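## Superposition, RMSD/RMSF, core region, distances, hydrogen-bond and
## salt-bridge occupancies, and the significance-test wrappers.

test_that("superposition on identical and rigidly moved frames is exact", {
  set.seed(1)
  A <- matrix(rnorm(24), 8)
  expect_equal(superpose(A, A)$rmsd, 0, tolerance = 1e-10)
  expect_equal(superpose(A, A)$rotation, diag(3), tolerance = 1e-8)
  B <- sweep(A, 2, c(5, 0, 0), "+")
  expect_equal(superpose(B, A)$rmsd, 0, tolerance = 1e-10)
})

test_that("superposition rmsd is invariant under random rigid motions", {
  set.seed(2)
  A <- matrix(rnorm(30), 10)
  B <- A + matrix(rnorm(30, sd = 0.3), 10)
  base <- superpose(B, A)$rmsd
  for (k in 1:10) {
    R <- random_rotation()
    t <- rnorm(3, sd = 5)
    Bm <- sweep(B %*% t(R), 2, t, "+")
    sp <- superpose(Bm, A)
    expect_equal(sp$rmsd, base, tolerance = 1e-8)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
  }
})

test_that("superposition attains the minimum found by direct optimization", {
  ## 4-atom toy with one displaced atom; oracle: optimize over Euler angles
  A <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  B <- A; B[4, ] <- B[4, ] + c(0.6, -0.4, 0.5)
  kabsch <- superpose(B, A)$rmsd
  obj <- function(par) {
    ca <- cos(par[1]); sa <- sin(par[1])
    cb <- cos(par[2]); sb <- sin(par[2])
    cc <- cos(par[3]); sc <- sin(par[3])
    R <- matrix(c(cb * cc, -cb * sc, sb,
                  sa * sb * cc + ca * sc, -sa * sb * sc + ca * cc, -sa * cb,
                  -ca * sb * cc + sa * sc, ca * sb * sc + sa * cc, ca * cb),
                3, 3, byrow = TRUE)
    Bc <- sweep(B, 2, colMeans(B))
    Ac <- sweep(A, 2, colMeans(A))
    sqrt(mean(rowSums((Bc %*% t(R) - Ac)^2)))
  }
  set.seed(3)
  best <- min(vapply(1:20, function(k)
    stats::optim(runif(3, -pi, pi), obj)$value, numeric(1)))
  expect_equal(kabsch, best, tolerance = 1e-3)
})

test_that("collinear or tiny fit selections are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
  expect_error(superpose(line[1:2, ], line[1:2, ]), "at least 3")
})

test_that("rmsd series is zero for static and co-moving systems", {
  rs <- gen_helix_coil_ensemble(8, 0, n_frames = 6, n_replicates = 2,
                                seed = 5)$ensemble
  out <- rmsd_series(rs, equilibration = 0)
  expect_lt(max(unlist(out$series)), 1e-8)

  ## ligand co-moving rigidly with the protein: zero ligand RMSD after fit
  top <- rs$topology
  prot <- seq_len(nrow(top))
  base <- get_frame(rs, 1, 1)
  lig_top <- topology(name = c(top$name, "P1", "P2", "P3"),
                      element = c(top$element, "P", "P", "P"),
                      resid = c(top$resid, 99, 99, 99),
                      resname = c(top$resname, "ADP", "ADP", "ADP"),
                      chain = c(top$chain, "L", "L", "L"))
  lig_xyz <- rbind(base, matrix(c(10, 0, 0, 10, 2, 0, 10, 0, 2), 3,
                                byrow = TRUE))
  frames <- array(NA_real_, c(4, nrow(lig_xyz), 3))
  set.seed(6)
  for (f in 1:4) {
    R <- random_rotation()
    frames[f, , ] <- sweep(lig_xyz %*% t(R), 2, rnorm(3, sd = 3), "+")
  }
  ens <- ensemble(lig_top, list(frames))
  out2 <- rmsd_series(ens, fit_selection = prot,
                      measure_selection = "resid 99", equilibration = 0)
  expect_lt(max(unlist(out2$series)), 1e-8)
})

test_that("harmonic rmsd matches the Gaussian closed form within 5%", {
  rs <- gen_helix_coil_ensemble(10, 0, n_frames = 1, n_replicates = 1,
                                seed = 7)$ensemble
  ref <- get_frame(rs, 1, 1)
  sigma <- 0.5
  ens <- gen_harmonic_ensemble(rs$topology, ref, sigma, n_frames = 1500,
                               n_replicates = 1, seed = 7)
  out <- rmsd_series(ens, reference = ref, equilibration = 0)
  expect_equal(out$stat$grand_mean, sqrt(3) * sigma,
               tolerance = 0.05)
})

test_that("rmsf recovers heterogeneous designed amplitudes (0.74 vs 1.00 A)", {
  rs <- gen_helix_coil_ensemble(10, 0, n_frames = 1, n_replicates = 1,
                                seed = 8)$ensemble
  ref <- get_frame(rs, 1, 1)
  n <- nrow(ref)
  design <- ifelse(seq_len(n) <= n / 2, 0.74, 1.00)
  ens <- gen_harmonic_ensemble(rs$topology, ref, design / sqrt(3),
                               n_frames = 2000, n_replicates = 2, seed = 8)
  rf <- rmsf(ens, equilibration = 0)
  lo <- seq_len(n) <= n / 2
  expect_lt(abs(mean(rf$mean[lo]) - 0.74) / 0.74, 0.05)
  expect_lt(abs(mean(rf$mean[!lo]) - 1.00), 0.05)
  expect_true(all(rf$sem >= 0))
})

test_that("core region keeps the lowest-RMSF fraction with serial tie-breaks", {
  r <- c(0.5, 0.4, 0.9, 0.3, 0.8, 0.2, 1.5, 0.6, 0.7, 2.0)
  expect_identical(core_region(r, 1:10, 0.9), sort(order(r)[1:9]))
  expect_identical(core_region(r, 1:10, 1.0), 1:10)
  ## all-equal: lowest serials win
  expect_identical(core_region(rep(1, 10), 11:20, 0.9), 11:19)
  expect_error(core_region(numeric(0)), "empty")
})

test_that("distance series: fixed pair, centroid identity, min-mode brute force", {
  top <- topology(name = c("NH1", "O1", "A1", "A2", "A3", "B1", "B2"),
                  element = c("N", "O", "C", "C", "C", "C", "C"),
                  resid = c(1, 2, 3, 3, 3, 4, 4),
                  resname = c("ARG", "GGP", "X", "X", "X", "Y", "Y"))
  xyz <- rbind(c(0, 0, 0), c(3.06, 0, 0),
               c(1, 1, 0), c(2, 5, 1), c(-1, 2, 2),
               c(4, 4, 4), c(0.5, 1.2, 0.4))
  frames <- array(rep(xyz, each = 3), c(3, 7, 3))
  ens <- ensemble(top, list(frames, frames))
  d <- distance_series(ens, "name NH1", "name O1", mode = "centroid",
                       equilibration = 0)
  expect_equal(d$stat$grand_mean, 3.06, tolerance = 1e-9)
  expect_equal(d$stat$sem, 0)

  expect_warning(
    d0 <- distance_series(ens, "resid 3", "resid 3", mode = "centroid",
                          equilibration = 0), "overlap")
  expect_equal(d0$stat$grand_mean, 0)

  dm <- distance_series(ens, "resid 3", "resid 4", mode = "min",
                        equilibration = 0)
  brute <- min(as.numeric(gsdyn:::pairwise_dist(xyz[3:5, ], xyz[6:7, ])))
  expect_equal(dm$stat$grand_mean, brute, tolerance = 1e-9)
})

hb_fixture <- function(d, angle_deg) {
  ## donor O at origin, H on the x axis, acceptor placed so that the
  ## donor-H-acceptor angle equals angle_deg and |D-A| = d
  top <- topology(name = c("OG", "HG", "OP"), element = c("O", "H", "O"),
                  resid = c(1, 1, 2), resname = c("SER", "SER", "PO4"))
  h <- c(0.97, 0, 0)
  ## acceptor on a ray from H making the requested angle with (D - H)
  th <- angle_deg * pi / 180
  dir <- c(cos(pi - th), sin(pi - th), 0)
  ## choose the distance from H so that |D-A| = d
  f <- function(s) sqrt(sum((h + s * dir)^2)) - d
  s <- stats::uniroot(f, c(0.01, d + 2))$root
  xyz <- rbind(c(0, 0, 0), h, h + s * dir)
  ensemble(top, array(rep(xyz, each = 1), c(1, 3, 3)))
}

test_that("hydrogen-bond criteria classify distance/angle combinations", {
  crit <- hbond_criteria()
  ev <- hbond_events(hb_fixture(2.7, 150), "name OG", "name OP", crit)
  expect_equal(ev$class, "strong")
  ev2 <- hbond_events(hb_fixture(3.0, 150), "name OG", "name OP", crit)
  expect_equal(ev2$class, "weak")
  ev3 <- hbond_events(hb_fixture(2.7, 100), "name OG", "name OP", crit)
  expect_equal(nrow(ev3), 0)
  ## boundaries are inclusive (just-inside values classify as strong)
  ev4 <- hbond_events(hb_fixture(2.8 - 1e-4, 120 + 0.01), "name OG",
                      "name OP", crit)
  expect_equal(ev4$class, "strong")
  ## donor without hydrogen falls back to distance-only, with warning
  noH <- hb_fixture(2.7, 150)
  keep <- noH$topology$name != "HG"
  top2 <- noH$topology[keep, ]
  class(top2) <- c("topology", "data.frame")
  ens2 <- ensemble(top2, matrix(noH$replicates[[1]][1, keep, ], ncol = 3))
  expect_warning(ev5 <- hbond_events(ens2, "name OG", "name OP", crit),
                 "distance-only")
  expect_equal(ev5$class, "strong")
})

test_that("strong events are a subset of weak events on generated ensembles", {
  g <- gen_bridge_site(occupancy = 0.5, n_frames = 40, n_replicates = 1,
                       seed = 9, jitter = 0.15)
  ens <- g$ensemble
  don <- select_atoms(ens$topology, "water and name O")
  acc <- select_atoms(ens$topology, "name O1 O2 O3")
  ev <- hbond_events(ens, don, acc)
  key <- function(e) paste(e$replicate, e$frame, e$donor, e$acceptor)
  expect_true(all(key(ev[ev$class == "strong", ]) %in% key(ev)))
  occ_s <- occupancy(ev, n_frames = 40, class_level = "strong")
  occ_w <- occupancy(ev, n_frames = 40, class_level = "weak")
  expect_lte(occ_s$grand_mean, occ_w$grand_mean)
})

test_that("occupancy counts frames with at least one event", {
  present <- list(c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(occupancy(present)$grand_mean, 0.5)
  expect_equal(occupancy(list(rep(TRUE, 5)))$grand_mean, 1)
  expect_equal(occupancy(list(rep(FALSE, 5)))$grand_mean, 0)
})

test_that("salt bridges use the strict 4.0 A distance-only rule", {
  mk <- function(d) {
    top <- topology(name = c("NH1", "OD1"), element = c("N", "O"),
                    resid = 1:2, resname = c("ARG", "ASP"))
    ensemble(top, rbind(c(0, 0, 0), c(d, 0, 0)))
  }
  expect_equal(salt_bridge_occupancy(mk(2.63), "name NH1",
                                     "name OD1")$grand_mean, 1)
  expect_equal(salt_bridge_occupancy(mk(4.0), "name NH1",
                                     "name OD1")$grand_mean, 0)
  ## alternating 3 A / 5 A
  top <- topology(name = c("NH1", "OD1"), element = c("N", "O"),
                  resid = 1:2, resname = c("ARG", "ASP"))
  arr <- array(0, c(4, 2, 3))
  arr[, 2, 1] <- c(3, 5, 3, 5)
  ens <- ensemble(top, list(arr))
  expect_equal(salt_bridge_occupancy(ens, "name NH1",
                                     "name OD1")$grand_mean, 0.5)
})

test_that("t-test wrappers match the standard definitions and conventions", {
  expect_equal(welch_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(t_test_two_sided(c(1, 2, 3), c(1, 2, 3))$t, 0)
  ## degenerate zero-variance samples
  expect_equal(t_test_two_sided(c(2, 2), c(2, 2))$p, 1)
  expect_error(t_test_two_sided(c(2, 2), c(3, 3)), "degenerate")
  ## closed form: t = mean / (sd / sqrt(n))
  x <- c(2.0, 2.1, 1.9)
  tt <- one_sample_t(x, 0)
  t_ref <- mean(x) / (sd(x) / sqrt(3))
  expect_equal(tt$t, t_ref, tolerance = 1e-12)
  expect_equal(tt$p, 2 * pt(-abs(t_ref), df = 2), tolerance = 1e-12)
  expect_lt(tt$p, 0.05)
})

test_that("replicate SEM shrinks as 1/sqrt(n) on replicated generators", {
  set.seed(10)
  means <- rnorm(12)
  s3 <- replicate_stat(means[1:3])
  s12 <- replicate_stat(means)
  expect_equal(s3$sem, sd(means[1:3]) / sqrt(3))
  expect_equal(s12$sem, sd(means) / sqrt(12))
  expect_gte(s3$sem, 0)
})
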