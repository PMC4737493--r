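## Water density grids, RDFs, and water-mediated bridge detection.

water_box_topology <- function(n_waters, box = NULL, extra = NULL) {
  nm <- rep("O", n_waters); el <- rep("O", n_waters)
  rid <- seq_len(n_waters); rnm <- rep("HOH", n_waters)
  ch <- rep("W", n_waters)
  if (!is.null(extra)) {
    nm <- c(extra$name, nm); el <- c(extra$element, el)
    rid <- c(extra$resid, rid + max(extra$resid))
    rnm <- c(extra$resname, rnm); ch <- c(extra$chain, ch)
  }
  topology(name = nm, element = el, resid = rid, resname = rnm, chain = ch,
           box = box)
}

test_that("grid counts are conserved and localize a pinned water", {
  top <- water_box_topology(1)
  xyz <- matrix(c(2.0, 3.0, 4.0), 1)
  arr <- array(rep(xyz, each = 10), c(10, 1, 3))
  grids <- density_grid(ensemble(top, list(arr)), "water and name O",
                        region = list(min = c(0, 0, 0), max = c(6, 6, 6)),
                        equilibration = 0)
  g <- grids[[1]]
  expect_equal(sum(g$counts), 10)
  expect_equal(max(g$counts), 10)
})

test_that("an empty water selection yields an all-zero grid", {
  top <- topology(name = "CA", element = "C", resid = 1, resname = "ALA")
  ens <- ensemble(top, matrix(c(1, 1, 1), 1))
  suppressWarnings(
    grids <- density_grid(ens, "resname HOH",
                          region = list(min = c(0, 0, 0),
                                        max = c(3, 3, 3))))
  expect_equal(sum(grids[[1]]$counts), 0)
})

test_that("uniform random waters produce Poisson cell counts", {
  n_wat <- 60; n_frames <- 60
  top <- water_box_topology(n_wat)
  set.seed(202)
  arr <- array(runif(n_frames * n_wat * 3, 0, 10), c(n_frames, n_wat, 3))
  ens <- ensemble(top, list(arr))
  g <- density_grid(ens, "water", region = list(min = c(0, 0, 0),
                                                max = c(10, 10, 10)),
                    spacing = 2, equilibration = 0)[[1]]
  ## counts conserved exactly
  expect_equal(sum(g$counts), n_wat * n_frames)
  lambda <- n_wat * n_frames / prod(g$dim)
  obs <- as.numeric(g$counts)
  ## chi-square goodness of fit against Poisson(lambda), pooled tails
  ks <- 0:max(obs)
  pr <- dpois(ks, lambda)
  breaks_keep <- which(pr * length(obs) >= 5)
  pool <- function(x) c(sum(x[seq_len(min(breaks_keep) - 1)]),
                        x[breaks_keep],
                        sum(x[-seq_len(max(breaks_keep))]))
  expected <- pool(pr * length(obs))
  counts_tab <- tabulate(obs + 1, nbins = length(ks))
  observed <- pool(counts_tab)
  keep <- expected > 0
  stat <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  pval <- pchisq(stat, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("isopleth threshold is the stated fraction of the maximum", {
  g <- structure(list(origin = c(0, 0, 0), spacing = 1, dim = c(2, 2, 2),
                      counts = array(c(10, 4, 8, 1, 0, 9, 2, 3), c(2, 2, 2)),
                      n_frames = 10), class = "density_grid")
  iso <- isopleth_threshold(g, 0.8)
  expect_equal(iso$threshold, 8)
  expect_equal(sum(iso$mask), 3)          # cells 10, 8, 9
  iso1 <- isopleth_threshold(g, 1.0)
  expect_equal(sum(iso1$mask), 1)         # only the argmax
  iso0 <- isopleth_threshold(g, 1e-9)
  expect_equal(sum(iso0$mask), sum(g$counts > 0))
  g$counts[] <- 0L
  expect_error(isopleth_threshold(g), "all-zero")
})

test_that("OpenDX export is well-formed and re-readable", {
  g <- structure(list(origin = c(0, 0, 0), spacing = 0.5, dim = c(3, 2, 2),
                      counts = array(seq_len(12), c(3, 2, 2)),
                      n_frames = 1), class = "density_grid")
  f <- withr::local_tempfile(fileext = ".dx")
  write_dx(g, f)
  lines <- readLines(f)
  expect_match(lines[1], "counts 3 2 2")
  items <- as.numeric(unlist(strsplit(trimws(
    lines[(which(grepl("data follows", lines)) + 1):(length(lines) - 2)]),
    "[[:space:]]+")))
  expect_length(items, 12)
  ## z varies fastest
  expect_equal(items[1:4], c(g$counts[1, 1, 1], g$counts[1, 1, 2],
                             g$counts[1, 2, 1], g$counts[1, 2, 2]))
})

test_that("ideal-gas RDF is unity within 3 SEM over the mid range", {
  n_wat <- 250
  box <- c(20, 20, 20)
  extra <- list(name = "SG", element = "S", resid = 1, resname = "CYS",
                chain = "A")
  top <- water_box_topology(n_wat, box = box, extra = extra)
  n_frames <- 40
  reps <- lapply(1:3, function(r) {
    set.seed(300 + r)
    arr <- array(NA_real_, c(n_frames, n_wat + 1, 3))
    for (f in seq_len(n_frames)) {
      arr[f, 1, ] <- box / 2
      arr[f, -1, ] <- matrix(runif(n_wat * 3, 0, 20), ncol = 3)
    }
    arr
  })
  ens <- ensemble(top, reps)
  prof <- rdf(ens, "name SG", "water and name O", dr = 0.25, r_max = 8,
              equilibration = 0)
  mid <- prof$r > 1 & prof$r < 8
  dev <- abs(prof$mean[mid] - 1)
  ## Poisson counting floor for the 3-replicate SEM estimate
  lam_tot <- prof$reference_density * 4 * pi * prof$r[mid]^2 * 0.25 *
    n_frames * 3
  floor_se <- sqrt(1 / lam_tot)
  expect_true(all(dev < 3 * pmax(prof$sem[mid], floor_se) + 0.02))
  expect_true(all(prof$g >= 0))
})

shell_ensemble <- function(n_shell, radius = 2.8, n_frames = 5, seed = 1) {
  extra <- list(name = "OG", element = "O", resid = 1, resname = "SER",
                chain = "A")
  top <- water_box_topology(n_shell, extra = extra)
  set.seed(seed)
  dirs <- matrix(rnorm(n_shell * 3), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  xyz <- rbind(c(0, 0, 0), dirs * radius)
  ensemble(top, array(rep(xyz, each = n_frames),
                      c(n_frames, n_shell + 1, 3)))
}

test_that("a glued shell of waters gives a single RDF peak at its radius", {
  ens <- shell_ensemble(12, radius = 2.8)
  prof <- rdf(ens, "name OG", "water and name O", dr = 0.2, r_max = 6,
              equilibration = 0)
  peak_bin <- which.max(prof$mean)
  expect_equal(prof$r[peak_bin], 2.7, tolerance = 0.11)
  expect_true(all(prof$mean[-peak_bin] == 0))
})

test_that("first-shell peak heights scale with designed water counts (30% ratio)", {
  p1 <- rdf(shell_ensemble(13, seed = 2), "name OG", "water and name O",
            dr = 0.2, r_max = 6, equilibration = 0)
  p2 <- rdf(shell_ensemble(10, seed = 3), "name OG", "water and name O",
            dr = 0.2, r_max = 6, equilibration = 0)
  ## same count-matched normalization volume, so peak ratio ~ 13/10
  ratio <- max(p1$mean) * p1$reference_density /
    (max(p2$mean) * p2$reference_density)
  expect_equal(ratio, 1.3, tolerance = 0.05)
})

## hand-built linear chain OG - (waters) - O1 with given link length; link
## lengths above d_strong exercise the weak class, which the generator's
## strong-by-construction geometry cannot
bridge_frame <- function(link = 2.7, n_waters = 1) {
  gap <- link * (n_waters + 1)
  if (link <= 2.75) {
    g <- gen_bridge_site(gap = gap, occupancy = 1, n_bridge_waters = n_waters,
                         decoy_waters = 0, n_frames = 1, n_replicates = 1,
                         seed = 5, jitter = 0)
    return(list(top = g$ensemble$topology, xyz = get_frame(g$ensemble, 1, 1)))
  }
  nm <- c("CB", "OG", "HG", "P", "O1", "O2", "O3")
  el <- c("C", "O", "H", "P", "O", "O", "O")
  rid <- c(1, 1, 1, 2, 2, 2, 2)
  rnm <- c(rep("SER", 3), rep("PO4", 4))
  ch <- rep("A", 7)
  xyz <- rbind(c(-1.4, 0, 0), c(0, 0, 0), c(0.98, 0, 0),
               c(gap + 1.6, 0, 0), c(gap, 0, 0),
               c(gap + 2.1, 1.3, 0), c(gap + 2.1, -1.3, 0))
  for (w in seq_len(n_waters)) {
    nm <- c(nm, "O", "H1", "H2"); el <- c(el, "O", "H", "H")
    rid <- c(rid, rep(2 + w, 3)); rnm <- c(rnm, rep("HOH", 3))
    ch <- c(ch, rep("W", 3))
    o <- c(link * w, 0, 0)
    xyz <- rbind(xyz, o, o + c(0.96, 0, 0), o + c(0, 0.96, 0))
  }
  list(top = topology(name = nm, element = el, resid = rid, resname = rnm,
                      chain = ch),
       xyz = xyz)
}

test_that("constructed single-water chains are found at the right class", {
  fr <- bridge_frame(2.7, 1)
  a <- select_atoms(fr$top, "name OG")
  b <- select_atoms(fr$top, "name O1 O2 O3")
  strong <- find_bridges(fr$top, fr$xyz, a, b, class_level = "strong")
  expect_length(strong, 1)
  expect_equal(strong[[1]]$n_waters, 1)

  fr2 <- bridge_frame(3.0, 1)
  weak <- find_bridges(fr2$top, fr2$xyz, a, b, class_level = "weak")
  strong2 <- find_bridges(fr2$top, fr2$xyz, a, b, class_level = "strong")
  expect_gte(length(weak), 1)
  expect_length(strong2, 0)
})

test_that("the depth bound excludes chains longer than max_waters", {
  fr <- bridge_frame(2.6, 4)   # valid 4-water chain only
  a <- select_atoms(fr$top, "name OG")
  b <- select_atoms(fr$top, "name O1 O2 O3")
  expect_length(find_bridges(fr$top, fr$xyz, a, b, class_level = "weak",
                             max_waters = 3), 0)
  expect_gte(length(find_bridges(fr$top, fr$xyz, a, b, class_level = "weak",
                                 max_waters = 4)), 1)
  expect_error(find_bridges(fr$top, fr$xyz, a, b, max_waters = 0),
               "max_waters")
})

test_that("bridge search equals exhaustive enumeration on random frames", {
  crit <- hbond_criteria()
  base <- gen_bridge_site(gap = 7.5, occupancy = 1, n_bridge_waters = 2,
                          decoy_waters = 4, n_frames = 1, n_replicates = 1,
                          seed = 6, jitter = 0)
  top <- base$ensemble$topology
  a <- select_atoms(top, "name OG")
  b <- select_atoms(top, "name O1 O2 O3")
  wat_o <- which(top$resname == "HOH" & top$element == "O")
  set.seed(404)
  for (k in 1:25) {
    xyz <- get_frame(base$ensemble, 1, 1)
    ## scatter all waters over the site region to randomize connectivity
    for (w in wat_o) {
      shift <- runif(3, c(-1, -3, -2), c(9, 3, 2)) - xyz[w, ]
      xyz[w + 0:2, ] <- sweep(xyz[w + 0:2, , drop = FALSE], 2, -shift)
    }
    for (cl in c("strong", "weak")) {
      found <- length(find_bridges(top, xyz, a, b, crit, cl)) > 0
      oracle <- brute_force_bridge(top, xyz, a, b, crit, cl)
      expect_identical(found, oracle)
    }
  }
})

test_that("strong bridge frequency never exceeds weak, and recovery is binomial", {
  g <- gen_bridge_site(occupancy = 0.31, n_frames = 500, n_replicates = 3,
                       seed = 7)
  fw <- bridge_frequency(g$ensemble, "name OG", "name O1 O2 O3",
                         class_level = "weak", equilibration = 0)
  fs <- bridge_frequency(g$ensemble, "name OG", "name O1 O2 O3",
                         class_level = "strong", equilibration = 0)
  expect_lte(fs$grand_mean, fw$grand_mean)
  truth <- mean(vapply(g$truth, mean, numeric(1)))
  expect_equal(fs$grand_mean, truth, tolerance = 1e-12)
  se <- sqrt(0.31 * 0.69 / (500 * 3))
  expect_lt(abs(fs$grand_mean - 0.31), 3 * se)
})
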