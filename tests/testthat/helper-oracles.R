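## Independent oracles used to pin the implementation.

## ---- generic body-bar rigidity-matrix rank/null-space oracle ----------------
## A bar between attachment point a (on body i) and b (on body j) constrains
## u . (v_i + w_i x a - v_j - w_j x b) = 0 with u = a - b; unknowns per body
## are (w, v) in R^6. Internal DOF = nullity - 6 * n_components; two bodies
## are mutually rigid iff every null-space vector gives them identical rigid
## motions (w_u = w_v, v_u = v_v).

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

rigidity_matrix <- function(net) {
  bars <- net$bars
  n <- net$n_bodies
  m <- nrow(bars)
  R <- matrix(0, m, 6 * n)
  for (k in seq_len(m)) {
    a <- as.numeric(bars[k, c("ax", "ay", "az")])
    b <- as.numeric(bars[k, c("bx", "by", "bz")])
    u <- a - b
    i <- bars$i[k]; j <- bars$j[k]
    R[k, (6 * (i - 1) + 1):(6 * (i - 1) + 3)] <- cross3(a, u)
    R[k, (6 * (i - 1) + 4):(6 * (i - 1) + 6)] <- u
    R[k, (6 * (j - 1) + 1):(6 * (j - 1) + 3)] <-
      R[k, (6 * (j - 1) + 1):(6 * (j - 1) + 3)] - cross3(b, u)
    R[k, (6 * (j - 1) + 4):(6 * (j - 1) + 6)] <-
      R[k, (6 * (j - 1) + 4):(6 * (j - 1) + 6)] - u
  }
  R
}

components_of <- function(net) {
  n <- net$n_bodies
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_len(nrow(net$bars)))
    parent[find(net$bars$i[k])] <- find(net$bars$j[k])
  comp <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(comp, levels = unique(comp)))
}

rank_oracle <- function(net, tol = 1e-8) {
  n <- net$n_bodies
  comp <- components_of(net)
  if (nrow(net$bars) == 0) {
    return(list(dof = 0L, cluster = seq_len(n),
                rank = 0L, n_components = n))
  }
  R <- rigidity_matrix(net)
  sv <- svd(R)
  rank <- sum(sv$d > tol * max(sv$d, 1))
  nullity <- 6 * n - rank
  ## null-space basis
  NS <- if (nullity > 0) svd(R, nv = 6 * n)$v[, (rank + 1):(6 * n),
                                              drop = FALSE] else
    matrix(0, 6 * n, 0)
  rigid_pair <- function(u, v) {
    if (comp[u] != comp[v]) return(FALSE)
    if (ncol(NS) == 0) return(TRUE)
    du <- NS[(6 * (u - 1) + 1):(6 * u), , drop = FALSE]
    dv <- NS[(6 * (v - 1) + 1):(6 * v), , drop = FALSE]
    max(abs(du - dv)) < 1e-6
  }
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (u in seq_len(max(n - 1, 0))) for (v in (u + 1):n) {
    if (find(u) != find(v) && rigid_pair(u, v))
      parent[find(u)] <- find(v)
  }
  cl <- vapply(seq_len(n), find, integer(1))
  list(dof = as.integer(nullity - 6 * length(unique(comp))),
       cluster = as.integer(factor(cl, levels = unique(cl))),
       rank = rank, n_components = length(unique(comp)))
}

## partitions equal up to relabeling
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

## ---- brute-force water-bridge oracle ---------------------------------------
## enumerate every ordered tuple of distinct waters of size 1..max_waters and
## test all links directly; returns TRUE iff some chain connects a to b
brute_force_bridge <- function(top, coords, endpoint_a, endpoint_b,
                               criteria, class_level, max_waters = 3) {
  waters <- which(top$resname %in% water_resnames() & top$element == "O")
  hmap <- gsdyn:::attached_hydrogens(top, coords)
  ok <- function(p, q) {
    cl <- gsdyn:::link_class(coords, p, q, hmap, criteria)
    !is.na(cl) && (class_level == "weak" || cl == "strong")
  }
  tuples <- list()
  for (k in seq_len(min(max_waters, length(waters)))) {
    perm <- gtools_permutations(waters, k)
    for (r in seq_len(nrow(perm))) tuples[[length(tuples) + 1]] <- perm[r, ]
  }
  for (tu in tuples) {
    for (a in endpoint_a) for (b in endpoint_b) {
      chain <- c(a, tu, b)
      links <- vapply(seq_len(length(chain) - 1), function(s)
        ok(chain[s], chain[s + 1]), logical(1))
      if (all(links)) return(TRUE)
    }
  }
  FALSE
}

## all ordered k-permutations of v (tiny n only)
gtools_permutations <- function(v, k) {
  if (k == 1) return(matrix(v, ncol = 1))
  out <- NULL
  for (i in seq_along(v)) {
    sub <- gtools_permutations(v[-i], k - 1)
    out <- rbind(out, cbind(v[i], sub))
  }
  out
}

## ---- Kabsch-Sander energy, written out independently ------------------------
ks_energy_oracle <- function(C, O, N, H) {
  q1q2f <- 0.42 * 0.20 * 332
  dist <- function(p, q) sqrt(sum((p - q)^2))
  ## 0.084 * 332 = 27.888 = q1*q2*f of the original parameterization
  q1q2f * (1 / dist(O, N) + 1 / dist(C, H) - 1 / dist(O, H) - 1 / dist(C, N))
}

## ---- misc fixtures ----------------------------------------------------------
## tiny 50-atom topology for selection-algebra enumeration
fixture_topology_50 <- function() {
  nm <- rep(c("N", "CA", "C", "O", "CB"), 10)
  topology(name = nm, element = substr(nm, 1, 1),
           resid = rep(1:10, each = 5),
           resname = rep(c("ALA", "CYS", "SER", "ARG", "HOH"), each = 10),
           chain = rep(c("A", "B"), each = 25))
}

## random proper rotation matrix
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2), 3, 3, byrow = TRUE)
}

## chain-backbone network with random energy-labelled H-bond bars
random_hbond_network <- function(seed, n_bodies = 8) {
  set.seed(seed)
  backbone <- data.frame(i = seq_len(n_bodies - 1), j = 2:n_bodies,
                         mult = 5L, origin = "covalent", energy = NA_real_)
  k <- 4 + seed %% 4
  i <- sample.int(n_bodies, k, replace = TRUE)
  j <- sample.int(n_bodies, k, replace = TRUE)
  ok <- i != j
  hb <- data.frame(i = pmin(i, j)[ok], j = pmax(i, j)[ok], mult = 5L,
                   origin = "hbond",
                   energy = -round(runif(sum(ok), 0.5, 5.5), 1))
  constraint_network(n_bodies, rbind(backbone, hb))
}
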