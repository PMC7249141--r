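# Independent oracles and small generators used across the test files.
# These deliberately avoid the package's own implementation paths.

# Horn quaternion-eigenvalue superposition: independent check of Kabsch.
quaternion_rmsd_oracle <- function(ref, mov) {
  n <- nrow(ref)
  q <- sweep(ref, 2, colMeans(ref))
  p <- sweep(mov, 2, colMeans(mov))
  S <- t(p) %*% q
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(p^2) + sum(q^2) - 2 * lam) / n))
}

# Brute-force topology oracle: enumerate angles/dihedrals by path search.
brute_force_topology <- function(nbrs) {
  n <- length(nbrs)
  angles <- list(); dihedrals <- list()
  for (i in seq_len(n)) for (j in nbrs[[i]]) for (k in nbrs[[j]]) {
    if (k != i && i < k) angles[[length(angles) + 1L]] <- c(i, j, k)
  }
  for (i in seq_len(n)) for (j in nbrs[[i]]) for (k in nbrs[[j]]) {
    if (k == i) next
    for (l in nbrs[[k]]) {
      if (l == j || l == i) next
      if (j < k) dihedrals[[length(dihedrals) + 1L]] <- c(i, j, k, l)
    }
  }
  list(angles = angles, dihedrals = dihedrals)
}

# random connected molecule-like graph on n atoms (random tree + extra edges)
random_test_molecule <- function(n, seed, extra_edges = 0) {
  set.seed(seed)
  bonds <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1, 1), 0L))
  k <- 0
  while (k < extra_edges) {
    cand <- sort(sample.int(n, 2))
    if (!any(bonds[, 1] == cand[2] & bonds[, 2] == cand[1]) &&
        !any(bonds[, 1] == cand[1] & bonds[, 2] == cand[2])) {
      bonds <- rbind(bonds, rev(cand))
      k <- k + 1
    }
  }
  molecule(paste0("rand", seed), rep("C", n), rep("c3", n), rep(0, n),
           matrix(rnorm(3 * n, sd = 3), n, 3), bonds)
}

sorted_tuples <- function(m, canon) {
  if (!length(m)) return(character(0))
  if (is.list(m)) m <- do.call(rbind, m)
  sort(apply(m, 1, function(r) paste(canon(r), collapse = "-")))
}

canon_angle_idx <- function(r) if (r[1] <= r[3]) r else rev(r)
canon_dihedral_idx <- function(r) {
  if (r[2] < r[3] || (r[2] == r[3] && r[1] <= r[4])) r else rev(r)
}

# direct-formula gradient of the total energy by central differences
fd_gradient <- function(mol, top, ff, terms = NULL, h = 1e-5) {
  if (is.null(terms)) terms <- c("bond", "angle", "dihedral", "improper",
                                 "nonbond")
  n <- nrow(mol$xyz)
  g <- matrix(0, n, 3)
  for (a in seq_len(n)) for (d in 1:3) {
    mp <- mol; mp$xyz[a, d] <- mp$xyz[a, d] + h
    mm <- mol; mm$xyz[a, d] <- mm$xyz[a, d] - h
    g[a, d] <- (energy(mp, top, ff, terms = terms)$total -
                  energy(mm, top, ff, terms = terms)$total) / (2 * h)
  }
  g
}

random_rotation <- function(seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(A)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

fixture_cache <- new.env()
cached_fixture <- function(name = "diethoxyborinic_acid") {
  if (is.null(fixture_cache[[name]])) fixture_cache[[name]] <- build_fixture(name)
  fixture_cache[[name]]
}
cached_min_fixture <- function() {
  if (is.null(fixture_cache$minimized)) {
    bu <- cached_fixture()
    fixture_cache$minimized <- minimize(bu$molecule, bu$topology,
                                        bu$forcefield, gtol = 1e-4)
  }
  fixture_cache$minimized
}
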