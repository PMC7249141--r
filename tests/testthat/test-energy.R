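test_that("bond energy matches the hand-computed harmonic value", {
  bu <- cached_fixture("toy_bond")
  mol <- bu$molecule
  mol$xyz[2, 1] <- 1.472   # r - req = 0.1 A
  e <- energy(mol, bu$topology, bu$forcefield, terms = "bond")
  expect_equal(e$bond, 350.221 * 0.1^2, tolerance = 1e-10)  # = 3.50221
  expect_equal(e$total, e$bond)
})

test_that("an isolated LJ pair at its minimum gives -eps_ij", {
  mol <- molecule("lj", c("B", "O"), c("B", "ob"), c(0, 0),
                  rbind(c(0, 0, 0), c(1.98 + 1.6612, 0, 0)), NULL)
  ff <- forcefield()
  ff <- ff_add_nonbond(ff, "B", 1.98, 0.034)
  ff <- ff_add_nonbond(ff, "ob", 1.6612, 0.2100)
  e <- energy(mol, enumerate_topology(mol), ff, terms = "nonbond")
  expect_equal(e$vdw, -sqrt(0.034 * 0.2100), tolerance = 1e-12)
  expect_equal(e$coulomb, 0)
})

test_that("two-term torsion energies match hand evaluation", {
  bu <- cached_fixture("toy_dihedral")
  # (2.350/2)(1+cos 0) + (1.654/2)(1+cos 0) = 4.004 at phi = 0
  e0 <- energy(bu$molecule, bu$topology, bu$forcefield, terms = "dihedral")
  expect_equal(e0$dihedral, 4.004, tolerance = 1e-9)
  m90 <- set_dihedral(bu$molecule, c(1, 2, 3, 4), 90)
  e90 <- energy(m90, bu$topology, bu$forcefield, terms = "dihedral")
  expect_equal(e90$dihedral, 2.350 / 2, tolerance = 1e-9)
})

test_that("energy breakdown total equals the component sum", {
  bu <- cached_fixture()
  e <- energy(bu$molecule, bu$topology, bu$forcefield)
  expect_equal(e$total,
               e$bond + e$angle + e$dihedral + e$improper + e$vdw + e$coulomb,
               tolerance = 1e-12)
})

test_that("analytic gradient matches finite differences on random conformers", {
  bu <- cached_fixture()
  mol <- bu$molecule
  worst <- 0
  for (seed in 1:20) {
    set.seed(seed)
    m <- mol
    m$xyz <- m$xyz + matrix(rnorm(57, 0, 0.06), 19, 3)
    g <- gradient(m, bu$topology, bu$forcefield)
    gfd <- fd_gradient(m, bu$topology, bu$forcefield)
    worst <- max(worst, max(abs(g - gfd)) / max(abs(gfd)))
  }
  expect_lt(worst, 1e-6)
})

test_that("gradient is zero at a bond minimum and translation invariant", {
  bu <- cached_fixture("toy_bond")
  g <- gradient(bu$molecule, bu$topology, bu$forcefield, terms = "bond")
  expect_lt(max(abs(g)), 1e-12)

  full <- cached_fixture()
  g1 <- gradient(full$molecule, full$topology, full$forcefield)
  shifted <- full$molecule
  shifted$xyz <- shifted$xyz + matrix(c(1.3, -2.1, 0.7), 19, 3, byrow = TRUE)
  g2 <- gradient(shifted, full$topology, full$forcefield)
  expect_equal(g1, g2, tolerance = 1e-9)
})

test_that("energy is invariant under rigid rotation plus translation", {
  bu <- cached_fixture()
  e1 <- energy(bu$molecule, bu$topology, bu$forcefield)$total
  for (seed in 1:5) {
    R <- random_rotation(seed)
    m <- bu$molecule
    m$xyz <- m$xyz %*% t(R) + matrix(rnorm(3), 19, 3, byrow = TRUE)
    e2 <- energy(m, bu$topology, bu$forcefield)$total
    expect_equal(e2, e1, tolerance = 1e-9)
  }
})

test_that("torsion energy is 360-degree periodic", {
  bu <- cached_fixture("toy_dihedral")
  for (phi in c(-170, -35, 10, 120)) {
    e1 <- energy(set_dihedral(bu$molecule, c(1, 2, 3, 4), phi),
                 bu$topology, bu$forcefield, terms = "dihedral")$dihedral
    e2 <- energy(set_dihedral(bu$molecule, c(1, 2, 3, 4), phi + 360),
                 bu$topology, bu$forcefield, terms = "dihedral")$dihedral
    expect_equal(e1, e2, tolerance = 1e-9)
  }
})

test_that("numerical Hessian of a harmonic bond has the analytic spectrum", {
  bu <- cached_fixture("toy_bond")
  h <- numerical_hessian(bu$molecule, bu$topology, bu$forcefield,
                         terms = "bond")
  blk <- -h$matrix[1:3, 4:6]
  ev <- eigen((blk + t(blk)) / 2, symmetric = TRUE)$values
  expect_equal(sort(ev, decreasing = TRUE), c(2 * 350.221, 0, 0),
               tolerance = 1e-3)
  # translation invariance: every 3-column row block sums to ~0
  n <- 2
  rs <- sapply(seq_len(3), function(d)
    rowSums(h$matrix[, seq(d, 3 * n, by = 3), drop = FALSE]))
  expect_lt(max(abs(rs)), 1e-4)
})

test_that("numerical Hessian is symmetric before symmetrization", {
  bu <- cached_fixture("toy_angle")
  # recompute the raw asymmetry with the same stencil the package uses
  sys_terms <- c("bond", "angle")
  n <- 3; step <- 1e-4
  H <- matrix(0, 9, 9)
  for (a in seq_len(n)) for (d in 1:3) {
    mp <- bu$molecule; mp$xyz[a, d] <- mp$xyz[a, d] + step
    mm <- bu$molecule; mm$xyz[a, d] <- mm$xyz[a, d] - step
    gp <- gradient(mp, bu$topology, bu$forcefield, terms = sys_terms)
    gm <- gradient(mm, bu$topology, bu$forcefield, terms = sys_terms)
    H[3 * (a - 1) + d, ] <- as.vector(t(gp - gm)) / (2 * step)
  }
  expect_lt(max(abs(H - t(H))), 1e-4)
})

test_that("minimization reaches the gradient tolerance and does not wander", {
  bu <- cached_fixture("toy_bond")
  stretched <- bu$molecule
  stretched$xyz[2, 1] <- 1.9
  m <- minimize(stretched, bu$topology, bu$forcefield, gtol = 1e-6,
                terms = "bond")
  expect_lt(abs(atom_distance(m$xyz, 1, 2) - 1.372), 1e-5)

  again <- minimize(m, bu$topology, bu$forcefield, gtol = 1e-6,
                    terms = "bond")
  expect_equal(again$xyz, m$xyz, tolerance = 1e-6)
})

test_that("harmonic-only minimum puts every bond at its equilibrium length", {
  bu <- cached_fixture()
  m <- minimize(bu$molecule, bu$topology, bu$forcefield, gtol = 1e-6,
                terms = c("bond", "angle"))
  ty <- m$atoms$type
  for (r in seq_len(nrow(bu$topology$bonds))) {
    ij <- bu$topology$bonds[r, ]
    req <- lookup_bond(bu$forcefield, ty[ij])$req
    expect_lt(abs(atom_distance(m$xyz, ij[1], ij[2]) - req), 0.01)
  }
})

test_that("zero_dihedral removes exactly the targeted terms", {
  bu <- cached_fixture("toy_dihedral")
  ffz <- zero_dihedral(bu$forcefield, c("h1", "ob", "B", "ob"))
  e <- energy(bu$molecule, bu$topology, ffz, terms = "dihedral")
  expect_equal(e$dihedral, 0)
  expect_equal(ffz$bonds, bu$forcefield$bonds)
  expect_equal(ffz$angles, bu$forcefield$angles)
  expect_identical(zero_dihedral(ffz, c("h1", "ob", "B", "ob")), ffz)
  expect_error(zero_dihedral(bu$forcefield, c("q", "q", "q", "q")),
               "no dihedral")

  # zeroing one quadruple leaves other torsions untouched
  full <- cached_fixture()
  ffz2 <- zero_dihedral(full$forcefield, c("h1", "ob", "B", "ob"))
  kept <- lookup_dihedral(ffz2, c("ob", "B", "ob", "c3"))
  expect_equal(sort(kept$Vn), c(1.472, 1.980))
})

test_that("overlapping atoms are rejected", {
  mol <- molecule("clash", c("B", "O"), c("B", "ob"), c(0.1, -0.1),
                  rbind(c(0, 0, 0), c(1e-9, 0, 0)), NULL)
  ff <- forcefield()
  ff <- ff_add_nonbond(ff, "B", 1.98, 0.034)
  ff <- ff_add_nonbond(ff, "ob", 1.6612, 0.2100)
  expect_error(energy(mol, enumerate_topology(mol), ff, terms = "nonbond"),
               "overlap")
})

test_that("unresolvable parameters are reported by tuple", {
  bu <- cached_fixture("toy_bond")
  expect_error(energy(bu$molecule, bu$topology, forcefield(),
                      terms = "bond"), "B-ob|ob-B")
})
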