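test_that("unit conversion is correct and idempotent", {
  m <- diag(6)
  h <- hessian_data(m, units = "hartree/bohr^2", natoms = 2)
  conv <- convert_units(h)
  expect_equal(conv$units, "kcal/mol/A^2")
  expect_equal(conv$matrix[1, 1], 627.509474 / 0.529177210903^2,
               tolerance = 1e-9)       # ~2240.877
  expect_equal(conv$matrix[1, 1], 2240.877, tolerance = 1e-3)
  expect_identical(convert_units(conv), conv)
  hk <- hessian_data(m, units = "kcal/mol/A^2", natoms = 2)
  expect_identical(convert_units(hk), hk)
  expect_error(hessian_data(m, units = "eV"), "arg")
})

test_that("seminario_bond recovers an isolated harmonic bond exactly", {
  bu <- cached_fixture("toy_bond")
  h <- numerical_hessian(bu$molecule, bu$topology, bu$forcefield,
                         terms = "bond")
  v <- seminario_bond(h, bu$molecule$xyz, 1, 2)
  expect_equal(v[["Kr"]], 350.221, tolerance = 0.001)
  expect_equal(v[["req"]], 1.372, tolerance = 1e-9)
  # req is purely geometric
  v2 <- seminario_bond(h, bu$molecule$xyz * 1.1, 1, 2)
  expect_equal(v2[["req"]], 1.372 * 1.1)
})

test_that("seminario extraction is invariant under rigid rotation", {
  bu <- cached_fixture("toy_angle")
  h0 <- numerical_hessian(bu$molecule, bu$topology, bu$forcefield,
                          terms = c("bond", "angle"))
  b0 <- seminario_bond(h0, bu$molecule$xyz, 1, 2)
  a0 <- seminario_angle(h0, bu$molecule$xyz, 1, 2, 3)
  for (seed in c(11, 12)) {
    R <- random_rotation(seed)
    mr <- bu$molecule
    mr$xyz <- mr$xyz %*% t(R)
    hr <- numerical_hessian(mr, bu$topology, bu$forcefield,
                            terms = c("bond", "angle"))
    br <- seminario_bond(hr, mr$xyz, 1, 2)
    ar <- seminario_angle(hr, mr$xyz, 1, 2, 3)
    expect_equal(br[["Kr"]], b0[["Kr"]], tolerance = 1e-6)
    expect_equal(ar[["Ktheta"]], a0[["Ktheta"]], tolerance = 1e-6)
  }
})

test_that("seminario_angle recovers an isolated bend with stiff arms", {
  bu <- cached_fixture("toy_angle")
  h <- numerical_hessian(bu$molecule, bu$topology, bu$forcefield,
                         terms = c("bond", "angle"))
  v <- seminario_angle(h, bu$molecule$xyz, 1, 2, 3)
  expect_equal(v[["Ktheta"]], 104.357, tolerance = 0.02)
  expect_equal(v[["theta_eq"]], 120.00, tolerance = 1e-6)
})

test_that("collinear arms and degenerate bonds are rejected", {
  xyz <- rbind(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0))
  h <- hessian_data(diag(9), natoms = 3)
  expect_error(seminario_angle(h, xyz, 1, 2, 3), "collinear")
  expect_error(seminario_bond(h, rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)),
                              1, 2), "near-zero")
})

test_that("extract_all averages symmetry-equivalent instances per type", {
  bu <- cached_fixture()
  mh <- mm_hessian_fixture(bu)
  res <- extract_all(mh$molecule, bu$topology, mh$hessian)
  # the two ob-c3 bonds collapse into one averaged row
  row <- res$bonds[res$bonds$t1 == "c3" & res$bonds$t2 == "ob", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$n_instances, 2)
  inst <- res$bond_instances
  both <- inst[inst$t1 == "c3" & inst$t2 == "ob", ]
  expect_equal(row$Kr, mean(both$Kr))
  # boron-oxygen bond constants recover the generating value closely here
  bob <- res$bonds[res$bonds$t1 == "B", ]
  expect_lt(abs(bob$req - 1.372), 0.005)
  expect_equal(bob$Kr, 350.221, tolerance = 0.05)
  # equilibrium geometry is recovered for every Table-1 angle type
  expect_lt(abs(res$angles$theta_eq[res$angles$t1 == "ob" &
                               res$angles$t3 == "ob"] - 120.00), 0.5)
})

test_that("extract_all validates dimensions and handles empty topology", {
  bu <- cached_fixture("toy_bond")
  h <- numerical_hessian(bu$molecule, bu$topology, bu$forcefield,
                         terms = "bond")
  expect_error(extract_all(cached_fixture()$molecule,
                           cached_fixture()$topology, h), "atom count")
  lone <- molecule("atom", "B", "B", 0, matrix(0, 1, 3), NULL)
  hz <- hessian_data(matrix(0, 3, 3), natoms = 1)
  res <- extract_all(lone, enumerate_topology(lone), hz)
  expect_equal(nrow(res$bonds), 0)
  expect_equal(nrow(res$angles), 0)
})

test_that("hessian text format round-trips, including packed triangles", {
  bu <- cached_fixture("toy_angle")
  h <- numerical_hessian(bu$molecule, bu$topology, bu$forcefield,
                         terms = c("bond", "angle"))
  p <- withr::local_tempfile(fileext = ".txt")
  write_hessian(h, p)
  back <- read_hessian(p)
  expect_equal(back$matrix, h$matrix, tolerance = 1e-9)
  expect_equal(back$units, h$units)

  # lower-triangle packed variant
  m <- h$matrix
  tri <- m[lower.tri(m, diag = TRUE)]
  packed <- m
  packed_vals <- unlist(lapply(seq_len(nrow(m)), function(r) m[r, 1:r]))
  writeLines(c(sprintf("hessian kcal/mol/A^2 %d", h$natoms),
               paste(sprintf("%.10e", packed_vals), collapse = " ")), p)
  back2 <- read_hessian(p)
  expect_equal(back2$matrix, h$matrix, tolerance = 1e-9)

  writeLines(c("hessian parsecs 2", "1 2 3"), p)
  expect_error(read_hessian(p), "unit")
})

test_that("the full-fixture harmonic Hessian is positive semidefinite", {
  bu <- cached_fixture()
  mh <- mm_hessian_fixture(bu)
  ev <- eigen(mh$hessian$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-3)
  # zero modes of the bonds+angles surface: 6 rigid-body, 7 free torsions
  # (no dihedral terms active), and the boron out-of-plane umbrella (angle
  # terms respond only quadratically at a planar trivalent center)
  expect_equal(sum(abs(ev) < 1e-3), 14)
  expect_gt(sort(ev, decreasing = TRUE)[3 * 19 - 14], 1)
})
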