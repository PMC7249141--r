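test_that("Kabsch superposition handles exact and rotated copies", {
  set.seed(1)
  P <- matrix(rnorm(15), 5, 3)
  expect_equal(kabsch_superpose(P, P)$rmsd, 0, tolerance = 1e-12)
  R <- random_rotation(4)
  moved <- P %*% t(R) + matrix(c(3, -1, 2), 5, 3, byrow = TRUE)
  fit <- kabsch_superpose(P, moved)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(moved %*% t(fit$rotation) +
                 matrix(fit$translation, 5, 3, byrow = TRUE), P,
               tolerance = 1e-9)
})

test_that("Kabsch equals the quaternion oracle on random instances", {
  worst <- 0
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(4:12, 1)
    A <- matrix(rnorm(3 * n), n, 3)
    B <- A + matrix(rnorm(3 * n, 0, 0.3), n, 3)
    worst <- max(worst, abs(kabsch_superpose(A, B)$rmsd -
                              quaternion_rmsd_oracle(A, B)))
  }
  expect_lt(worst, 1e-9)
})

test_that("collinear point sets are flagged degenerate", {
  P <- cbind(1:5, 0, 0) + 0.0
  fit <- kabsch_superpose(P, P)
  expect_true(fit$degenerate)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
})

test_that("rmsd_ad uses the boron core and ignores rigid motion", {
  ref <- cached_min_fixture()
  expect_equal(rmsd_ad(ref, ref), 0, tolerance = 1e-12)
  # default selection: boron + its three bonded neighbors
  b <- which(ref$atoms$element == "B")
  sel <- sort(c(b, ref$bonds[ref$bonds[, 1] == b, 2],
                ref$bonds[ref$bonds[, 2] == b, 1]))
  expect_length(sel, 4)

  pert <- perturb_structure(ref, 0.1, seed = 7)
  direct <- quaternion_rmsd_oracle(ref$xyz[sel, ], pert$xyz[sel, ])
  expect_equal(rmsd_ad(ref, pert), direct, tolerance = 1e-9)

  R <- random_rotation(9)
  moved <- pert
  moved$xyz <- moved$xyz %*% t(R) + matrix(c(5, 6, 7), 19, 3, byrow = TRUE)
  expect_equal(rmsd_ad(ref, moved), rmsd_ad(ref, pert), tolerance = 1e-9)
  expect_equal(rmsd_ad(ref, moved, "all"), rmsd_ad(ref, pert, "all"),
               tolerance = 1e-9)
})

test_that("rmsd_l matches hand computation", {
  ref <- cached_min_fixture()
  expect_equal(rmsd_l(ref, ref), 0, tolerance = 1e-12)
  # one bond off by 0.1 A among 4 equal bonds -> sqrt(0.01/4) = 0.05
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0), c(4, 0, 0))
  m1 <- molecule("chain", rep("C", 5), rep("c3", 5), rep(0, 5), xyz,
                 cbind(1:4, 2:5))
  m2 <- m1
  m2$xyz[5, 1] <- m2$xyz[5, 1] + 0.1
  expect_equal(rmsd_l(m1, m2), 0.05, tolerance = 1e-12)
  expect_error(rmsd_l(m1, m2, bonds = matrix(0, 0, 2)), "empty")

  pert <- perturb_structure(ref, 0.05, seed = 3)
  dl <- vapply(seq_len(nrow(ref$bonds)), function(r) {
    b <- ref$bonds[r, ]
    sqrt(sum((ref$xyz[b[1], ] - ref$xyz[b[2], ])^2)) -
      sqrt(sum((pert$xyz[b[1], ] - pert$xyz[b[2], ])^2))
  }, 0)
  expect_equal(rmsd_l(ref, pert), sqrt(mean(dl^2)), tolerance = 1e-12)
})

test_that("rmsd_a separates out-of-plane (boron-centered) angles", {
  ref <- cached_min_fixture()
  a0 <- rmsd_a(ref, ref)
  expect_equal(as.numeric(a0), 0, tolerance = 1e-12)
  expect_equal(attr(a0, "outplane"), 0, tolerance = 1e-12)

  # a single angle off by 3 degrees reports exactly 3
  xyz <- rbind(c(1, 0, 0), c(0, 0, 0), c(cos(deg2rad(70)),
                                         sin(deg2rad(70)), 0))
  m1 <- molecule("bend", rep("C", 3), rep("c3", 3), rep(0, 3), xyz,
                 rbind(c(1, 2), c(2, 3)))
  m2 <- m1
  m2$xyz[3, ] <- c(cos(deg2rad(73)), sin(deg2rad(73)), 0)
  expect_equal(as.numeric(rmsd_a(m1, m2)), 3, tolerance = 1e-9)

  # exclusion removes exactly the angles centered on trivalent boron
  pert <- perturb_structure(ref, 0.05, seed = 5)
  angles <- enumerate_topology(ref)$angles
  centered_b <- angles[, 2] == which(ref$atoms$element == "B")
  expect_equal(sum(centered_b), 3)
  d_all <- vapply(seq_len(nrow(angles)), function(r) {
    atom_angle(ref$xyz, angles[r, 1], angles[r, 2], angles[r, 3]) -
      atom_angle(pert$xyz, angles[r, 1], angles[r, 2], angles[r, 3])
  }, 0)
  a <- rmsd_a(ref, pert)
  expect_equal(as.numeric(a), sqrt(mean(d_all[!centered_b]^2)),
               tolerance = 1e-12)
  expect_equal(attr(a, "outplane"), sqrt(mean(d_all[centered_b]^2)),
               tolerance = 1e-12)
  expect_equal(as.numeric(rmsd_a(ref, pert, exclude_out_of_plane = FALSE)),
               sqrt(mean(d_all^2)), tolerance = 1e-12)
})

test_that("report averages reproduce the published Table rows exactly", {
  rows <- data.frame(name = c("IVEKAW02", "TEAMBO04"),
                     rmsd_ad = c(0.206, 0.212),
                     rmsd_l = c(0.0468, 0.0765),
                     rmsd_a = c(2.179, 5.976),
                     rmsd_a_outplane = c(1.442, 3.381))
  rep <- make_report(rows)
  avg <- rep[rep$name == "Average", ]
  expect_equal(avg$rmsd_ad, 0.209)
  expect_equal(avg$rmsd_l, 0.06165)
  expect_equal(avg$rmsd_a, mean(c(2.179, 5.976)))      # 4.0775
  expect_equal(avg$rmsd_a_outplane, mean(c(1.442, 3.381)))  # 2.4115

  one <- make_report(rows[1, ])
  expect_equal(one$rmsd_ad[2], one$rmsd_ad[1])
})

test_that("report built from structures matches the direct metric calls", {
  ref <- cached_min_fixture()
  pert <- perturb_structure(ref, 0.08, seed = 13)
  rep <- make_report(list(list(name = "pert", ref = ref, test = pert)))
  expect_equal(rep$rmsd_ad[1], rmsd_ad(ref, pert), tolerance = 1e-12)
  expect_equal(rep$rmsd_l[1], rmsd_l(ref, pert), tolerance = 1e-12)
  a <- rmsd_a(ref, pert)
  expect_equal(rep$rmsd_a[1], as.numeric(a), tolerance = 1e-12)
  expect_equal(rep$rmsd_a_outplane[1], attr(a, "outplane"),
               tolerance = 1e-12)
  expect_equal(rep$rmsd_ad[2], rep$rmsd_ad[1])  # average of one row
})
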