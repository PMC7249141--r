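toy_scan <- function(truth, phi = seq(-180, 180, by = 5), noise = 0,
                     offset = 0, seed = 1, base = NULL) {
  set.seed(seed)
  if (is.null(base)) base <- 0.3 * sin(deg2rad(phi) * 2 + 1)  # fake MM shape
  e_qm <- base + fourier_energy(truth, phi) + offset +
    (if (noise > 0) rnorm(length(phi), 0, noise) else 0)
  dihedral_scan(phi, e_qm, base)
}

test_that("fourier_energy matches hand-evaluated published models", {
  h1 <- fourier_model(c(1, 2), c(2.350, 1.654), c(0, 0))
  expect_equal(fourier_energy(h1, 0), 4.004, tolerance = 1e-12)
  obc <- fourier_model(c(1, 2), c(1.980, 1.472), c(180, 180))
  # at 180: first term at its maximum (1.980), second at its zero
  expect_equal(fourier_energy(obc, 180), 1.980, tolerance = 1e-12)
  expect_equal(fourier_energy(obc, 90), 1.980 / 2 + 1.472, tolerance = 1e-12)
  # periodicity
  expect_equal(fourier_energy(h1, 47), fourier_energy(h1, 47 + 360))
})

test_that("objective is zero on exact data and offset-invariant", {
  truth <- fourier_model(c(1, 3), c(1.2, 0.4), c(0, 180))
  sc <- toy_scan(truth)
  expect_equal(as.numeric(objective(truth, sc)), 0, tolerance = 1e-18)
  sc2 <- sc; sc2$e_qm <- sc2$e_qm + 57.3
  expect_equal(as.numeric(objective(truth, sc2)), 0, tolerance = 1e-18)
  expect_equal(attr(objective(truth, sc2), "K") -
                 attr(objective(truth, sc), "K"), 57.3)
  single <- dihedral_scan(0, 5, 1)
  expect_equal(as.numeric(objective(truth, single)), 0)
})

test_that("the genetic stage is reproducible, elitist and monotone", {
  truth <- fourier_model(c(1, 2), c(2.0, 1.0), c(0, 0))
  sc <- toy_scan(truth)
  cfg <- fit_config(seed = 5, generations = 40, pop_size = 32)
  g1 <- fit_genetic(sc, cfg)
  g2 <- fit_genetic(sc, cfg)
  expect_identical(g1$best$model, g2$best$model)
  expect_identical(g1$best_curve, g2$best_curve)
  expect_true(all(diff(g1$best_curve) <= 1e-12))
  expect_equal(g1$best$objective, min(vapply(g1$population, `[[`, 0,
                                             "objective")))
  expect_error(fit_genetic(dihedral_scan(numeric(0), numeric(0),
                                         numeric(0)), cfg), "empty")
})

test_that("simplex refinement is a fixed point at truth and never worsens", {
  truth <- fourier_model(c(1, 2), c(2.350, 1.654), c(0, 0))
  sc <- toy_scan(truth)
  cfg <- fit_config(seed = 1)
  at_truth <- fit_simplex(truth, sc, cfg)
  expect_equal(at_truth$model$Vn, truth$Vn, tolerance = 1e-6)
  half <- fourier_model(truth$n, truth$Vn / 2, truth$gamma)
  ref <- fit_simplex(half, sc, cfg)
  expect_equal(ref$model$Vn, truth$Vn, tolerance = 1e-3)
  expect_lte(ref$objective, as.numeric(objective(half, sc)))
  # single-barrier variant exercises the 1-D path
  t1 <- fourier_model(2, 1.7, 180)
  sc1 <- toy_scan(t1)
  r1 <- fit_simplex(fourier_model(2, 0.4, 180), sc1, cfg)
  expect_equal(r1$model$Vn, 1.7, tolerance = 1e-4)
})

test_that("hybrid fit recovers arbitrary noiseless models", {
  cfg <- fit_config(seed = 3, generations = 150)
  for (seed in c(2, 9)) {
    set.seed(seed)
    ns <- sort(sample(1:3, 2))
    truth <- fourier_model(ns, round(runif(2, 0.2, 6), 3),
                           sample(c(0, 180), 2, replace = TRUE))
    fit <- fit_hybrid(toy_scan(truth, seed = seed), cfg)
    expect_equal(fit$model$n, truth$n)
    expect_equal(fit$model$gamma, truth$gamma)
    expect_lt(max(abs(fit$model$Vn - truth$Vn)), 1e-2)
    expect_lte(fit$rmse, sqrt(fit_genetic(toy_scan(truth, seed = seed),
                                          cfg)$best$objective / 73) + 1e-12)
  }
})

test_that("hybrid fit tolerates measurement noise", {
  truth <- fourier_model(c(1, 2), c(2.350, 1.654), c(0, 0))
  cfg <- fit_config(seed = 11, generations = 120)
  errs <- vapply(1:6, function(s) {
    fit <- fit_hybrid(toy_scan(truth, noise = 0.1, seed = s), cfg)
    keep <- match(truth$n, fit$model$n)
    max(abs(ifelse(is.na(keep), 0, fit$model$Vn[keep]) - truth$Vn))
  }, 0)
  expect_lt(mean(errs), 0.1)
  # fitted curve stays within 3 sigma of the noisy target everywhere
  sc <- toy_scan(truth, noise = 0.1, seed = 21)
  fit <- fit_hybrid(sc, cfg)
  dev <- sc$e_qm - sc$e_mm_zeroed - fourier_energy(fit$model, sc$phi) - fit$K
  expect_lte(max(abs(dev)), 3 * 0.1)
})

test_that("build_scan computes a zeroed baseline on supplied geometries", {
  bu <- cached_fixture()
  truth <- fourier_model(c(1, 2), c(2.350, 1.654), c(0, 0))
  sc <- synth_scan(bu, c("h1", "ob", "B", "ob"), truth, noise_sd = 0,
                   seed = 1)
  expect_equal(nrow(sc), 73)   # -180..180 in 5-degree steps
  conformers <- attr(sc, "conformers")
  sc2 <- build_scan(conformers, sc$phi, bu$forcefield,
                    types = c("h1", "ob", "B", "ob"))
  expect_equal(sc2$e_mm_zeroed, sc$e_mm_zeroed)  # deterministic rebuild

  # the zeroed dihedral contributes nothing to the baseline
  ffz <- zero_dihedral(bu$forcefield, c("h1", "ob", "B", "ob"))
  top <- bu$topology
  e_direct <- vapply(conformers, function(m)
    energy(m, top, ffz)$total, 0)
  expect_equal(sc$e_mm_zeroed, e_direct, tolerance = 1e-12)

  expect_error(build_scan(conformers, sc$phi + 5, bu$forcefield,
                          types = c("h1", "ob", "B", "ob")), "differs")
})

test_that("scan TSV round-trips", {
  truth <- fourier_model(1, 2, 0)
  sc <- toy_scan(truth)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_scan(sc, p)
  back <- read_scan(p, types = c("h1", "ob", "B", "ob"))
  expect_equal(back$phi, sc$phi)
  expect_equal(back$e_qm, sc$e_qm, tolerance = 1e-9)
  expect_equal(back$e_mm_zeroed, sc$e_mm_zeroed, tolerance = 1e-9)
})
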