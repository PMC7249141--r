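# Fitting truncated-Fourier dihedral terms to a QM-minus-MM torsion profile
# with a genetic algorithm followed by downhill-simplex refinement (the
# paramfit-style protocol). The model is
#   E(phi) = sum_terms (Vn/2) (1 + cos(n phi - gamma)),  gamma in {0, 180},
# and the objective compares profile *shapes*: a global offset K is set to
# its analytic least-squares optimum, so adding any constant to the QM
# energies leaves the fit unchanged.

#' Torsion scan container
#'
#' @param phi Angles in degrees (distinct).
#' @param e_qm Quantum target energies, kcal/mol (arbitrary zero).
#' @param e_mm_zeroed MM energies with the target dihedral's terms zeroed,
#'   kcal/mol.
#' @param types Type-label quadruple of the target dihedral.
#' @return An object of class `dihedral_scan` (a data.frame with attribute
#'   `types`).
#' @export
dihedral_scan <- function(phi, e_qm, e_mm_zeroed, types = c("X", "X", "X", "X")) {
  stopifnot(length(phi) == length(e_qm), length(phi) == length(e_mm_zeroed))
  if (anyDuplicated(phi)) stop("duplicate phi values in scan")
  df <- data.frame(phi = as.numeric(phi), e_qm = as.numeric(e_qm),
                   e_mm_zeroed = as.numeric(e_mm_zeroed))
  structure(df, types = as.character(types),
            class = c("dihedral_scan", "data.frame"))
}

#' Read / write a torsion scan as TSV
#'
#' Columns `phi`, `e_qm` and optionally `e_mm_zeroed` (zero-filled when
#' absent), tab-separated with a header line.
#'
#' @param path File path.
#' @param types Type quadruple to attach on read.
#' @return [read_scan()]: a [dihedral_scan()].
#' @export
read_scan <- function(path, types = c("X", "X", "X", "X")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("phi", "e_qm") %in% names(df)))
    stop("scan file must have columns 'phi' and 'e_qm': ", path)
  if (is.null(df$e_mm_zeroed)) df$e_mm_zeroed <- 0
  dihedral_scan(df$phi, df$e_qm, df$e_mm_zeroed, types)
}

#' @rdname read_scan
#' @param scan A [dihedral_scan()].
#' @export
write_scan <- function(scan, path) {
  utils::write.table(as.data.frame(scan)[c("phi", "e_qm", "e_mm_zeroed")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Truncated-Fourier dihedral model
#'
#' @param n Integer periodicities (1-4, one term per periodicity).
#' @param Vn Barriers, kcal/mol (non-negative).
#' @param gamma Phases, degrees, each 0 or 180.
#' @return An object of class `fourier_model`.
#' @export
fourier_model <- function(n, Vn, gamma) {
  stopifnot(length(n) == length(Vn), length(n) == length(gamma))
  if (anyDuplicated(n)) stop("one term per periodicity")
  if (any(!gamma %in% c(0, 180))) stop("phases must be 0 or 180 degrees")
  if (any(Vn < 0)) stop("Vn must be non-negative")
  structure(list(n = as.integer(n), Vn = as.numeric(Vn),
                 gamma = as.numeric(gamma)), class = "fourier_model")
}

#' @export
print.fourier_model <- function(x, ...) {
  cat("fourier model:\n")
  for (k in seq_along(x$n))
    cat(sprintf("  n=%d  Vn=%8.4f kcal/mol  gamma=%5.0f deg\n",
                x$n[k], x$Vn[k], x$gamma[k]))
  invisible(x)
}

#' Evaluate a Fourier dihedral model
#'
#' `sum_terms (Vn/2)(1 + cos(n phi - gamma))`; the Amber IDIVF divider is
#' applied when terms are assembled into a force field, not here.
#'
#' @param model A [fourier_model()].
#' @param phi Angle(s), degrees.
#' @return Energy in kcal/mol (vectorized over `phi`).
#' @export
fourier_energy <- function(model, phi) {
  phir <- deg2rad(phi)
  out <- numeric(length(phi))
  for (k in seq_along(model$n))
    out <- out + (model$Vn[k] / 2) *
      (1 + cos(model$n[k] * phir - deg2rad(model$gamma[k])))
  out
}

#' Fitting objective (sum of squared shape residuals)
#'
#' `sum_i (e_qm_i - e_mm_zeroed_i - E_model(phi_i) - K)^2` with the offset
#' `K` at its analytic optimum (the mean residual), so the objective
#' depends only on the shape of the profile.
#'
#' @param model A [fourier_model()].
#' @param scan A [dihedral_scan()].
#' @return Scalar objective (kcal^2/mol^2), with attribute `K`.
#' @export
objective <- function(model, scan) {
  res <- scan$e_qm - scan$e_mm_zeroed - fourier_energy(model, scan$phi)
  K <- mean(res)
  structure(sum((res - K)^2), K = K)
}

#' Fit configuration
#'
#' @param periodicities Candidate periodicities (one Vn gene each).
#' @param pop_size GA population size.
#' @param generations GA generations.
#' @param elite_frac Fraction of the population copied unchanged.
#' @param mutation_scale Gaussian mutation s.d. as a fraction of `v_max`.
#' @param phase_flip_prob Per-gene probability of flipping a phase.
#' @param v_max Upper bound of the initial Vn sampling range, kcal/mol.
#' @param simplex_tol Relative convergence tolerance of the simplex stage.
#' @param parsimony Minimum RMSE degradation (kcal/mol) that justifies
#'   keeping an extra Fourier term during model pruning.
#' @param seed Mandatory RNG seed (recorded in the fit result).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(periodicities = 1:3, pop_size = 64, generations = 300,
                       elite_frac = 0.1, mutation_scale = 0.1,
                       phase_flip_prob = 0.05, v_max = 6,
                       simplex_tol = 1e-10, parsimony = 0.05, seed) {
  if (missing(seed)) stop("fit_config requires an explicit seed")
  stopifnot(pop_size > 1, generations > 0, elite_frac > 0, elite_frac <= 1,
            mutation_scale > 0, v_max > 0)
  structure(list(periodicities = as.integer(periodicities),
                 pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 elite_frac = elite_frac, mutation_scale = mutation_scale,
                 phase_flip_prob = phase_flip_prob, v_max = v_max,
                 simplex_tol = simplex_tol, parsimony = parsimony,
                 seed = as.integer(seed)), class = "fit_config")
}

fit_result <- function(model, scan, cfg, history = NULL) {
  obj <- objective(model, scan)
  res <- scan$e_qm - scan$e_mm_zeroed - fourier_energy(model, scan$phi) -
    attr(obj, "K")
  structure(list(model = model, rmse = sqrt(mean(res^2)), residuals = res,
                 K = attr(obj, "K"), objective = as.numeric(obj),
                 config = cfg, history = history), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  print(x$model)
  cat(sprintf("  offset K = %.4f kcal/mol, rmse = %.5f kcal/mol (seed %d)\n",
              x$K, x$rmse, x$config$seed))
  invisible(x)
}

ga_decode <- function(genes, cfg) {
  np <- length(cfg$periodicities)
  fourier_model(cfg$periodicities, pmax(genes[seq_len(np)], 0),
                ifelse(genes[np + seq_len(np)] > 0.5, 180, 0))
}

ga_objective <- function(genes, cfg, scan) {
  np <- length(cfg$periodicities)
  pen <- sum(pmin(genes[seq_len(np)], 0)^2) * 1e4
  as.numeric(objective(ga_decode(genes, cfg), scan)) + pen
}

#' Genetic-algorithm stage of the dihedral fit
#'
#' Genes are one barrier `Vn` per candidate periodicity plus one binary
#' phase (0/180) per term. Tournament selection, uniform crossover,
#' Gaussian barrier mutation and phase flips; elitism guarantees the best
#' objective is non-increasing across generations. Fully reproducible from
#' `cfg$seed`.
#'
#' @param scan A [dihedral_scan()].
#' @param cfg A [fit_config()].
#' @return A list: `best` (a `fit_result`), `population` (list of
#'   `fit_result`, best first), `best_curve` (best objective per
#'   generation).
#' @export
fit_genetic <- function(scan, cfg) {
  if (nrow(scan) == 0) stop("empty scan")
  set.seed(cfg$seed)
  np <- length(cfg$periodicities)
  ng <- 2L * np
  pop <- matrix(stats::runif(cfg$pop_size * ng), cfg$pop_size, ng)
  pop[, seq_len(np)] <- pop[, seq_len(np)] * cfg$v_max
  fit <- apply(pop, 1, ga_objective, cfg = cfg, scan = scan)
  n_elite <- max(1L, ceiling(cfg$elite_frac * cfg$pop_size))
  best_curve <- numeric(cfg$generations)
  for (gen in seq_len(cfg$generations)) {
    ord <- order(fit)
    pop <- pop[ord, , drop = FALSE]
    fit <- fit[ord]
    newpop <- pop
    for (child in seq(n_elite + 1L, cfg$pop_size)) {
      pick <- function() {
        c2 <- sample.int(cfg$pop_size, 2)
        pop[c2[which.min(fit[c2])], ]
      }
      pa <- pick(); pb <- pick()
      mask <- stats::runif(ng) < 0.5
      g <- ifelse(mask, pa, pb)
      mut <- stats::rnorm(np, 0, cfg$mutation_scale * cfg$v_max)
      g[seq_len(np)] <- pmax(0, g[seq_len(np)] + mut)
      flip <- stats::runif(np) < cfg$phase_flip_prob
      g[np + which(flip)] <- 1 - g[np + which(flip)]
      newpop[child, ] <- g
    }
    pop <- newpop
    fit[-seq_len(n_elite)] <- apply(pop[-seq_len(n_elite), , drop = FALSE],
                                    1, ga_objective, cfg = cfg, scan = scan)
    best_curve[gen] <- min(fit)
  }
  ord <- order(fit)
  pop <- pop[ord, , drop = FALSE]
  results <- lapply(seq_len(cfg$pop_size), function(r)
    fit_result(ga_decode(pop[r, ], cfg), scan, cfg))
  list(best = results[[1]], population = results, best_curve = best_curve)
}

#' Simplex refinement of a Fourier model
#'
#' Downhill-simplex (Nelder-Mead; golden-section Brent for a single term)
#' refinement of the barrier heights with periodicities and phases held
#' fixed and the offset K analytic. The returned objective never exceeds
#' the starting model's.
#'
#' @param start A [fourier_model()] fixing periodicities and phases.
#' @param scan A [dihedral_scan()].
#' @param cfg A [fit_config()].
#' @return A `fit_result`.
#' @export
fit_simplex <- function(start, scan, cfg) {
  fn <- function(v) {
    pen <- sum(pmin(v, 0)^2) * 1e4
    m <- start; m$Vn <- pmax(v, 0)
    as.numeric(objective(m, scan)) + pen
  }
  v0 <- start$Vn
  if (length(v0) == 1) {
    opt <- stats::optim(v0, fn, method = "Brent", lower = 0,
                        upper = max(10 * cfg$v_max, 2 * v0 + 1))
  } else {
    opt <- stats::optim(v0, fn, method = "Nelder-Mead",
                        control = list(maxit = 5000,
                                       reltol = cfg$simplex_tol))
  }
  refined <- start
  refined$Vn <- pmax(opt$par, 0)
  if (as.numeric(objective(refined, scan)) >
      as.numeric(objective(start, scan))) refined <- start
  fit_result(refined, scan, cfg)
}

drop_term <- function(model, k) {
  fourier_model(model$n[-k], model$Vn[-k], model$gamma[-k])
}

#' Hybrid genetic + simplex dihedral fit
#'
#' The paramfit-style pipeline: a genetic stage explores barrier heights
#' and phases over the candidate periodicities, the champion is refined by
#' downhill simplex, and near-redundant terms are pruned greedily (a term
#' is dropped when removing it and re-refining degrades the RMSE by less
#' than `cfg$parsimony` kcal/mol).
#'
#' @inheritParams fit_genetic
#' @return A `fit_result`; `$model` holds the final terms, `$rmse` the
#'   root-mean-square residual, `$history` the GA best-objective curve.
#' @export
fit_hybrid <- function(scan, cfg) {
  ga <- fit_genetic(scan, cfg)
  best <- fit_simplex(ga$best$model, scan, cfg)
  repeat {
    if (length(best$model$n) <= 1) break
    k <- which.min(best$model$Vn)
    cand <- fit_simplex(drop_term(best$model, k), scan, cfg)
    if (cand$rmse - best$rmse < cfg$parsimony) best <- cand else break
  }
  best$history <- ga$best_curve
  best
}

#' Convert fitted terms to force-field dihedral entries
#'
#' @param fit A `fit_result` from [fit_hybrid()] or [fit_simplex()].
#' @param types Type quadruple for the fitted dihedral.
#' @param ff Force field to extend (empty by default).
#' @param divider Amber IDIVF for the emitted terms.
#' @return The extended [forcefield()]; serialize with [write_frcmod()] to
#'   get the negative-periodicity multi-term layout.
#' @export
fit_to_forcefield <- function(fit, types, ff = forcefield(), divider = 1) {
  m <- fit$model
  for (k in seq_along(m$n))
    ff <- ff_add_dihedral(ff, types, divider, m$Vn[k], m$gamma[k], m$n[k])
  ff
}

#' Assemble a scan's MM baseline from supplied conformers
#'
#' For each conformer (one per grid angle) the MM energy is evaluated with
#' the target dihedral's terms zeroed ([zero_dihedral()]), on the supplied
#' geometry unchanged — no re-minimization, matching a rigid torsion scan
#' whose QM geometries are reused directly. The torsion measured on the
#' first topology instance of the target quadruple must agree with the
#' declared grid angle to within 1 degree.
#'
#' @param conformers List of [molecule()] objects, one per angle.
#' @param phi Declared grid angles, degrees.
#' @param ff A [forcefield()].
#' @param cfg An [energy_config()].
#' @param types Target dihedral type quadruple.
#' @param e_qm Optional QM energies to store (defaults to zeros).
#' @return A [dihedral_scan()] with `e_mm_zeroed` filled in.
#' @export
build_scan <- function(conformers, phi, ff, cfg = energy_config(), types,
                       e_qm = NULL) {
  stopifnot(length(conformers) == length(phi))
  mol0 <- conformers[[1]]
  top <- enumerate_topology(mol0)
  ffz <- zero_dihedral(ff, types)
  ty <- mol0$atoms$type
  quad <- NULL
  for (r in seq_len(nrow(top$dihedrals))) {
    tq <- ty[top$dihedrals[r, ]]
    if (identical(canon_quad(tq), canon_quad(types))) {
      quad <- top$dihedrals[r, ]
      break
    }
  }
  if (is.null(quad)) stop("no topology dihedral matches ",
                          paste(types, collapse = "-"))
  sys <- compile_system(mol0, top, ffz, cfg)
  emm <- numeric(length(phi))
  for (k in seq_along(conformers)) {
    xyz <- conformers[[k]]$xyz
    measured <- atom_dihedral(xyz, quad[1], quad[2], quad[3], quad[4])
    dd <- abs(((measured - phi[k] + 180) %% 360) - 180)
    if (dd > 1)
      stop(sprintf("conformer %d torsion %.2f deg differs from declared %.2f",
                   k, measured, phi[k]))
    emm[k] <- sum(eval_energy(sys, xyz))
  }
  dihedral_scan(phi, if (is.null(e_qm)) numeric(length(phi)) else e_qm,
                emm, types)
}
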