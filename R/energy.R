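# Amber potential:
#   E = sum Kr (r - req)^2 + sum Ktheta (theta - theta_eq)^2
#     + sum (Vn / (2 IDIVF)) (1 + cos(n phi - gamma))        [+ impropers]
#     + sum_{i<j} A/R^12 - B/R^6 + q_i q_j / (eps R)
# with 1-2 and 1-3 pairs excluded and 1-4 pairs scaled by 1/scnb (vdW) and
# 1/scee (Coulomb). Energies kcal/mol, lengths Angstrom, charges e.

#' Coulomb constant, kcal A / (mol e^2) (Amber's value)
#' @keywords internal
K_COULOMB <- 332.0522173

#' Nonbonded / electrostatic evaluation settings
#'
#' @param dielectric Relative dielectric (1 = vacuum).
#' @param scee 1-4 electrostatic divisor (Amber default 1.2).
#' @param scnb 1-4 van-der-Waals divisor (Amber default 2.0).
#' @param cutoff Nonbonded cutoff in Angstrom; the default 999 means
#'   effectively no cutoff.
#' @return An object of class `energy_config`.
#' @export
energy_config <- function(dielectric = 1, scee = 1.2, scnb = 2.0,
                          cutoff = 999) {
  stopifnot(dielectric > 0, scee > 0, scnb > 0, cutoff > 0)
  structure(list(dielectric = dielectric, scee = scee, scnb = scnb,
                 cutoff = cutoff), class = "energy_config")
}

ALL_TERMS <- c("bond", "angle", "dihedral", "improper", "nonbond")

# Resolve every topology tuple against the force field once, producing flat
# index/parameter arrays so that repeated energy/gradient evaluation (in the
# minimizer and the integrator) is pure vectorized arithmetic.
compile_system <- function(mol, top, ff, cfg = energy_config(),
                           terms = ALL_TERMS) {
  ty <- mol$atoms$type
  n <- n_atoms(mol)
  sys <- list(natoms = n, cfg = cfg, terms = terms)

  if ("bond" %in% terms && nrow(top$bonds)) {
    m <- nrow(top$bonds)
    Kr <- numeric(m); req <- numeric(m)
    for (r in seq_len(m)) {
      hit <- lookup_bond(ff, ty[top$bonds[r, ]])
      if (!nrow(hit)) stop("no bond parameters for ",
                           paste(ty[top$bonds[r, ]], collapse = "-"))
      Kr[r] <- hit$Kr[1]; req[r] <- hit$req[1]
    }
    sys$bond <- list(i = top$bonds[, 1], j = top$bonds[, 2], Kr = Kr, req = req)
  }

  if ("angle" %in% terms && nrow(top$angles)) {
    m <- nrow(top$angles)
    Kt <- numeric(m); t0 <- numeric(m)
    for (r in seq_len(m)) {
      hit <- lookup_angle(ff, ty[top$angles[r, ]])
      if (!nrow(hit)) stop("no angle parameters for ",
                           paste(ty[top$angles[r, ]], collapse = "-"))
      Kt[r] <- hit$Ktheta[1]; t0[r] <- deg2rad(hit$theta_eq[1])
    }
    sys$angle <- list(i = top$angles[, 1], j = top$angles[, 2],
                      k = top$angles[, 3], Kt = Kt, t0 = t0)
  }

  expand_torsions <- function(quads, lookup, what) {
    ii <- integer(0); jj <- integer(0); kk <- integer(0); ll <- integer(0)
    pk <- numeric(0); nn <- numeric(0); gg <- numeric(0)
    for (r in seq_len(nrow(quads))) {
      hit <- lookup(ff, ty[quads[r, ]])
      if (!nrow(hit)) stop("no ", what, " parameters for ",
                           paste(ty[quads[r, ]], collapse = "-"))
      for (h in seq_len(nrow(hit))) {
        ii <- c(ii, quads[r, 1]); jj <- c(jj, quads[r, 2])
        kk <- c(kk, quads[r, 3]); ll <- c(ll, quads[r, 4])
        div <- if (!is.null(hit$divider)) hit$divider[h] else 1
        pk <- c(pk, hit$Vn[h] / (2 * div))
        nn <- c(nn, abs(hit$n[h]))
        gg <- c(gg, deg2rad(hit$gamma[h]))
      }
    }
    list(i = ii, j = jj, k = kk, l = ll, pk = pk, n = nn, gamma = gg)
  }

  if ("dihedral" %in% terms && nrow(top$dihedrals))
    sys$dihedral <- expand_torsions(top$dihedrals, lookup_dihedral, "dihedral")
  if ("improper" %in% terms && nrow(top$impropers))
    sys$improper <- expand_torsions(top$impropers, lookup_improper, "improper")

  if ("nonbond" %in% terms) {
    rmh <- numeric(n); eps <- numeric(n)
    for (a in seq_len(n)) {
      hit <- ff$nonbond[ff$nonbond$type == ty[a], , drop = FALSE]
      if (!nrow(hit)) stop("no nonbond parameters for type ", ty[a])
      rmh[a] <- hit$rmin_half[1]; eps[a] <- hit$epsilon[1]
    }
    all_pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
    key <- function(m) m[, 1] * (n + 1L) + m[, 2]
    excl <- if (nrow(top$excluded)) key(top$excluded) else integer(0)
    p14 <- if (nrow(top$pairs14)) key(top$pairs14) else integer(0)
    keep <- !(key(all_pairs) %in% excl)
    pr <- all_pairs[keep, , drop = FALSE]
    is14 <- key(pr) %in% p14
    i <- pr[, 1]; j <- pr[, 2]
    rstar <- rmh[i] + rmh[j]
    eij <- sqrt(eps[i] * eps[j])
    A <- eij * rstar^12
    B <- 2 * eij * rstar^6
    qq <- K_COULOMB * mol$atoms$charge[i] * mol$atoms$charge[j] /
      cfg$dielectric
    A[is14] <- A[is14] / cfg$scnb
    B[is14] <- B[is14] / cfg$scnb
    qq[is14] <- qq[is14] / cfg$scee
    sys$pairs <- list(i = i, j = j, A = A, B = B, qq = qq)
  }
  sys
}

# scatter-add rows of M into G at (possibly repeated) indices idx
acc_rows <- function(G, idx, M) {
  if (!length(idx)) return(G)
  S <- rowsum(M, idx)
  u <- as.integer(rownames(S))
  G[u, ] <- G[u, ] + S
  G
}

rowdot <- function(A, B) rowSums(A * B)

# angle values (radians) for index vectors, vectorized
angles_rad <- function(xyz, i, j, k) {
  rij <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
  rkj <- xyz[k, , drop = FALSE] - xyz[j, , drop = FALSE]
  dij <- sqrt(rowdot(rij, rij)); dkj <- sqrt(rowdot(rkj, rkj))
  cs <- pmin(1, pmax(-1, rowdot(rij, rkj) / (dij * dkj)))
  acos(cs)
}

cross_rows <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

# signed torsions (radians) for index vectors, vectorized
torsions_rad <- function(xyz, i, j, k, l) {
  b1 <- xyz[j, , drop = FALSE] - xyz[i, , drop = FALSE]
  b2 <- xyz[k, , drop = FALSE] - xyz[j, , drop = FALSE]
  b3 <- xyz[l, , drop = FALSE] - xyz[k, , drop = FALSE]
  n1 <- cross_rows(b1, b2)
  n2 <- cross_rows(b2, b3)
  nb2 <- sqrt(rowdot(b2, b2))
  m1 <- cross_rows(n1, b2 / nb2)
  atan2(rowdot(m1, n2), rowdot(n1, n2))
}

eval_energy <- function(sys, xyz) {
  e <- c(bond = 0, angle = 0, dihedral = 0, improper = 0, vdw = 0,
         coulomb = 0)
  if (!is.null(sys$bond)) {
    b <- sys$bond
    d <- xyz[b$j, , drop = FALSE] - xyz[b$i, , drop = FALSE]
    r <- sqrt(rowdot(d, d))
    e["bond"] <- sum(b$Kr * (r - b$req)^2)
  }
  if (!is.null(sys$angle)) {
    a <- sys$angle
    th <- angles_rad(xyz, a$i, a$j, a$k)
    e["angle"] <- sum(a$Kt * (th - a$t0)^2)
  }
  for (nm in c("dihedral", "improper")) {
    if (!is.null(sys[[nm]])) {
      d <- sys[[nm]]
      phi <- torsions_rad(xyz, d$i, d$j, d$k, d$l)
      e[nm] <- sum(d$pk * (1 + cos(d$n * phi - d$gamma)))
    }
  }
  if (!is.null(sys$pairs) && length(sys$pairs$i)) {
    p <- sys$pairs
    d <- xyz[p$i, , drop = FALSE] - xyz[p$j, , drop = FALSE]
    r2 <- rowdot(d, d)
    if (any(r2 < 1e-12)) stop("overlapping atoms in nonbonded pair")
    r <- sqrt(r2)
    keep <- r <= sys$cfg$cutoff
    r6 <- r2[keep]^3
    e["vdw"] <- sum(p$A[keep] / r6^2 - p$B[keep] / r6)
    e["coulomb"] <- sum(p$qq[keep] / r[keep])
  }
  e
}

eval_gradient <- function(sys, xyz) {
  G <- matrix(0, nrow(xyz), 3)
  if (!is.null(sys$bond)) {
    b <- sys$bond
    d <- xyz[b$j, , drop = FALSE] - xyz[b$i, , drop = FALSE]
    r <- sqrt(rowdot(d, d))
    dEdr <- 2 * b$Kr * (r - b$req)
    u <- d / r
    G <- acc_rows(G, b$j, u * dEdr)
    G <- acc_rows(G, b$i, -u * dEdr)
  }
  if (!is.null(sys$angle)) {
    a <- sys$angle
    rij <- xyz[a$i, , drop = FALSE] - xyz[a$j, , drop = FALSE]
    rkj <- xyz[a$k, , drop = FALSE] - xyz[a$j, , drop = FALSE]
    dij <- sqrt(rowdot(rij, rij)); dkj <- sqrt(rowdot(rkj, rkj))
    uij <- rij / dij; ukj <- rkj / dkj
    cs <- pmin(1, pmax(-1, rowdot(uij, ukj)))
    sn <- pmax(sqrt(1 - cs^2), 1e-10)
    th <- acos(cs)
    dEdth <- 2 * a$Kt * (th - a$t0)
    dth_di <- (uij * cs - ukj) / (dij * sn)
    dth_dk <- (ukj * cs - uij) / (dkj * sn)
    G <- acc_rows(G, a$i, dth_di * dEdth)
    G <- acc_rows(G, a$k, dth_dk * dEdth)
    G <- acc_rows(G, a$j, -(dth_di + dth_dk) * dEdth)
  }
  for (nm in c("dihedral", "improper")) {
    if (is.null(sys[[nm]])) next
    d <- sys[[nm]]
    b1 <- xyz[d$j, , drop = FALSE] - xyz[d$i, , drop = FALSE]
    b2 <- xyz[d$k, , drop = FALSE] - xyz[d$j, , drop = FALSE]
    b3 <- xyz[d$l, , drop = FALSE] - xyz[d$k, , drop = FALSE]
    n1 <- cross_rows(b1, b2)
    n2 <- cross_rows(b2, b3)
    nb2 <- sqrt(rowdot(b2, b2))
    m1 <- cross_rows(n1, b2 / nb2)
    phi <- atan2(rowdot(m1, n2), rowdot(n1, n2))
    dEdphi <- -d$pk * d$n * sin(d$n * phi - d$gamma)
    sq1 <- rowdot(n1, n1); sq2 <- rowdot(n2, n2)
    dphi_di <- n1 * (nb2 / sq1)
    dphi_dl <- -n2 * (nb2 / sq2)
    c12 <- rowdot(b1, b2) / nb2^2
    c32 <- rowdot(b3, b2) / nb2^2
    dphi_dj <- -dphi_di * (1 + c12) + dphi_dl * c32
    dphi_dk <- dphi_di * c12 - dphi_dl * (1 + c32)
    G <- acc_rows(G, d$i, dphi_di * dEdphi)
    G <- acc_rows(G, d$j, dphi_dj * dEdphi)
    G <- acc_rows(G, d$k, dphi_dk * dEdphi)
    G <- acc_rows(G, d$l, dphi_dl * dEdphi)
  }
  if (!is.null(sys$pairs) && length(sys$pairs$i)) {
    p <- sys$pairs
    d <- xyz[p$i, , drop = FALSE] - xyz[p$j, , drop = FALSE]
    r2 <- rowdot(d, d)
    if (any(r2 < 1e-12)) stop("overlapping atoms in nonbonded pair")
    r <- sqrt(r2)
    keep <- r <= sys$cfg$cutoff
    r2k <- r2[keep]; rk <- r[keep]
    r6 <- r2k^3
    # dE/dr for A/r^12 - B/r^6 + qq/r
    dEdr <- (-12 * p$A[keep] / (r6^2 * rk) + 6 * p$B[keep] / (r6 * rk)
             - p$qq[keep] / r2k)
    u <- d[keep, , drop = FALSE] / rk
    G <- acc_rows(G, p$i[keep], u * dEdr)
    G <- acc_rows(G, p$j[keep], -u * dEdr)
  }
  G
}

#' Evaluate the Amber potential energy
#'
#' @param mol A [molecule()] with typed atoms and charges.
#' @param top Its [enumerate_topology()] result.
#' @param ff A [forcefield()] resolving every topology tuple (an error names
#'   the first unresolvable tuple otherwise).
#' @param cfg An [energy_config()].
#' @param terms Character subset of
#'   `c("bond","angle","dihedral","improper","nonbond")`: term classes to
#'   evaluate (all by default).
#' @return An object of class `energy_breakdown`: components `bond`,
#'   `angle`, `dihedral`, `improper`, `vdw`, `coulomb` and their sum
#'   `total`, all kcal/mol.
#' @export
energy <- function(mol, top, ff, cfg = energy_config(), terms = ALL_TERMS) {
  sys <- compile_system(mol, top, ff, cfg, terms)
  e <- eval_energy(sys, mol$xyz)
  structure(as.list(c(e, total = sum(e))), class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("  %-9s %14.6f kcal/mol\n", nm, x[[nm]]))
  invisible(x)
}

#' Analytic gradient of the Amber potential
#'
#' @inheritParams energy
#' @return N x 3 matrix of dE/dx in kcal/mol/A. Matches central finite
#'   differences of [energy()] to high accuracy (see package tests).
#' @export
gradient <- function(mol, top, ff, cfg = energy_config(), terms = ALL_TERMS) {
  sys <- compile_system(mol, top, ff, cfg, terms)
  eval_gradient(sys, mol$xyz)
}

#' Numerical Cartesian Hessian
#'
#' Central finite differences of the analytic gradient (step `step`
#' Angstrom), symmetrized as (H + t(H))/2.
#'
#' @inheritParams energy
#' @param step Finite-difference step, Angstrom.
#' @return A [hessian_data()] in kcal/mol/A^2.
#' @export
numerical_hessian <- function(mol, top, ff, cfg = energy_config(),
                              terms = ALL_TERMS, step = 1e-4) {
  sys <- compile_system(mol, top, ff, cfg, terms)
  n <- n_atoms(mol)
  H <- matrix(0, 3 * n, 3 * n)
  xyz <- mol$xyz
  for (a in seq_len(n)) {
    for (d in 1:3) {
      xp <- xyz; xp[a, d] <- xp[a, d] + step
      xm <- xyz; xm[a, d] <- xm[a, d] - step
      gp <- eval_gradient(sys, xp)
      gm <- eval_gradient(sys, xm)
      H[3 * (a - 1) + d, ] <- as.vector(t(gp - gm)) / (2 * step)
    }
  }
  hessian_data((H + t(H)) / 2, units = "kcal/mol/A^2", natoms = n)
}

#' Minimize the Amber potential
#'
#' Quasi-Newton (L-BFGS-B via [stats::optim()]) minimization using the
#' analytic gradient, iterated until the RMS Cartesian gradient falls below
#' `gtol`.
#'
#' @inheritParams energy
#' @param gtol Target RMS gradient, kcal/mol/A.
#' @param max_rounds Maximum optimizer restarts before giving up.
#' @return The minimized [molecule()], with attributes `energy` (final
#'   total, kcal/mol) and `rms_gradient`.
#' @export
minimize <- function(mol, top, ff, cfg = energy_config(), gtol = 1e-4,
                     terms = ALL_TERMS, max_rounds = 40) {
  stopifnot(gtol > 0)
  sys <- compile_system(mol, top, ff, cfg, terms)
  n <- n_atoms(mol)
  fn <- function(x) sum(eval_energy(sys, matrix(x, n, 3)))
  gr <- function(x) as.vector(eval_gradient(sys, matrix(x, n, 3)))
  x <- as.vector(mol$xyz)
  best <- x
  for (round in seq_len(max_rounds)) {
    opt <- stats::optim(best, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = 2000, factr = 10))
    if (fn(opt$par) <= fn(best)) best <- opt$par
    g <- gr(best)
    if (sqrt(mean(g^2)) <= gtol) break
    if (round == max_rounds) {
      out <- mol; out$xyz <- matrix(best, n, 3)
      stop(structure(class = c("boronparam_minimization_error", "error",
                               "condition"),
                     list(message = sprintf(
                       "minimization did not reach gtol=%g (rms grad %.3g)",
                       gtol, sqrt(mean(g^2))),
                       call = sys.call(), best = out)))
    }
  }
  out <- mol
  out$xyz <- matrix(best, n, 3)
  attr(out, "energy") <- fn(best)
  attr(out, "rms_gradient") <- sqrt(mean(gr(best)^2))
  out
}

#' Zero out a dihedral's barrier terms
#'
#' Returns a force field in which every term matched for the given type
#' quadruple (exact or wildcard, per [lookup_dihedral()]) has `Vn = 0`.
#' Used to build the MM baseline of a torsion scan: the profile being fit
#' must exclude the target dihedral's own contribution.
#'
#' @param ff A [forcefield()].
#' @param types Character vector of 4 type labels.
#' @return The modified [forcefield()].
#' @export
zero_dihedral <- function(ff, types) {
  idx <- dihedral_match_rows(ff, types)
  if (!length(idx)) stop("no dihedral terms match ",
                         paste(types, collapse = "-"))
  ff$dihedrals$Vn[idx] <- 0
  ff
}
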