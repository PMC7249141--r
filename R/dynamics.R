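# Minimal vacuum molecular dynamics: leapfrog integration, SHAKE on bonds
# to hydrogen (Amber ntc=2: those bonds are constrained and their energy
# terms removed from the potential), Berendsen weak-coupling thermostat.
# Units: Angstrom, ps, amu, kcal/mol.

KB_KCAL <- 0.0019872041   # Boltzmann constant, kcal/mol/K
ACCEL_CONV <- 418.4       # (kcal/mol/A)/amu -> A/ps^2

#' Molecular-dynamics configuration
#'
#' @param dt Time step, ps (Amber-style default 0.002).
#' @param n_steps Number of steps.
#' @param temperature Target temperature, K.
#' @param tautp Berendsen coupling time constant, ps (default 0.5).
#' @param thermostat Enable the Berendsen thermostat.
#' @param shake_on_h Constrain bonds involving hydrogen (ntc = 2).
#' @param shake_tol Relative SHAKE tolerance on constrained lengths.
#' @param seed RNG seed for velocity initialization.
#' @param cutoff Nonbonded cutoff, Angstrom (default 999: none).
#' @param stride Record a trajectory frame every `stride` steps.
#' @return An object of class `md_config`.
#' @export
md_config <- function(dt = 0.002, n_steps = 1000, temperature = 300,
                      tautp = 0.5, thermostat = TRUE, shake_on_h = TRUE,
                      shake_tol = 1e-8, seed = 1, cutoff = 999, stride = 10) {
  stopifnot(dt > 0, tautp >= dt, temperature >= 0, n_steps >= 0, stride >= 1)
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 temperature = temperature, tautp = tautp,
                 thermostat = thermostat, shake_on_h = shake_on_h,
                 shake_tol = shake_tol, seed = as.integer(seed),
                 cutoff = cutoff, stride = as.integer(stride)),
            class = "md_config")
}

atom_masses <- function(mol, ff) {
  m <- numeric(n_atoms(mol))
  for (a in seq_len(n_atoms(mol))) {
    hit <- ff$masses[ff$masses$type == mol$atoms$type[a], , drop = FALSE]
    if (!nrow(hit)) stop("no mass for type ", mol$atoms$type[a])
    m[a] <- hit$mass[1]
  }
  m
}

#' Maxwell-Boltzmann velocity initialization
#'
#' Draws velocities from the Maxwell-Boltzmann distribution at `T` and
#' removes the center-of-mass momentum. `T = 0` gives all zeros.
#'
#' @param mol A [molecule()].
#' @param masses Per-atom masses, amu.
#' @param temperature Temperature, K.
#' @param seed RNG seed.
#' @return N x 3 velocity matrix, A/ps.
#' @export
init_velocities <- function(mol, masses, temperature, seed) {
  n <- n_atoms(mol)
  if (temperature <= 0) return(matrix(0, n, 3))
  set.seed(seed)
  sd <- sqrt(KB_KCAL * temperature * ACCEL_CONV / masses)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sd
  sweep(v, 2, colSums(v * masses) / sum(masses))
}

kinetic_energy <- function(v, masses) {
  sum(0.5 * masses * rowSums(v^2)) / ACCEL_CONV
}

instantaneous_temperature <- function(v, masses, ndof) {
  2 * kinetic_energy(v, masses) / (KB_KCAL * ndof)
}

#' Berendsen velocity rescaling
#'
#' Weak-coupling scale factor
#' `lambda = sqrt(1 + (dt/tautp) (T_target/T_inst - 1))`; velocities are
#' returned unscaled when the instantaneous temperature is zero.
#'
#' @param v N x 3 velocities, A/ps.
#' @param t_inst Instantaneous temperature, K.
#' @param t_target Target temperature, K.
#' @param dt Time step, ps.
#' @param tautp Coupling constant, ps.
#' @return Scaled velocities.
#' @export
berendsen_scale <- function(v, t_inst, t_target, dt, tautp) {
  if (t_inst <= 0) return(v)
  lambda <- sqrt(1 + (dt / tautp) * (t_target / t_inst - 1))
  v * lambda
}

# SHAKE: iteratively restore constrained distances; xyz_prev supplies the
# reference bond vectors for the Lagrange-multiplier direction.
shake_positions <- function(xyz, xyz_prev, cons, masses, tol, max_iter = 500) {
  if (!nrow(cons)) return(xyz)
  for (iter in seq_len(max_iter)) {
    worst <- 0
    for (r in seq_len(nrow(cons))) {
      i <- cons[r, 1]; j <- cons[r, 2]; d0 <- cons[r, 3]
      d <- xyz[i, ] - xyz[j, ]
      diff2 <- sum(d * d) - d0^2
      worst <- max(worst, abs(diff2) / d0^2)
      if (abs(diff2) / d0^2 > tol) {
        s <- xyz_prev[i, ] - xyz_prev[j, ]
        g <- diff2 / (2 * sum(s * d) * (1 / masses[i] + 1 / masses[j]))
        xyz[i, ] <- xyz[i, ] - g * s / masses[i]
        xyz[j, ] <- xyz[j, ] + g * s / masses[j]
      }
    }
    if (worst <= tol) return(xyz)
  }
  stop("SHAKE did not converge in ", max_iter, " iterations")
}

# Build the MD engine state: compiled potential (H-bond terms removed when
# shake is on), constraint table, masses, DOF count.
md_system <- function(mol, ff, cfg) {
  top <- enumerate_topology(mol)
  ecfg <- energy_config(cutoff = cfg$cutoff)
  sys <- compile_system(mol, top, ff, ecfg)
  masses <- atom_masses(mol, ff)
  cons <- matrix(numeric(0), ncol = 3)
  if (cfg$shake_on_h && !is.null(sys$bond)) {
    ish <- mol$atoms$element[sys$bond$i] == "H" |
      mol$atoms$element[sys$bond$j] == "H"
    if (any(ish)) {
      cons <- cbind(sys$bond$i[ish], sys$bond$j[ish], sys$bond$req[ish])
      sys$bond <- lapply(sys$bond, function(x) x[!ish])
      if (!length(sys$bond$i)) sys$bond <- NULL
    }
  }
  ndof <- 3 * n_atoms(mol) - 3 - nrow(cons)
  list(sys = sys, masses = masses, cons = cons, ndof = ndof)
}

#' One leapfrog step
#'
#' Advances positions and half-step velocities by `dt` using the analytic
#' gradient; when constraints are present, SHAKE restores constrained
#' lengths and velocities are recomputed from the actual displacement.
#'
#' @param state List with `xyz` (N x 3) and `vel` (N x 3, velocities at
#'   t - dt/2).
#' @param engine An internal engine from `md_system()` (see [run_md()] for
#'   the high-level interface).
#' @param dt Time step, ps.
#' @param shake_tol SHAKE tolerance.
#' @return Updated state (plus `potential`, kcal/mol).
#' @keywords internal
step_leapfrog <- function(state, engine, dt, shake_tol = 1e-8) {
  g <- eval_gradient(engine$sys, state$xyz)
  acc <- -g / engine$masses * ACCEL_CONV
  vel <- state$vel + acc * dt
  xyz_new <- state$xyz + vel * dt
  if (nrow(engine$cons)) {
    xyz_new <- shake_positions(xyz_new, state$xyz, engine$cons,
                               engine$masses, shake_tol)
    vel <- (xyz_new - state$xyz) / dt
  }
  # on-step energy bookkeeping at the pre-advance time t: PE(x(t)) and KE
  # from the average of the two half-step velocities (~= v(t)), so that
  # their sum is a conserved-quantity estimate in NVE runs
  list(xyz = xyz_new, vel = vel,
       potential = sum(eval_energy(engine$sys, state$xyz)),
       ke_onstep = kinetic_energy((state$vel + vel) / 2, engine$masses))
}

#' Run thermostatted (or NVE) vacuum dynamics
#'
#' Leapfrog integration at fixed target temperature. Velocities are
#' initialized from Maxwell-Boltzmann unless supplied.
#'
#' @param mol A [molecule()] (typed, charged, with coordinates).
#' @param ff A [forcefield()] with masses for every type.
#' @param cfg An [md_config()].
#' @param vel Optional initial velocities (N x 3, A/ps).
#' @return An object of class `md_trajectory`: list with `frames` (each a
#'   list `time`, `xyz`, `kinetic`, `potential`, `temperature`), `times`,
#'   `temperatures` (every step), and the final `state`.
#' @export
run_md <- function(mol, ff, cfg = md_config(), vel = NULL) {
  engine <- md_system(mol, ff, cfg)
  if (is.null(vel))
    vel <- init_velocities(mol, engine$masses, cfg$temperature, cfg$seed)
  state <- list(xyz = mol$xyz, vel = vel)
  frames <- list()
  temps <- numeric(cfg$n_steps)
  for (s in seq_len(cfg$n_steps)) {
    state <- step_leapfrog(state, engine, cfg$dt, cfg$shake_tol)
    t_inst <- instantaneous_temperature(state$vel, engine$masses,
                                        engine$ndof)
    temps[s] <- t_inst
    if (cfg$thermostat)
      state$vel <- berendsen_scale(state$vel, t_inst, cfg$temperature,
                                   cfg$dt, cfg$tautp)
    if (s %% cfg$stride == 0) {
      frames[[length(frames) + 1L]] <- list(
        time = s * cfg$dt, xyz = state$xyz,
        kinetic = state$ke_onstep,
        potential = state$potential,
        temperature = 2 * state$ke_onstep / (KB_KCAL * engine$ndof))
    }
  }
  structure(list(frames = frames,
                 times = vapply(frames, `[[`, 0, "time"),
                 temperatures = temps, state = state, config = cfg,
                 molecule = mol),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames, %d steps of %.4g ps; mean T %.1f K\n",
              length(x$frames), length(x$temperatures), x$config$dt,
              mean(x$temperatures)))
  invisible(x)
}

#' Staged heating run
#'
#' Runs consecutive thermostatted segments with stepwise target
#' temperatures — the default ramps in 100 K increments up to 325 K.
#' Velocities carry over between stages; the first stage draws them from
#' Maxwell-Boltzmann at its own target.
#'
#' @param mol,ff,cfg As in [run_md()]; `cfg$temperature` and `cfg$n_steps`
#'   are overridden per stage.
#' @param schedule Two-column data.frame / matrix of (target temperature K,
#'   duration ps).
#' @return An `md_trajectory` concatenating all stages (empty schedule
#'   gives an empty trajectory).
#' @export
heat <- function(mol, ff, cfg = md_config(),
                 schedule = data.frame(temperature = c(100, 200, 300, 325),
                                       duration = 1)) {
  schedule <- as.data.frame(schedule)
  frames <- list(); temps <- numeric(0)
  state <- NULL
  cur <- mol
  offset <- 0
  if (nrow(schedule)) {
    for (st in seq_len(nrow(schedule))) {
      scfg <- cfg
      scfg$temperature <- schedule[[1]][st]
      scfg$n_steps <- max(1L, as.integer(round(schedule[[2]][st] / cfg$dt)))
      scfg$thermostat <- TRUE
      traj <- run_md(cur, ff, scfg,
                     vel = if (is.null(state)) NULL else state$vel)
      for (f in traj$frames) {
        f$time <- f$time + offset
        frames[[length(frames) + 1L]] <- f
      }
      temps <- c(temps, traj$temperatures)
      state <- traj$state
      cur$xyz <- state$xyz
      offset <- offset + scfg$n_steps * cfg$dt
    }
  }
  structure(list(frames = frames,
                 times = vapply(frames, `[[`, 0, "time"),
                 temperatures = temps, state = state, config = cfg,
                 molecule = mol, schedule = schedule),
            class = "md_trajectory")
}

#' Per-frame RMSD against a reference
#'
#' Applies the [rmsd_ad()] superposed-displacement metric to every frame.
#'
#' @param traj An `md_trajectory`.
#' @param ref Reference [molecule()] (defaults to the trajectory's starting
#'   molecule).
#' @param selection As in [rmsd_ad()].
#' @return data.frame with columns `time` (ps) and `rmsd` (Angstrom).
#' @export
trajectory_rmsd <- function(traj, ref = traj$molecule,
                            selection = "boron-core") {
  mol <- traj$molecule
  out <- data.frame(time = numeric(0), rmsd = numeric(0))
  for (f in traj$frames) {
    test <- mol; test$xyz <- f$xyz
    out[nrow(out) + 1L, ] <- list(f$time, rmsd_ad(ref, test, selection))
  }
  out
}

#' Write a trajectory as multi-frame XYZ
#'
#' @param traj An `md_trajectory`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_xyz_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  el <- traj$molecule$atoms$element
  for (f in traj$frames) {
    writeLines(c(sprintf("%d", length(el)),
                 sprintf("t = %.4f ps", f$time)), con)
    for (a in seq_along(el))
      writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", el[a],
                         f$xyz[a, 1], f$xyz[a, 2], f$xyz[a, 3]), con)
  }
  invisible(path)
}
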