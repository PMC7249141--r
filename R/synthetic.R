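# Synthetic test-input generator. The main fixture is diethoxyborinic acid
# HO-B(OC2H5)2 (19 atoms), typed with the boron conventions (sp2 boron "B",
# boron-bound oxygens "ob") and parameterized with the published bond/angle/
# dihedral/improper constants for the boron terms plus GAFF-style filler
# values for the plain organic terms. Partial charges are synthetic
# placeholders summing to zero. Everything is built deterministically in
# code; nothing is read from disk.

fixture_forcefield <- function() {
  ff <- forcefield()
  # boron terms (published values)
  ff <- ff_add_bond(ff, "h1", "ob", 546.139, 0.970)
  ff <- ff_add_bond(ff, "ob", "B", 350.221, 1.372)
  ff <- ff_add_bond(ff, "ob", "c3", 219.866, 1.435)
  ff <- ff_add_angle(ff, "h1", "ob", "B", 50.184, 110.55)
  ff <- ff_add_angle(ff, "ob", "B", "ob", 104.357, 120.00)
  ff <- ff_add_angle(ff, "B", "ob", "c3", 110.735, 121.35)
  ff <- ff_add_angle(ff, "ob", "c3", "c3", 114.01, 111.44)
  ff <- ff_add_angle(ff, "ob", "c3", "h1", 77.700, 107.94)
  ff <- ff_add_dihedral(ff, c("h1", "ob", "B", "ob"), 1, 2.350, 0, 1)
  ff <- ff_add_dihedral(ff, c("h1", "ob", "B", "ob"), 1, 1.654, 0, 2)
  ff <- ff_add_dihedral(ff, c("ob", "B", "ob", "c3"), 1, 1.980, 180, 1)
  ff <- ff_add_dihedral(ff, c("ob", "B", "ob", "c3"), 1, 1.472, 180, 2)
  ff <- ff_add_dihedral(ff, c("B", "ob", "c3", "c3"), 2, 5.400, 180, 2)
  ff <- ff_add_dihedral(ff, c("B", "ob", "c3", "h1"), 1, 5.400, 180, 2)
  ff <- ff_add_dihedral(ff, c("ob", "c3", "c3", "h1"), 1, 0.300, 180, 2)
  ff <- ff_add_improper(ff, c("ob", "ob", "B", "ob"), 40.5, 180.0, 2)
  ff <- ff_add_nonbond(ff, "B", 1.98, 0.034)
  ff <- ff_add_nonbond(ff, "ob", 1.6612, 0.2100)
  # GAFF-style fillers (synthetic provenance)
  ff <- ff_add_bond(ff, "c3", "c3", 303.1, 1.535)
  ff <- ff_add_bond(ff, "c3", "h1", 335.9, 1.093)
  ff <- ff_add_angle(ff, "c3", "c3", "h1", 46.4, 110.05)
  ff <- ff_add_angle(ff, "h1", "c3", "h1", 39.2, 108.46)
  ff <- ff_add_dihedral(ff, c("h1", "c3", "c3", "h1"), 1, 0.15, 0, 3)
  ff <- ff_add_nonbond(ff, "c3", 1.9080, 0.1094)
  ff <- ff_add_nonbond(ff, "h1", 1.3870, 0.0157)
  ff <- ff_add_mass(ff, "B", 10.81)
  ff <- ff_add_mass(ff, "ob", 16.00)
  ff <- ff_add_mass(ff, "c3", 12.01)
  ff <- ff_add_mass(ff, "h1", 1.008)
  ff
}

FIXTURE_PAPER_TERMS <- list(
  bonds = c("h1-ob", "B-ob", "c3-ob"),
  angles = c("B-ob-h1", "ob-B-ob", "B-ob-c3", "c3-c3-ob", "h1-c3-ob"),
  dihedrals = c("h1-ob-B-ob", "c3-ob-B-ob", "B-ob-c3-c3", "B-ob-c3-h1",
                "h1-c3-c3-ob"),
  impropers = "ob-ob-B-ob",
  nonbond = c("B", "ob")
)

# ideal-internal-coordinate build of HO-B(OC2H5)2
diethoxyborinic_geometry <- function() {
  xyz <- matrix(NA_real_, 19, 3)
  xyz[1, ] <- c(0, 0, 0)                       # B
  xyz[2, ] <- c(1.372, 0, 0)                   # O (hydroxyl)
  # O3, O4 at 120 deg in the xy plane
  xyz[3, ] <- 1.372 * c(cos(deg2rad(120)), sin(deg2rad(120)), 0)
  xyz[4, ] <- 1.372 * c(cos(deg2rad(-120)), sin(deg2rad(-120)), 0)
  xyz[5, ] <- place_atom(xyz[2, ], xyz[1, ], xyz[3, ], 0.970, 110.55, 0)
  # ethoxy arms as a propeller (+/-90 deg B-O-C torsions) to keep them apart
  xyz[6, ] <- place_atom(xyz[3, ], xyz[1, ], xyz[2, ], 1.435, 121.35, 90)
  xyz[7, ] <- place_atom(xyz[6, ], xyz[3, ], xyz[1, ], 1.535, 111.44, 180)
  xyz[8, ] <- place_atom(xyz[4, ], xyz[1, ], xyz[2, ], 1.435, 121.35, -90)
  xyz[9, ] <- place_atom(xyz[8, ], xyz[4, ], xyz[1, ], 1.535, 111.44, 180)
  xyz[10, ] <- place_atom(xyz[6, ], xyz[3, ], xyz[7, ], 1.093, 107.94, 121)
  xyz[11, ] <- place_atom(xyz[6, ], xyz[3, ], xyz[7, ], 1.093, 107.94, -121)
  xyz[12, ] <- place_atom(xyz[7, ], xyz[6, ], xyz[3, ], 1.093, 110.05, 180)
  xyz[13, ] <- place_atom(xyz[7, ], xyz[6, ], xyz[3, ], 1.093, 110.05, 60)
  xyz[14, ] <- place_atom(xyz[7, ], xyz[6, ], xyz[3, ], 1.093, 110.05, -60)
  xyz[15, ] <- place_atom(xyz[8, ], xyz[4, ], xyz[9, ], 1.093, 107.94, 121)
  xyz[16, ] <- place_atom(xyz[8, ], xyz[4, ], xyz[9, ], 1.093, 107.94, -121)
  xyz[17, ] <- place_atom(xyz[9, ], xyz[8, ], xyz[4, ], 1.093, 110.05, 180)
  xyz[18, ] <- place_atom(xyz[9, ], xyz[8, ], xyz[4, ], 1.093, 110.05, 60)
  xyz[19, ] <- place_atom(xyz[9, ], xyz[8, ], xyz[4, ], 1.093, 110.05, -60)
  xyz
}

diethoxyborinic_molecule <- function() {
  element <- c("B", "O", "O", "O", "H", "C", "C", "C", "C",
               rep("H", 10))
  type <- c("B", "ob", "ob", "ob", "h1", "c3", "c3", "c3", "c3",
            rep("h1", 10))
  charge <- c(0.80, -0.65, -0.55, -0.55, 0.40, 0.20, -0.175, 0.20, -0.175,
              rep(0.05, 10))
  bonds <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 5), c(3, 6), c(6, 7),
                 c(4, 8), c(8, 9), c(6, 10), c(6, 11), c(7, 12), c(7, 13),
                 c(7, 14), c(8, 15), c(8, 16), c(9, 17), c(9, 18), c(9, 19))
  molecule("diethoxyborinic_acid", element, type, charge,
           diethoxyborinic_geometry(), bonds)
}

#' Build a synthetic test fixture
#'
#' Deterministic constructors for the structures and parameters the test
#' suite and examples run on:
#' * `"diethoxyborinic_acid"` — HO-B(OC2H5)2 with the boron bond, angle,
#'   dihedral, improper and nonbonded parameters of the parameterization
#'   study embedded verbatim, GAFF-style fillers for the plain organic
#'   terms, and placeholder charges summing to zero;
#' * `"toy_bond"` — an isolated ob-B harmonic bond (2 atoms);
#' * `"toy_angle"` — an isolated ob-B-ob bend with stiff arms (3 atoms);
#' * `"toy_dihedral"` — a 4-atom h1-ob-B-ob chain carrying the fitted
#'   two-term torsion.
#'
#' @param name One of the fixture names above.
#' @return A `fixture_bundle`: list with `molecule`, `topology`,
#'   `forcefield`, and `provenance` (which term keys are published values
#'   vs synthetic fillers).
#' @export
build_fixture <- function(name = c("diethoxyborinic_acid", "toy_bond",
                                   "toy_angle", "toy_dihedral")) {
  name <- match.arg(name)
  full <- fixture_forcefield()
  if (name == "diethoxyborinic_acid") {
    mol <- diethoxyborinic_molecule()
    ff <- full
  } else if (name == "toy_bond") {
    mol <- molecule("toy_bond", c("O", "B"), c("ob", "B"), c(0, 0),
                    rbind(c(0, 0, 0), c(1.372, 0, 0)), rbind(c(1, 2)))
    ff <- forcefield()
    ff <- ff_add_bond(ff, "ob", "B", 350.221, 1.372)
    ff <- ff_add_nonbond(ff, "B", 1.98, 0.034)
    ff <- ff_add_nonbond(ff, "ob", 1.6612, 0.2100)
    ff <- ff_add_mass(ff, "B", 10.81)
    ff <- ff_add_mass(ff, "ob", 16.00)
  } else if (name == "toy_angle") {
    th <- deg2rad(120)
    xyz <- rbind(c(1.372, 0, 0), c(0, 0, 0),
                 1.372 * c(cos(th), sin(th), 0))
    mol <- molecule("toy_angle", c("O", "B", "O"), c("ob", "B", "ob"),
                    c(0, 0, 0), xyz, rbind(c(1, 2), c(2, 3)))
    ff <- forcefield()
    ff <- ff_add_bond(ff, "ob", "B", 350.221, 1.372)
    ff <- ff_add_angle(ff, "ob", "B", "ob", 104.357, 120.00)
    ff <- ff_add_nonbond(ff, "B", 1.98, 0.034)
    ff <- ff_add_nonbond(ff, "ob", 1.6612, 0.2100)
    ff <- ff_add_mass(ff, "B", 10.81)
    ff <- ff_add_mass(ff, "ob", 16.00)
  } else {
    # h1-ob-B-ob chain at phi = 0
    xyz <- matrix(NA_real_, 4, 3)
    xyz[2, ] <- c(0, 0, 0)                 # ob
    xyz[3, ] <- c(1.372, 0, 0)             # B
    xyz[4, ] <- place_atom(xyz[3, ], xyz[2, ], c(0, 1, 0), 1.372, 120, 90)
    xyz[1, ] <- place_atom(xyz[2, ], xyz[3, ], xyz[4, ], 0.970, 110.55, 0)
    mol <- molecule("toy_dihedral", c("H", "O", "B", "O"),
                    c("h1", "ob", "B", "ob"), c(0, 0, 0, 0), xyz,
                    rbind(c(1, 2), c(2, 3), c(3, 4)))
    ff <- forcefield()
    ff <- ff_add_bond(ff, "h1", "ob", 546.139, 0.970)
    ff <- ff_add_bond(ff, "ob", "B", 350.221, 1.372)
    ff <- ff_add_angle(ff, "h1", "ob", "B", 50.184, 110.55)
    ff <- ff_add_angle(ff, "ob", "B", "ob", 104.357, 120.00)
    ff <- ff_add_dihedral(ff, c("h1", "ob", "B", "ob"), 1, 2.350, 0, 1)
    ff <- ff_add_dihedral(ff, c("h1", "ob", "B", "ob"), 1, 1.654, 0, 2)
    ff <- ff_add_nonbond(ff, "B", 1.98, 0.034)
    ff <- ff_add_nonbond(ff, "ob", 1.6612, 0.2100)
    ff <- ff_add_nonbond(ff, "h1", 1.3870, 0.0157)
    ff <- ff_add_mass(ff, "B", 10.81)
    ff <- ff_add_mass(ff, "ob", 16.00)
    ff <- ff_add_mass(ff, "h1", 1.008)
  }
  structure(list(molecule = mol, topology = enumerate_topology(mol),
                 forcefield = ff, name = name,
                 provenance = FIXTURE_PAPER_TERMS),
            class = "fixture_bundle")
}

#' MM Hessian of a fixture at its own minimum
#'
#' Minimizes the fixture with only the selected term classes active, then
#' evaluates the numerical Cartesian Hessian of that restricted potential.
#' The default (bonds + angles) gives a purely harmonic surface whose
#' generating constants are the ground truth for Seminario-recovery tests.
#'
#' @param bundle A [build_fixture()] result.
#' @param terms Term classes to keep active.
#' @param gtol Minimization target RMS gradient.
#' @return List with `molecule` (minimized) and `hessian`
#'   (a [hessian_data()]).
#' @export
mm_hessian_fixture <- function(bundle, terms = c("bond", "angle"),
                               gtol = 1e-6) {
  top <- bundle$topology
  minmol <- minimize(bundle$molecule, top, bundle$forcefield,
                     gtol = gtol, terms = terms)
  h <- numerical_hessian(minmol, top, bundle$forcefield, terms = terms)
  list(molecule = minmol, hessian = h)
}

# indices of the atoms to rotate when turning dihedral i-j-k-l: the
# connected component containing l after deleting bond j-k
rotating_side <- function(mol, j, k) {
  nb <- neighbor_list(mol)
  seen <- rep(FALSE, n_atoms(mol))
  seen[j] <- TRUE
  frontier <- k
  seen[k] <- TRUE
  while (length(frontier)) {
    nxt <- unique(unlist(nb[frontier]))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  setdiff(which(seen), c(j, k))
}

#' Rigid rotation about a bond to a target torsion
#'
#' Rotates everything on the `l` side of the central `j-k` bond so that
#' the torsion `i-j-k-l` equals `phi_target` degrees; all internal
#' coordinates other than the torsions across `j-k` are untouched.
#'
#' @param mol A [molecule()] (the graph must split at `j-k`, i.e. the bond
#'   is not in a ring).
#' @param quad Atom indices `c(i, j, k, l)`.
#' @param phi_target Target torsion, degrees.
#' @return The rotated [molecule()].
#' @export
set_dihedral <- function(mol, quad, phi_target) {
  i <- quad[1]; j <- quad[2]; k <- quad[3]; l <- quad[4]
  cur <- atom_dihedral(mol$xyz, i, j, k, l)
  delta <- deg2rad(phi_target - cur)
  axis <- mol$xyz[k, ] - mol$xyz[j, ]
  R <- rotation_about_axis(axis, -delta)
  side <- rotating_side(mol, j, k)
  if (i %in% side) stop("bond ", j, "-", k, " appears to be in a ring")
  pivot <- mol$xyz[k, ]
  mol$xyz[side, ] <- sweep(mol$xyz[side, , drop = FALSE], 2, pivot) %*%
    t(R) + matrix(pivot, length(side), 3, byrow = TRUE)
  mol
}

#' Synthesize a torsion scan with known Fourier truth
#'
#' Generates rigid-rotation conformers of the fixture over a -180..180
#' degree grid (5 degree steps by default, 73 points), computes the zeroed
#' MM baseline with [build_scan()], and sets the pseudo-QM energies to
#' `e_mm_zeroed + fourier_energy(truth, phi) + offset + N(0, noise_sd^2)`.
#' A noiseless scan is therefore exactly representable by the truth model,
#' and fitting it back is a closed-loop recovery experiment.
#'
#' @param bundle A [build_fixture()] result whose topology contains the
#'   target quadruple.
#' @param types Target dihedral type quadruple.
#' @param truth A [fourier_model()] acting as ground truth.
#' @param noise_sd Gaussian noise s.d., kcal/mol.
#' @param seed RNG seed.
#' @param offset Constant added to the pseudo-QM energies (arbitrary QM
#'   zero; the fit must be invariant to it).
#' @param step Grid step, degrees.
#' @return A [dihedral_scan()]; attribute `conformers` carries the
#'   generated geometries.
#' @export
synth_scan <- function(bundle, types, truth, noise_sd = 0, seed = 1,
                       offset = -1234.5, step = 5) {
  mol <- bundle$molecule
  top <- bundle$topology
  ty <- mol$atoms$type
  quad <- NULL
  for (r in seq_len(nrow(top$dihedrals))) {
    if (identical(canon_quad(ty[top$dihedrals[r, ]]), canon_quad(types))) {
      quad <- top$dihedrals[r, ]
      break
    }
  }
  if (is.null(quad)) stop("fixture topology has no dihedral of types ",
                          paste(types, collapse = "-"))
  # orient the instance to match the type order requested
  if (!identical(ty[quad], as.character(types))) quad <- rev(quad)
  phi <- seq(-180, 180, by = step)
  conformers <- lapply(phi, function(p) set_dihedral(mol, quad, p))
  scan <- build_scan(conformers, phi, bundle$forcefield,
                     types = types)
  set.seed(seed)
  noise <- if (noise_sd > 0) stats::rnorm(length(phi), 0, noise_sd) else 0
  scan$e_qm <- scan$e_mm_zeroed + fourier_energy(truth, phi) + offset + noise
  attr(scan, "conformers") <- conformers
  scan
}

#' Gaussian perturbation of a structure
#'
#' Adds i.i.d. Gaussian displacements to every coordinate — a stand-in for
#' an experimental reference structure in validation tests (synthetic; no
#' crystallographic data involved).
#'
#' @param mol A [molecule()].
#' @param sigma Displacement s.d. per coordinate, Angstrom.
#' @param seed RNG seed.
#' @return The perturbed [molecule()].
#' @export
perturb_structure <- function(mol, sigma, seed) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(mol)
  set.seed(seed)
  mol$xyz <- mol$xyz + matrix(stats::rnorm(3 * n_atoms(mol), 0, sigma),
                              n_atoms(mol), 3)
  mol
}
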