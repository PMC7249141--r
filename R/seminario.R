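# Seminario-method extraction of harmonic bond/angle constants from a
# Cartesian Hessian. The method eigendecomposes the negated 3x3 interatomic
# Hessian block and projects its eigenvalues onto the bond direction (bonds)
# or onto in-plane perpendiculars (angles); the result is invariant to
# rigid rotation of the input and to the choice of internal coordinates.

HARTREE_KCAL <- 627.509474      # kcal/mol per hartree
BOHR_ANGSTROM <- 0.529177210903 # Angstrom per bohr

#' Cartesian Hessian container
#'
#' @param matrix 3N x 3N matrix of second derivatives, atom-major
#'   (rows/columns 3(a-1)+1..3a belong to atom a).
#' @param units `"hartree/bohr^2"` or `"kcal/mol/A^2"`.
#' @param natoms Atom count N.
#' @return An object of class `hessian_data`.
#' @export
hessian_data <- function(matrix, units = c("kcal/mol/A^2", "hartree/bohr^2"),
                         natoms = nrow(matrix) / 3) {
  units <- match.arg(units)
  if (nrow(matrix) != ncol(matrix)) stop("Hessian must be square")
  if (nrow(matrix) %% 3 != 0) stop("Hessian dimension must be divisible by 3")
  if (nrow(matrix) != 3 * natoms) stop("Hessian dimension does not match natoms")
  structure(list(matrix = (matrix + t(matrix)) / 2, units = units,
                 natoms = as.integer(natoms)), class = "hessian_data")
}

#' @export
print.hessian_data <- function(x, ...) {
  cat(sprintf("hessian_data: %d atoms (%dx%d), units %s\n", x$natoms,
              3 * x$natoms, 3 * x$natoms, x$units))
  invisible(x)
}

#' Convert a Hessian to kcal/mol/A^2
#'
#' A Hessian already in the target units is returned unchanged, so the
#' conversion is idempotent. 1 hartree/bohr^2 = 627.509474 / 0.529177210903^2
#' = 2240.877 kcal/mol/A^2.
#'
#' @param h A [hessian_data()].
#' @return A [hessian_data()] in kcal/mol/A^2.
#' @export
convert_units <- function(h) {
  stopifnot(inherits(h, "hessian_data"))
  if (h$units == "kcal/mol/A^2") return(h)
  f <- HARTREE_KCAL / BOHR_ANGSTROM^2
  hessian_data(h$matrix * f, units = "kcal/mol/A^2", natoms = h$natoms)
}

hessian_block <- function(h, i, j) {
  ri <- 3 * (i - 1) + 1:3
  rj <- 3 * (j - 1) + 1:3
  h$matrix[ri, rj, drop = FALSE]
}

# sum_m lambda_m |u . v_m| for the eigensystem of -block
projected_stiffness <- function(block, u) {
  es <- eigen(-(block + t(block)) / 2, symmetric = TRUE)
  sum(es$values * abs(as.vector(u %*% es$vectors)))
}

#' Seminario bond constant
#'
#' Projects the eigenvalues of the negated interatomic Hessian block onto
#' the unit bond vector, giving the curvature k of the bond stretch; the
#' Amber constant is `Kr = k/2` since `Kr (r - req)^2` has curvature `2 Kr`.
#' `req` is the geometric distance.
#'
#' @param h A [hessian_data()] in kcal/mol/A^2 (convert first with
#'   [convert_units()]).
#' @param xyz N x 3 coordinates (Angstrom) the Hessian was evaluated at.
#' @param i,j Atom indices of the bond.
#' @return Named vector `c(Kr=, req=)` (kcal/mol/A^2, A).
#' @export
seminario_bond <- function(h, xyz, i, j) {
  stopifnot(inherits(h, "hessian_data"), i != j)
  if (h$units != "kcal/mol/A^2") stop("Hessian must be in kcal/mol/A^2; use convert_units()")
  d <- xyz[j, ] - xyz[i, ]
  r <- vnorm(d)
  if (r < 1e-6) stop("near-zero bond length between atoms ", i, " and ", j)
  u <- d / r
  k <- projected_stiffness(hessian_block(h, i, j), u)
  c(Kr = k / 2, req = r)
}

#' Seminario angle constant
#'
#' For angle i-j-k (j central) the two arm stiffnesses are obtained by
#' projecting the (i,j) and (k,j) eigen systems onto the in-plane unit
#' vectors perpendicular to each arm, and combined in series:
#' `1/k_theta = 1/(R_ji^2 S_ij) + 1/(R_jk^2 S_kj)`. Returned
#' `Ktheta = k_theta/2` (Amber curvature convention) in kcal/mol/rad^2;
#' `theta_eq` is the geometric angle in degrees.
#'
#' @inheritParams seminario_bond
#' @param k Third atom index (outer).
#' @return Named vector `c(Ktheta=, theta_eq=)`.
#' @export
seminario_angle <- function(h, xyz, i, j, k) {
  stopifnot(inherits(h, "hessian_data"))
  if (h$units != "kcal/mol/A^2") stop("Hessian must be in kcal/mol/A^2; use convert_units()")
  rji <- xyz[i, ] - xyz[j, ]
  rjk <- xyz[k, ] - xyz[j, ]
  uji <- unitv(rji); ujk <- unitv(rjk)
  cr <- cross3(uji, ujk)
  if (vnorm(cr) < 1e-6) stop("collinear arms for angle ", i, "-", j, "-", k)
  un <- cr / vnorm(cr)
  u_pa <- cross3(un, uji)
  u_pc <- cross3(ujk, un)
  s_ij <- projected_stiffness(hessian_block(h, i, j), u_pa)
  s_kj <- projected_stiffness(hessian_block(h, k, j), u_pc)
  kth <- 1 / (1 / (vnorm(rji)^2 * s_ij) + 1 / (vnorm(rjk)^2 * s_kj))
  c(Ktheta = kth / 2, theta_eq = atom_angle(xyz, i, j, k))
}

#' Extract all bond and angle parameters from a Hessian
#'
#' Runs [seminario_bond()] / [seminario_angle()] over every topology bond
#' and angle, then averages instances sharing a (canonically ordered) type
#' tuple. Hessians in hartree/bohr^2 are converted automatically.
#'
#' @param mol Typed [molecule()] (atom count must match the Hessian).
#' @param top Its [enumerate_topology()].
#' @param h A [hessian_data()].
#' @return An object of class `seminario_result`: data.frames `bonds`
#'   (`t1,t2,Kr,req,n_instances`) and `angles`
#'   (`t1,t2,t3,Ktheta,theta_eq,n_instances`), plus the per-instance tables
#'   `bond_instances`, `angle_instances`.
#' @export
extract_all <- function(mol, top, h) {
  if (h$natoms != n_atoms(mol))
    stop("Hessian atom count (", h$natoms, ") does not match molecule (",
         n_atoms(mol), ")")
  h <- convert_units(h)
  ty <- mol$atoms$type
  xyz <- mol$xyz

  bi <- data.frame(t1 = character(0), t2 = character(0), Kr = numeric(0),
                   req = numeric(0), stringsAsFactors = FALSE)
  for (r in seq_len(nrow(top$bonds))) {
    ij <- top$bonds[r, ]
    v <- seminario_bond(h, xyz, ij[1], ij[2])
    key <- canon_pair(ty[ij])
    bi[nrow(bi) + 1L, ] <- list(key[1], key[2], v[["Kr"]], v[["req"]])
  }
  ai <- data.frame(t1 = character(0), t2 = character(0), t3 = character(0),
                   Ktheta = numeric(0), theta_eq = numeric(0),
                   stringsAsFactors = FALSE)
  for (r in seq_len(nrow(top$angles))) {
    ijk <- top$angles[r, ]
    v <- seminario_angle(h, xyz, ijk[1], ijk[2], ijk[3])
    key <- canon_triple(ty[ijk])
    ai[nrow(ai) + 1L, ] <- list(key[1], key[2], key[3],
                                v[["Ktheta"]], v[["theta_eq"]])
  }
  agg <- function(df, keys, vals) {
    if (!nrow(df)) {
      out <- df
      out$n_instances <- integer(0)
      return(out)
    }
    kf <- apply(df[keys], 1, paste, collapse = "-")
    out <- do.call(rbind, lapply(unique(kf), function(kk) {
      sub <- df[kf == kk, , drop = FALSE]
      row <- sub[1, keys, drop = FALSE]
      for (v in vals) row[[v]] <- mean(sub[[v]])
      row$n_instances <- nrow(sub)
      row
    }))
    rownames(out) <- NULL
    out
  }
  structure(list(
    bonds = agg(bi, c("t1", "t2"), c("Kr", "req")),
    angles = agg(ai, c("t1", "t2", "t3"), c("Ktheta", "theta_eq")),
    bond_instances = bi,
    angle_instances = ai
  ), class = "seminario_result")
}

#' @export
print.seminario_result <- function(x, ...) {
  cat("seminario_result\nbonds:\n"); print(x$bonds)
  cat("angles:\n"); print(x$angles)
  invisible(x)
}

#' Merge Seminario results into a force field
#'
#' @param res A [extract_all()] result.
#' @param ff A [forcefield()] to extend (empty by default).
#' @return The [forcefield()] with the extracted bond/angle terms added.
#' @export
seminario_to_forcefield <- function(res, ff = forcefield()) {
  for (r in seq_len(nrow(res$bonds)))
    ff <- ff_add_bond(ff, res$bonds$t1[r], res$bonds$t2[r],
                      res$bonds$Kr[r], res$bonds$req[r])
  for (r in seq_len(nrow(res$angles)))
    ff <- ff_add_angle(ff, res$angles$t1[r], res$angles$t2[r],
                       res$angles$t3[r], res$angles$Ktheta[r],
                       res$angles$theta_eq[r])
  ff
}

#' Read / write the plain-text Hessian format
#'
#' A one-line header `hessian <units> <natoms>` followed by whitespace-
#' separated numbers: either the full 3N x 3N matrix (row-major) or its
#' packed lower triangle (row-wise), which is mirrored on read.
#'
#' @param path File path.
#' @return [read_hessian()]: a [hessian_data()].
#' @export
read_hessian <- function(path) {
  if (!file.exists(path)) stop("hessian file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 3 || hdr[1] != "hessian")
    stop("bad hessian header (expected 'hessian <units> <natoms>'): ", lines[1])
  units <- hdr[2]
  if (!units %in% c("kcal/mol/A^2", "hartree/bohr^2"))
    stop("unknown hessian unit tag: ", units)
  n <- as.integer(hdr[3])
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[-1][nzchar(trimws(lines[-1]))]), "\\s+"))))
  if (any(is.na(vals))) stop("non-numeric entries in hessian body")
  dim3 <- 3L * n
  if (length(vals) == dim3^2) {
    m <- matrix(vals, dim3, dim3, byrow = TRUE)
  } else if (length(vals) == dim3 * (dim3 + 1) / 2) {
    m <- matrix(0, dim3, dim3)
    m[upper.tri(m, diag = TRUE)] <- vals  # filled column-wise = row-wise lower
    m <- t(m)
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
  } else {
    stop("hessian body has ", length(vals), " numbers; expected ",
         dim3^2, " (full) or ", dim3 * (dim3 + 1) / 2, " (lower triangle)")
  }
  hessian_data(m, units = units, natoms = n)
}

#' @rdname read_hessian
#' @param h A [hessian_data()].
#' @return [write_hessian()]: invisibly, `path`.
#' @export
write_hessian <- function(h, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("hessian %s %d", h$units, h$natoms), con)
  for (r in seq_len(nrow(h$matrix)))
    writeLines(paste(sprintf("%.10e", h$matrix[r, ]), collapse = " "), con)
  invisible(path)
}
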