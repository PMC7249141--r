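#' Construct a molecule object
#'
#' A molecule bundles per-atom data (element, force-field type label,
#' partial charge, Cartesian coordinates in Angstrom) with an undirected
#' bond list. Atom indices are 1-based everywhere in the package, matching
#' both R convention and the Tripos mol2 serialization.
#'
#' @param name Molecule name.
#' @param element Character vector of element symbols.
#' @param type Character vector of force-field type labels (e.g. "B", "ob",
#'   "c3", "h1"). Carried verbatim; no perception is attempted.
#' @param charge Numeric vector of partial charges (atomic units).
#' @param xyz N x 3 numeric matrix of coordinates (Angstrom).
#' @param bonds Two-column integer matrix of bonded atom pairs (any order;
#'   stored with the smaller index first, duplicates removed).
#' @return An object of class `molecule`.
#' @export
molecule <- function(name, element, type, charge, xyz, bonds) {
  n <- length(element)
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  stopifnot(length(type) == n, length(charge) == n, nrow(xyz) == n)
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (any(!nzchar(type))) stop("empty atom type label")
  if (is.null(bonds) || length(bonds) == 0) {
    bonds <- matrix(integer(0), ncol = 2)
  } else {
    bonds <- matrix(as.integer(bonds), ncol = 2)
  }
  if (nrow(bonds) > 0) {
    if (any(bonds < 1L) || any(bonds > n)) stop("bond index out of range")
    if (any(bonds[, 1] == bonds[, 2])) stop("self-bond not allowed")
    bonds <- t(apply(bonds, 1, sort))
    bonds <- unique(bonds)
    bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
  }
  structure(list(
    name = as.character(name),
    atoms = data.frame(element = as.character(element),
                       type = as.character(type),
                       charge = as.numeric(charge),
                       stringsAsFactors = FALSE),
    xyz = xyz,
    bonds = bonds
  ), class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule '%s': %d atoms, %d bonds\n",
              x$name, nrow(x$atoms), nrow(x$bonds)))
  cat("  types:", paste(unique(x$atoms$type), collapse = " "), "\n")
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

# Adjacency list (list of integer vectors, sorted).
neighbor_list <- function(mol) {
  n <- n_atoms(mol)
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer(0)
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[r, 1]; j <- mol$bonds[r, 2]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  lapply(nb, sort)
}

#' Read a Tripos mol2 file
#'
#' Parses the MOLECULE, ATOM and BOND records of a Tripos mol2 file. Atom
#' order is preserved; partial charges are taken from column 9 of the ATOM
#' records when present and set to zero otherwise. Element symbols are
#' derived from the atom-type field (text before the first dot) when they
#' are not standard symbols themselves.
#'
#' @param path Path to a mol2 file.
#' @return A [molecule()].
#' @export
read_mol2 <- function(path) {
  if (!file.exists(path)) stop("mol2 file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  sect <- function(tag) which(lines == paste0("@<TRIPOS>", tag))
  ia <- sect("ATOM"); ib <- sect("BOND")
  if (length(ia) == 0) stop("mol2 file has no ATOM section: ", path)
  if (length(ib) == 0) stop("mol2 file has no BOND section: ", path)
  markers <- sort(c(grep("^@<TRIPOS>", lines), length(lines) + 1L))
  body <- function(start) {
    end <- min(markers[markers > start]) - 1L
    ln <- lines[seq(start + 1L, length.out = max(0L, end - start))]
    ln[nzchar(trimws(ln)) & !grepl("^#", ln)]
  }
  im <- sect("MOLECULE")
  name <- if (length(im)) trimws(lines[im[1] + 1L]) else "mol"

  at_lines <- body(ia[1])
  parse_atom <- function(ln, lineno) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 6) stop("malformed ATOM record at line: ", lineno, ": ", ln)
    xyzv <- suppressWarnings(as.numeric(f[3:5]))
    if (any(is.na(xyzv))) stop("malformed ATOM coordinates at line: ", lineno, ": ", ln)
    q <- if (length(f) >= 9) suppressWarnings(as.numeric(f[9])) else 0
    if (is.na(q)) q <- 0
    list(name = f[2], xyz = xyzv, type = f[6], charge = q)
  }
  atoms <- lapply(seq_along(at_lines), function(k) parse_atom(at_lines[k], k))
  bd_lines <- body(ib[1])
  bonds <- if (length(bd_lines)) {
    t(vapply(seq_along(bd_lines), function(k) {
      f <- strsplit(trimws(bd_lines[k]), "\\s+")[[1]]
      if (length(f) < 3) stop("malformed BOND record at line: ", k, ": ", bd_lines[k])
      ij <- suppressWarnings(as.integer(f[2:3]))
      if (any(is.na(ij))) stop("malformed BOND record at line: ", k, ": ", bd_lines[k])
      ij
    }, integer(2)))
  } else matrix(integer(0), ncol = 2)

  type <- vapply(atoms, `[[`, "", "type")
  elem <- element_from_type(type, vapply(atoms, `[[`, "", "name"))
  molecule(name = name,
           element = elem,
           type = type,
           charge = vapply(atoms, `[[`, 0, "charge"),
           xyz = do.call(rbind, lapply(atoms, `[[`, "xyz")),
           bonds = bonds)
}

# Guess the element: SYBYL types look like "O.3"; GAFF types like "c3", "ob",
# "h1". Fall back on the leading letters of the atom name.
element_from_type <- function(type, name) {
  base <- sub("\\..*$", "", type)
  known <- c(B = "B", b = "B", ob = "O", o = "O", os = "O", oh = "O",
             c = "C", c3 = "C", c2 = "C", c1 = "C", ca = "C",
             h = "H", hc = "H", h1 = "H", h2 = "H", h3 = "H", ho = "H",
             ha = "H", hn = "H", n = "N", N = "N", O = "O", C = "C", H = "H")
  out <- character(length(type))
  for (k in seq_along(type)) {
    b <- base[k]
    if (b %in% names(known)) {
      out[k] <- known[[b]]
    } else if (toupper(b) %in% c("B", "C", "N", "O", "H", "F", "P", "S", "CL", "BR", "I")) {
      out[k] <- paste0(toupper(substr(b, 1, 1)), tolower(substring(b, 2)))
    } else {
      out[k] <- sub("[0-9]*$", "", toupper(substr(name[k], 1, 1)))
    }
  }
  out
}

#' Write a Tripos mol2 file
#'
#' Serializes a molecule to Tripos mol2. `read_mol2(write_mol2(m))` is the
#' identity on all fields a [molecule()] holds; charges are written with 6
#' decimal places, coordinates with 4.
#'
#' @param mol A [molecule()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mol2 <- function(mol, path) {
  n <- n_atoms(mol)
  nb <- nrow(mol$bonds)
  counts <- tabulate(factor(mol$atoms$element,
                            levels = unique(mol$atoms$element)))
  # unique per-element atom names (B1, O1, O2, ...)
  anames <- character(n)
  seen <- list()
  for (i in seq_len(n)) {
    e <- mol$atoms$element[i]
    seen[[e]] <- if (is.null(seen[[e]])) 1L else seen[[e]] + 1L
    anames[i] <- paste0(e, seen[[e]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@<TRIPOS>MOLECULE", mol$name,
               sprintf("%5d %5d %5d %5d %5d", n, nb, 1L, 0L, 0L),
               "SMALL", "USER_CHARGES", "", "@<TRIPOS>ATOM"), con)
  for (i in seq_len(n)) {
    writeLines(sprintf("%7d %-8s %10.4f %10.4f %10.4f %-6s %5d %-8s %10.6f",
                       i, anames[i], mol$xyz[i, 1], mol$xyz[i, 2],
                       mol$xyz[i, 3], mol$atoms$type[i], 1L, "MOL",
                       mol$atoms$charge[i]), con)
  }
  writeLines("@<TRIPOS>BOND", con)
  if (nb > 0) {
    for (r in seq_len(nb)) {
      writeLines(sprintf("%6d %5d %5d %s", r, mol$bonds[r, 1],
                         mol$bonds[r, 2], "1"), con)
    }
  }
  invisible(path)
}

#' Enumerate bonded topology
#'
#' Expands a molecule's bond graph into the term lists the Amber potential
#' sums over: bonds, angles (all unordered neighbor pairs around each
#' center), proper dihedrals (all bonded i-j-k-l paths with i != l), and
#' impropers (one per atom with exactly three neighbors, central atom third
#' in Amber order, peripherals sorted by type label then index). Also
#' classifies every atom pair as 1-2, 1-3 or 1-4 for nonbonded exclusions;
#' a pair gets the closest classification when several paths exist.
#'
#' @param mol A [molecule()].
#' @return An object of class `topology` with elements `bonds` (m x 2),
#'   `angles` (m x 3, center second), `dihedrals` (m x 4), `impropers`
#'   (m x 4, center third), and `pairs14`, `excluded` (two-column matrices).
#' @export
enumerate_topology <- function(mol) {
  n <- n_atoms(mol)
  nb <- neighbor_list(mol)
  bonds <- mol$bonds

  angles <- list()
  for (j in seq_len(n)) {
    ng <- nb[[j]]
    if (length(ng) >= 2) {
      cmb <- utils::combn(ng, 2)
      for (c1 in seq_len(ncol(cmb))) {
        angles[[length(angles) + 1L]] <- c(cmb[1, c1], j, cmb[2, c1])
      }
    }
  }
  angles <- if (length(angles)) do.call(rbind, angles) else matrix(integer(0), ncol = 3)

  dihedrals <- list()
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      for (jk in list(bonds[r, ], rev(bonds[r, ]))) {
        j <- jk[1]; k <- jk[2]
        if (j > k) next  # enumerate each central bond once, j < k
        for (i in setdiff(nb[[j]], k)) {
          for (l in setdiff(nb[[k]], j)) {
            if (i != l) dihedrals[[length(dihedrals) + 1L]] <- c(i, j, k, l)
          }
        }
      }
    }
  }
  dihedrals <- if (length(dihedrals)) do.call(rbind, dihedrals) else matrix(integer(0), ncol = 4)

  impropers <- list()
  for (j in seq_len(n)) {
    ng <- nb[[j]]
    if (length(ng) == 3) {
      ord <- ng[order(mol$atoms$type[ng], ng)]
      impropers[[length(impropers) + 1L]] <- c(ord[1], ord[2], j, ord[3])
    }
  }
  impropers <- if (length(impropers)) do.call(rbind, impropers) else matrix(integer(0), ncol = 4)

  # pair classification: BFS depth <= 3 from each atom
  cls <- matrix(0L, n, n)  # 0 none, 2/3/4 = 1-2/1-3/1-4
  for (i in seq_len(n)) {
    dist <- rep(NA_integer_, n); dist[i] <- 0L
    frontier <- i
    for (d in 1:3) {
      nxt <- unique(unlist(nb[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      dist[nxt] <- d
      frontier <- nxt
      if (!length(frontier)) break
    }
    for (j in which(!is.na(dist) & dist > 0)) cls[i, j] <- dist[j] + 1L
  }
  pair_mat <- function(code) {
    idx <- which(upper.tri(cls) & cls == code, arr.ind = TRUE)
    matrix(as.integer(idx), ncol = 2, dimnames = NULL)
  }
  structure(list(
    bonds = bonds, angles = angles, dihedrals = dihedrals,
    impropers = impropers,
    excluded = rbind(pair_mat(2L), pair_mat(3L)),
    pairs14 = pair_mat(4L)
  ), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d bonds, %d angles, %d dihedrals, %d impropers, %d 1-4 pairs\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals),
              nrow(x$impropers), nrow(x$pairs14)))
  invisible(x)
}

#' Apply boron atom-typing overrides
#'
#' Retypes every boron atom as `"B"` (sp2 boron) and every oxygen bonded to
#' a boron as `"ob"`; all other labels are left untouched. Idempotent; a
#' boron-free molecule is returned unchanged.
#'
#' @param mol A [molecule()].
#' @return The retyped [molecule()].
#' @export
retype_boron_environment <- function(mol) {
  is_b <- mol$atoms$element == "B"
  if (!any(is_b)) return(mol)
  mol$atoms$type[is_b] <- "B"
  nb <- neighbor_list(mol)
  for (b in which(is_b)) {
    ox <- nb[[b]][mol$atoms$element[nb[[b]]] == "O"]
    mol$atoms$type[ox] <- "ob"
  }
  mol
}
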