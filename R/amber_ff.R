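#' Construct a force field
#'
#' Container for Amber-style parameters, mirroring the sections of a frcmod
#' file. Dihedral barriers are stored as the per-term `Vn` printed in frcmod
#' (the 1/2 of the cosine form is applied in the energy expression) together
#' with the `divider` (Amber IDIVF). A negative periodicity on a stored term
#' is normalized to positive: the multi-term chaining convention is purely a
#' serialization detail handled by [write_frcmod()]/[read_frcmod()].
#'
#' @param bonds data.frame with columns `t1,t2,Kr,req` (kcal/mol/A^2, A).
#' @param angles data.frame with columns `t1,t2,t3,Ktheta,theta_eq`
#'   (kcal/mol/rad^2, degrees).
#' @param dihedrals data.frame with columns `t1,t2,t3,t4,divider,Vn,gamma,n`;
#'   type label `"X"` is the Amber wildcard.
#' @param impropers data.frame with columns `t1,t2,t3,t4,Vn,gamma,n`
#'   (central atom third).
#' @param nonbond data.frame with columns `type,rmin_half,epsilon` (A,
#'   kcal/mol).
#' @param masses data.frame with columns `type,mass` (amu).
#' @return An object of class `forcefield`.
#' @export
forcefield <- function(bonds = NULL, angles = NULL, dihedrals = NULL,
                       impropers = NULL, nonbond = NULL, masses = NULL) {
  empty <- function(...) {
    cols <- list(...)
    as.data.frame(lapply(cols, function(cl) vector(cl, 0)),
                  col.names = names(cols), stringsAsFactors = FALSE)
  }
  ff <- structure(list(
    bonds = empty(t1 = "character", t2 = "character",
                  Kr = "numeric", req = "numeric"),
    angles = empty(t1 = "character", t2 = "character", t3 = "character",
                   Ktheta = "numeric", theta_eq = "numeric"),
    dihedrals = empty(t1 = "character", t2 = "character", t3 = "character",
                      t4 = "character", divider = "integer", Vn = "numeric",
                      gamma = "numeric", n = "numeric"),
    impropers = empty(t1 = "character", t2 = "character", t3 = "character",
                      t4 = "character", Vn = "numeric", gamma = "numeric",
                      n = "numeric"),
    nonbond = empty(type = "character", rmin_half = "numeric",
                    epsilon = "numeric"),
    masses = empty(type = "character", mass = "numeric")
  ), class = "forcefield")
  if (!is.null(bonds)) for (r in seq_len(nrow(bonds)))
    ff <- ff_add_bond(ff, bonds$t1[r], bonds$t2[r], bonds$Kr[r], bonds$req[r])
  if (!is.null(angles)) for (r in seq_len(nrow(angles)))
    ff <- ff_add_angle(ff, angles$t1[r], angles$t2[r], angles$t3[r],
                       angles$Ktheta[r], angles$theta_eq[r])
  if (!is.null(dihedrals)) for (r in seq_len(nrow(dihedrals)))
    ff <- ff_add_dihedral(ff, unlist(dihedrals[r, c("t1", "t2", "t3", "t4")]),
                          dihedrals$divider[r], dihedrals$Vn[r],
                          dihedrals$gamma[r], dihedrals$n[r])
  if (!is.null(impropers)) for (r in seq_len(nrow(impropers)))
    ff <- ff_add_improper(ff, unlist(impropers[r, c("t1", "t2", "t3", "t4")]),
                          impropers$Vn[r], impropers$gamma[r], impropers$n[r])
  if (!is.null(nonbond)) for (r in seq_len(nrow(nonbond)))
    ff <- ff_add_nonbond(ff, nonbond$type[r], nonbond$rmin_half[r],
                         nonbond$epsilon[r])
  if (!is.null(masses)) for (r in seq_len(nrow(masses)))
    ff <- ff_add_mass(ff, masses$type[r], masses$mass[r])
  ff
}

#' @export
print.forcefield <- function(x, ...) {
  cat(sprintf(paste0("forcefield: %d bond, %d angle, %d dihedral, ",
                     "%d improper terms; %d nonbond types\n"),
              nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals),
              nrow(x$impropers), nrow(x$nonbond)))
  invisible(x)
}

#' @rdname forcefield
#' @param ff A `forcefield`.
#' @param t1,t2,t3,t4 Atom-type labels.
#' @param Kr,req,Ktheta,theta_eq,Vn,gamma,n,divider Term parameters.
#' @param types Character vector of type labels (length 4 for dihedral and
#'   improper adders).
#' @param type,rmin_half,epsilon,mass Nonbond/mass parameters.
#' @export
ff_add_bond <- function(ff, t1, t2, Kr, req) {
  stopifnot(Kr > 0, req > 0)
  have <- which((ff$bonds$t1 == t1 & ff$bonds$t2 == t2) |
                  (ff$bonds$t1 == t2 & ff$bonds$t2 == t1))
  if (length(have)) {
    warning("replacing duplicate bond term ", t1, "-", t2)
    ff$bonds <- ff$bonds[-have, , drop = FALSE]
  }
  ff$bonds[nrow(ff$bonds) + 1L, ] <- list(t1, t2, Kr, req)
  ff
}

#' @rdname forcefield
#' @export
ff_add_angle <- function(ff, t1, t2, t3, Ktheta, theta_eq) {
  stopifnot(Ktheta > 0, theta_eq > 0, theta_eq <= 180)
  have <- which(ff$angles$t2 == t2 &
                  ((ff$angles$t1 == t1 & ff$angles$t3 == t3) |
                     (ff$angles$t1 == t3 & ff$angles$t3 == t1)))
  if (length(have)) {
    warning("replacing duplicate angle term ",
            paste(c(t1, t2, t3), collapse = "-"))
    ff$angles <- ff$angles[-have, , drop = FALSE]
  }
  ff$angles[nrow(ff$angles) + 1L, ] <- list(t1, t2, t3, Ktheta, theta_eq)
  ff
}

#' @rdname forcefield
#' @export
ff_add_dihedral <- function(ff, types, divider, Vn, gamma, n) {
  n <- as.numeric(n)
  types <- as.character(types)
  stopifnot(length(types) == 4, divider >= 1, abs(n) %in% c(1, 2, 3, 4, 6))
  d <- ff$dihedrals
  have <- which(abs(d$n) == abs(n) & dihedral_rows_match(d, types))
  if (length(have)) {
    warning("replacing duplicate dihedral term ",
            paste(types, collapse = "-"), " |n|=", abs(n))
    ff$dihedrals <- ff$dihedrals[-have, , drop = FALSE]
  }
  ff$dihedrals[nrow(ff$dihedrals) + 1L, ] <-
    c(as.list(types), as.integer(divider), Vn, gamma, abs(n))
  ff
}

#' @rdname forcefield
#' @export
ff_add_improper <- function(ff, types, Vn, gamma, n) {
  stopifnot(length(types) == 4)
  key <- c(sort(types[c(1, 2, 4)]), types[3])[c(1, 2, 4, 3)]
  ff$impropers[nrow(ff$impropers) + 1L, ] <-
    c(as.list(key), Vn, gamma, as.numeric(n))
  ff
}

#' @rdname forcefield
#' @export
ff_add_nonbond <- function(ff, type, rmin_half, epsilon) {
  stopifnot(rmin_half > 0, epsilon >= 0)
  have <- which(ff$nonbond$type == type)
  if (length(have)) {
    warning("replacing duplicate nonbond type ", type)
    ff$nonbond <- ff$nonbond[-have, , drop = FALSE]
  }
  ff$nonbond[nrow(ff$nonbond) + 1L, ] <- list(type, rmin_half, epsilon)
  ff
}

#' @rdname forcefield
#' @export
ff_add_mass <- function(ff, type, mass) {
  have <- which(ff$masses$type == type)
  if (length(have)) ff$masses <- ff$masses[-have, , drop = FALSE]
  ff$masses[nrow(ff$masses) + 1L, ] <- list(type, mass)
  ff
}

# canonical orderings: terms are stored as inserted (so frcmod output
# reproduces published table layouts verbatim); these keys make lookups and
# aggregation direction-independent
canon_pair <- function(t) if (t[1] <= t[2]) t else rev(t)
canon_triple <- function(t) if (t[1] <= t[3]) t else rev(t)
canon_quad <- function(t) {
  if (t[2] < t[3] || (t[2] == t[3] && t[1] <= t[4])) t else rev(t)
}

# rows of a dihedral table matching a type quadruple in either direction
dihedral_rows_match <- function(d, types) {
  (d$t1 == types[1] & d$t2 == types[2] & d$t3 == types[3] &
     d$t4 == types[4]) |
    (d$t1 == types[4] & d$t2 == types[3] & d$t3 == types[2] &
       d$t4 == types[1])
}

#' Look up bond / angle parameters
#'
#' Direction-independent exact lookup. Returns a one-row data.frame, or a
#' zero-row data.frame when the force field holds no matching term.
#'
#' @param ff A [forcefield()].
#' @param types Character vector of 2 (bond) or 3 (angle) type labels.
#' @return A data.frame of matching terms.
#' @export
lookup_bond <- function(ff, types) {
  ff$bonds[(ff$bonds$t1 == types[1] & ff$bonds$t2 == types[2]) |
             (ff$bonds$t1 == types[2] & ff$bonds$t2 == types[1]), ,
           drop = FALSE]
}

#' @rdname lookup_bond
#' @export
lookup_angle <- function(ff, types) {
  ff$angles[ff$angles$t2 == types[2] &
              ((ff$angles$t1 == types[1] & ff$angles$t3 == types[3]) |
                 (ff$angles$t1 == types[3] & ff$angles$t3 == types[1])), ,
            drop = FALSE]
}

#' Look up dihedral parameters with GAFF wildcard semantics
#'
#' Match priority follows Amber: an exact quadruple match (in either
#' direction) wins; otherwise a wildcard pattern `X-t2-t3-X` on the two
#' central types (either direction) is used. The full multi-term expansion
#' for the winning pattern is returned; an empty data.frame means no match.
#'
#' @param ff A [forcefield()].
#' @param types Character vector of 4 type labels.
#' @return data.frame of matching dihedral terms (possibly several rows).
#' @export
lookup_dihedral <- function(ff, types) {
  d <- ff$dihedrals[dihedral_match_rows(ff, types), , drop = FALSE]
  d
}

# row indices matched for a quadruple: exact (either direction) first,
# wildcard X-t2-t3-X (either direction) otherwise
dihedral_match_rows <- function(ff, types) {
  stopifnot(length(types) == 4)
  d <- ff$dihedrals
  hit <- which(dihedral_rows_match(d, types))
  if (length(hit)) return(hit)
  which(dihedral_rows_match(d, c("X", types[2], types[3], "X")))
}

#' @rdname lookup_bond
#' @export
lookup_improper <- function(ff, types) {
  stopifnot(length(types) == 4)
  center <- types[3]
  peri <- sort(types[c(1, 2, 4)])
  d <- ff$impropers
  keep <- logical(nrow(d))
  for (r in seq_len(nrow(d))) {
    keep[r] <- d$t3[r] == center &&
      identical(sort(c(d$t1[r], d$t2[r], d$t4[r])), peri)
  }
  d[keep, , drop = FALSE]
}

#' Report topology terms with no force-field match
#'
#' The frcmod-building analogue of a parameter check: every unique type
#' tuple appearing in the molecule's topology that cannot be resolved in
#' `ff` (wildcards considered for dihedrals) is listed once.
#'
#' @param top A [enumerate_topology()] result.
#' @param mol The typed [molecule()].
#' @param ff A [forcefield()].
#' @return A list of data.frames `bonds`, `angles`, `dihedrals`,
#'   `impropers`, each holding the missing type tuples.
#' @export
missing_parameters <- function(top, mol, ff) {
  ty <- mol$atoms$type
  uniq_rows <- function(m, canon) {
    if (!nrow(m)) return(matrix(character(0), ncol = ncol(m)))
    keys <- t(apply(m, 1, function(ix) canon(ty[ix])))
    unique(keys)
  }
  bk <- uniq_rows(top$bonds, canon_pair)
  ak <- uniq_rows(top$angles, canon_triple)
  dk <- uniq_rows(top$dihedrals, canon_quad)
  ik <- if (nrow(top$impropers)) {
    unique(t(apply(top$impropers, 1, function(ix) {
      t <- ty[ix]; c(sort(t[c(1, 2, 4)]), t[3])[c(1, 2, 4, 3)]
    })))
  } else matrix(character(0), ncol = 4)

  mk_df <- function(keys, found) {
    keys <- keys[!found, , drop = FALSE]
    df <- as.data.frame(keys, stringsAsFactors = FALSE)
    if (ncol(df)) names(df) <- paste0("t", seq_len(ncol(df)))
    df
  }
  list(
    bonds = mk_df(bk, vapply(seq_len(nrow(bk)), function(r)
      nrow(lookup_bond(ff, bk[r, ])) > 0, logical(1))),
    angles = mk_df(ak, vapply(seq_len(nrow(ak)), function(r)
      nrow(lookup_angle(ff, ak[r, ])) > 0, logical(1))),
    dihedrals = mk_df(dk, vapply(seq_len(nrow(dk)), function(r)
      nrow(lookup_dihedral(ff, dk[r, ])) > 0, logical(1))),
    impropers = mk_df(ik, vapply(seq_len(nrow(ik)), function(r)
      nrow(lookup_improper(ff, ik[r, ])) > 0, logical(1)))
  )
}

fmt_types <- function(types) {
  paste(sprintf("%-2s", types), collapse = "-")
}

#' Write an Amber frcmod file
#'
#' Emits MASS, BOND, ANGLE, DIHE, IMPROPER and NONBON sections in the Amber
#' fixed-width dialect. Multi-term dihedrals for the same type quadruple are
#' chained with the negative-periodicity convention: every term but the last
#' carries a negative PN.
#'
#' @param ff A [forcefield()].
#' @param path Output path.
#' @param title First (remark) line of the file.
#' @return Invisibly, `path`.
#' @export
write_frcmod <- function(ff, path, title = "frcmod written by boronparam") {
  used <- unique(c(ff$bonds$t1, ff$bonds$t2, ff$angles$t1, ff$angles$t2,
                   ff$angles$t3,
                   unlist(ff$dihedrals[c("t1", "t2", "t3", "t4")]),
                   unlist(ff$impropers[c("t1", "t2", "t3", "t4")])))
  used <- setdiff(used, "X")
  known <- union(ff$masses$type, ff$nonbond$type)
  if (length(miss <- setdiff(used, known)) && nrow(ff$masses)) {
    stop("type label(s) with no MASS/NONBON entry: ",
         paste(miss, collapse = ", "))
  }
  out <- c(title, "MASS")
  for (r in seq_len(nrow(ff$masses)))
    out <- c(out, sprintf("%-2s %8.3f", ff$masses$type[r], ff$masses$mass[r]))
  out <- c(out, "", "BOND")
  for (r in seq_len(nrow(ff$bonds)))
    out <- c(out, sprintf("%s  %9.3f %9.4f",
                          fmt_types(unlist(ff$bonds[r, c("t1", "t2")])),
                          ff$bonds$Kr[r], ff$bonds$req[r]))
  out <- c(out, "", "ANGLE")
  for (r in seq_len(nrow(ff$angles)))
    out <- c(out, sprintf("%s  %9.3f %9.3f",
                          fmt_types(unlist(ff$angles[r, c("t1", "t2", "t3")])),
                          ff$angles$Ktheta[r], ff$angles$theta_eq[r]))
  out <- c(out, "", "DIHE")
  if (nrow(ff$dihedrals)) {
    d <- ff$dihedrals
    keys <- vapply(seq_len(nrow(d)), function(r)
      paste(unlist(d[r, c("t1", "t2", "t3", "t4")]), collapse = "-"), "")
    for (key in unique(keys)) {
      grp <- d[keys == key, , drop = FALSE]
      grp <- grp[order(abs(grp$n)), , drop = FALSE]
      for (r in seq_len(nrow(grp))) {
        pn <- if (r < nrow(grp)) -abs(grp$n[r]) else abs(grp$n[r])
        out <- c(out, sprintf("%s %4d %9.3f %9.3f %9.3f",
                              fmt_types(unlist(grp[r, c("t1", "t2", "t3", "t4")])),
                              grp$divider[r], grp$Vn[r], grp$gamma[r], pn))
      }
    }
  }
  out <- c(out, "", "IMPROPER")
  for (r in seq_len(nrow(ff$impropers)))
    out <- c(out, sprintf("%s %14.3f %9.3f %9.1f",
                          fmt_types(unlist(ff$impropers[r, c("t1", "t2", "t3", "t4")])),
                          ff$impropers$Vn[r], ff$impropers$gamma[r],
                          ff$impropers$n[r]))
  out <- c(out, "", "NONBON")
  for (r in seq_len(nrow(ff$nonbond)))
    out <- c(out, sprintf("  %-2s %10.4f %10.4f", ff$nonbond$type[r],
                          ff$nonbond$rmin_half[r], ff$nonbond$epsilon[r]))
  out <- c(out, "")
  writeLines(out, path)
  invisible(path)
}

#' Read an Amber frcmod file
#'
#' Parses the dialect written by [write_frcmod()] (which matches
#' AmberTools' fixed-width layout). Negative dihedral periodicities are
#' interpreted as multi-term chaining and normalized to positive `n` in the
#' returned object.
#'
#' @param path Path to a frcmod file.
#' @return A [forcefield()].
#' @export
read_frcmod <- function(path) {
  if (!file.exists(path)) stop("frcmod file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  section <- ""
  ff <- forcefield()
  headers <- c("MASS", "BOND", "ANGLE", "DIHE", "DIHEDRAL", "IMPROPER", "NONBON", "NONB")
  split_types <- function(ln, k, lineno) {
    width <- 3L * k - 1L
    field <- substr(ln, 1, width)
    rest <- substring(ln, width + 1L)
    types <- trimws(strsplit(field, "-")[[1]])
    if (length(types) != k || any(!nzchar(types)))
      stop("unparseable type field at line ", lineno, ": ", ln)
    nums <- suppressWarnings(as.numeric(strsplit(trimws(rest), "\\s+")[[1]]))
    if (any(is.na(nums)))
      stop("unparseable numeric field at line ", lineno, ": ", ln)
    list(types = types, nums = nums)
  }
  for (k in seq_along(lines)) {
    ln <- lines[k]
    t <- trimws(ln)
    if (k == 1 || !nzchar(t)) next
    up <- toupper(t)
    if (up %in% headers) { section <- up; next }
    if (section == "MASS") {
      f <- strsplit(t, "\\s+")[[1]]
      ff <- ff_add_mass(ff, f[1], as.numeric(f[2]))
    } else if (section == "BOND") {
      p <- split_types(ln, 2L, k)
      ff <- ff_add_bond(ff, p$types[1], p$types[2], p$nums[1], p$nums[2])
    } else if (section == "ANGLE") {
      p <- split_types(ln, 3L, k)
      ff <- ff_add_angle(ff, p$types[1], p$types[2], p$types[3],
                         p$nums[1], p$nums[2])
    } else if (section %in% c("DIHE", "DIHEDRAL")) {
      p <- split_types(ln, 4L, k)
      if (length(p$nums) < 4) stop("short DIHE line at ", k, ": ", ln)
      ff <- ff_add_dihedral(ff, p$types, p$nums[1], p$nums[2], p$nums[3],
                            abs(p$nums[4]))
    } else if (section == "IMPROPER") {
      p <- split_types(ln, 4L, k)
      ff <- ff_add_improper(ff, p$types, p$nums[1], p$nums[2], p$nums[3])
    } else if (section %in% c("NONBON", "NONB")) {
      f <- strsplit(t, "\\s+")[[1]]
      ff <- ff_add_nonbond(ff, f[1], as.numeric(f[2]), as.numeric(f[3]))
    } else {
      stop("line ", k, " outside any recognised section: ", ln)
    }
  }
  ff
}
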