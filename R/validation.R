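# Structure-validation metrics: RMSD of atomic displacement after optimal
# rigid superposition (RMSD-AD), of bond lengths (RMSD-L), and of bond
# angles (RMSD-A, with angles at trivalent planar centers reported
# separately as the out-of-plane set).

#' Kabsch least-squares superposition
#'
#' Closed-form optimal rigid superposition of matched point sets via SVD,
#' with the determinant correction guaranteeing a proper rotation
#' (det = +1).
#'
#' @param ref,mov M x 3 coordinate matrices (matched row order, M >= 3).
#' @return List with `rotation` (3 x 3), `translation` (length 3; the
#'   superposed coordinates are `mov %*% t(rotation) + translation`),
#'   `rmsd` (Angstrom), and `degenerate` (TRUE when the moving set is
#'   collinear so the rotation is not unique).
#' @export
kabsch_superpose <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  stopifnot(ncol(ref) == 3, ncol(mov) == 3, nrow(ref) == nrow(mov),
            nrow(ref) >= 3)
  cr <- colMeans(ref); cm <- colMeans(mov)
  P <- sweep(mov, 2, cm)
  Q <- sweep(ref, 2, cr)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-300)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(rotation = R, translation = as.vector(cr - cm %*% t(R)),
       rmsd = rmsd, degenerate = degenerate)
}

boron_core_selection <- function(mol) {
  b <- which(mol$atoms$element == "B")
  if (!length(b)) stop("no boron atom for the boron-core selection")
  nb <- neighbor_list(mol)
  sort(unique(c(b, unlist(nb[b]))))
}

#' RMSD of atomic displacement
#'
#' Kabsch-superposed RMSD over a selection of matched atoms. The default
#' selection is the boron core: each boron plus its bonded neighbors (for
#' a trivalent boron, the three directly adjacent atoms).
#'
#' @param ref,test [molecule()] objects with matched atom order.
#' @param selection Integer atom indices, or `"boron-core"` (default) or
#'   `"all"`.
#' @return RMSD in Angstrom.
#' @export
rmsd_ad <- function(ref, test, selection = "boron-core") {
  if (identical(selection, "boron-core")) {
    selection <- boron_core_selection(ref)
  } else if (identical(selection, "all")) {
    selection <- seq_len(n_atoms(ref))
  }
  stopifnot(max(selection) <= n_atoms(ref), max(selection) <= n_atoms(test))
  kabsch_superpose(ref$xyz[selection, , drop = FALSE],
                   test$xyz[selection, , drop = FALSE])$rmsd
}

#' RMSD of bond lengths
#'
#' Superposition-free: `sqrt(mean((L_ref - L_test)^2))` over the bond list.
#'
#' @param ref,test [molecule()] objects with matched atom order.
#' @param bonds Two-column index matrix (default: `ref$bonds`).
#' @return RMSD in Angstrom.
#' @export
rmsd_l <- function(ref, test, bonds = ref$bonds) {
  if (is.null(bonds) || nrow(bonds) == 0) stop("empty bond list")
  dl <- vapply(seq_len(nrow(bonds)), function(r) {
    atom_distance(ref$xyz, bonds[r, 1], bonds[r, 2]) -
      atom_distance(test$xyz, bonds[r, 1], bonds[r, 2])
  }, 0)
  sqrt(mean(dl^2))
}

# angles centered on a trivalent planar center (boron here) are the ones
# spanning its improper plane
is_outplane_angle <- function(mol, angles) {
  nb <- neighbor_list(mol)
  vapply(seq_len(nrow(angles)), function(r) {
    ctr <- angles[r, 2]
    mol$atoms$element[ctr] == "B" && length(nb[[ctr]]) == 3
  }, logical(1))
}

#' RMSD of bond angles
#'
#' `sqrt(mean((a_ref - a_test)^2))` over an angle list, in degrees. With
#' `exclude_out_of_plane = TRUE` (the default, matching the reporting
#' convention used for planar boron centers), angles centered on a
#' trivalent planar center are excluded from the main value and reported
#' separately in the `outplane` attribute.
#'
#' @param ref,test [molecule()] objects with matched atom order.
#' @param angles Three-column index matrix, center second (default: the
#'   angles of `ref`'s topology).
#' @param exclude_out_of_plane Exclude angles at trivalent planar centers.
#' @return RMSD in degrees; attribute `outplane` carries the RMSD of the
#'   excluded set (NA when empty or when nothing was excluded).
#' @export
rmsd_a <- function(ref, test, angles = NULL, exclude_out_of_plane = TRUE) {
  if (is.null(angles)) angles <- enumerate_topology(ref)$angles
  if (nrow(angles) == 0) stop("empty angle list")
  da <- vapply(seq_len(nrow(angles)), function(r) {
    atom_angle(ref$xyz, angles[r, 1], angles[r, 2], angles[r, 3]) -
      atom_angle(test$xyz, angles[r, 1], angles[r, 2], angles[r, 3])
  }, 0)
  if (exclude_out_of_plane) {
    op <- is_outplane_angle(ref, angles)
    main <- sqrt(mean(da[!op]^2))
    outp <- if (any(op)) sqrt(mean(da[op]^2)) else NA_real_
    structure(main, outplane = outp)
  } else {
    structure(sqrt(mean(da^2)), outplane = NA_real_)
  }
}

#' Build a Table-style RMSD validation report
#'
#' Two input forms are accepted:
#' * a list of entries `list(name=, ref=, test=)` — the three metrics are
#'   computed per entry ([rmsd_ad()] with the boron-core selection,
#'   [rmsd_l()] over the reference bonds, [rmsd_a()] with out-of-plane
#'   exclusion);
#' * a data.frame of precomputed rows with columns `name`, `rmsd_ad`,
#'   `rmsd_l`, `rmsd_a` (optionally `rmsd_a_outplane`), used as-is — e.g.
#'   published per-structure values.
#'
#' An `Average` row of unweighted arithmetic means is appended.
#'
#' @param entries List of entries or a precomputed data.frame (see above).
#' @return An object of class `rmsd_report`: a data.frame with the per-
#'   structure rows plus the Average row.
#' @export
make_report <- function(entries) {
  if (is.data.frame(entries)) {
    rows <- entries
    stopifnot(all(c("name", "rmsd_ad", "rmsd_l", "rmsd_a") %in% names(rows)))
    if (is.null(rows$rmsd_a_outplane)) rows$rmsd_a_outplane <- NA_real_
  } else {
    if (!length(entries)) stop("empty report")
    rows <- do.call(rbind, lapply(entries, function(e) {
      a <- rmsd_a(e$ref, e$test)
      data.frame(name = e$name,
                 rmsd_ad = rmsd_ad(e$ref, e$test),
                 rmsd_l = rmsd_l(e$ref, e$test),
                 rmsd_a = as.numeric(a),
                 rmsd_a_outplane = attr(a, "outplane"),
                 stringsAsFactors = FALSE)
    }))
  }
  avg <- data.frame(name = "Average",
                    rmsd_ad = mean(rows$rmsd_ad),
                    rmsd_l = mean(rows$rmsd_l),
                    rmsd_a = mean(rows$rmsd_a),
                    rmsd_a_outplane = mean(rows$rmsd_a_outplane),
                    stringsAsFactors = FALSE)
  out <- rbind(rows, avg)
  rownames(out) <- NULL
  structure(out, class = c("rmsd_report", "data.frame"))
}

#' @export
print.rmsd_report <- function(x, ...) {
  cat(sprintf("%-12s %9s %9s %18s\n", "Molecule", "RMSD-AD", "RMSD-L",
              "RMSD-A"))
  for (r in seq_len(nrow(x))) {
    a <- if (is.na(x$rmsd_a_outplane[r])) {
      sprintf("%9.4f", x$rmsd_a[r])
    } else {
      sprintf("%9.4f (%.4f)", x$rmsd_a[r], x$rmsd_a_outplane[r])
    }
    cat(sprintf("%-12s %9.4f %9.5f %18s\n", x$name[r], x$rmsd_ad[r],
                x$rmsd_l[r], a))
  }
  invisible(x)
}
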