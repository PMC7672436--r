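# Collective variables: Opening/Shear (via base frames), distances,
# pseudo-dihedrals, bending angle and RMSD-to-target.

#' Mass-weighted center of mass of a selection
#'
#' @param atoms Atom table.
#' @param exclude_hydrogens Drop hydrogens before averaging (default TRUE).
#' @return Length-3 position (Angstrom).
#' @export
center_of_mass <- function(atoms, exclude_hydrogens = TRUE) {
  if (exclude_hydrogens) atoms <- atoms[atoms$element != "H", , drop = FALSE]
  if (nrow(atoms) == 0) stop("empty selection after hydrogen exclusion")
  m <- .ATOMIC_MASS[atoms$element]
  if (any(is.na(m))) {
    stop("unknown element mass: ", paste(unique(atoms$element[is.na(m)]), collapse = ", "))
  }
  as.vector(crossprod(coords(atoms), m) / sum(m))
}

.select <- function(atoms, residues = NULL, names = NULL) {
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(residues)) keep <- keep & atoms$residue_index %in% residues
  if (!is.null(names)) keep <- keep & atoms$name %in% names
  out <- atoms[keep, , drop = FALSE]
  .as_atom_table(out)
}

#' DNA bending angle from three segment centers of mass
#'
#' Angle at the central segment's COM subtended by the two arm COMs; the
#' class-I default segments for a 26-residue duplex are residues 1-4 with
#' 23-26 (arm 1), 5-9 with 18-22 (central) -- note the standard convention
#' uses the central part as the vertex -- and 10-17 (arm 2).
#'
#' @param atoms Atom table.
#' @param segments List of three residue-index vectors
#'   (arm 1, vertex, arm 2).
#' @param exclude_hydrogens Passed to [center_of_mass()].
#' @return Angle in degrees in [0, 180].
#' @export
cv_bend_angle <- function(atoms,
                          segments = list(c(1:4, 23:26), c(5:9, 18:22), 10:17),
                          exclude_hydrogens = TRUE) {
  stopifnot(length(segments) == 3)
  for (i in 1:2) for (j in (i + 1):3) {
    if (length(intersect(segments[[i]], segments[[j]])) > 0) {
      stop("segments must be disjoint")
    }
  }
  coms <- lapply(segments, function(rs) {
    center_of_mass(.select(atoms, residues = rs), exclude_hydrogens)
  })
  angle3(coms[[1]], coms[[2]], coms[[3]])
}

#' Optimal-superposition RMSD to a target structure
#'
#' Unweighted Kabsch superposition over a one-to-one atom selection.
#'
#' @param atoms Atom table.
#' @param target Atom table of the target.
#' @param residues,names Optional selection filters applied to both.
#' @return RMSD in Angstrom (>= 0).
#' @export
cv_rmsd_to_target <- function(atoms, target, residues = NULL,
                              names = .BACKBONE_ATOMS) {
  a <- .select(atoms, residues, names)
  b <- .select(target, residues, names)
  if (nrow(a) != nrow(b)) {
    stop("selection size mismatch: ", nrow(a), " vs ", nrow(b), " atoms")
  }
  if (nrow(a) < 3) stop("need at least 3 atoms for superposition")
  .kabsch(coords(b), coords(a))$rmsd
}

#' Pseudo-dihedral of four centers of mass
#'
#' @param atoms Atom table.
#' @param selections List of four residue-index vectors (or lists with
#'   `residues`/`names` entries for finer control).
#' @param exclude_hydrogens Passed to [center_of_mass()].
#' @return Signed dihedral in degrees, (-180, 180].
#' @export
cv_pseudo_dihedral <- function(atoms, selections, exclude_hydrogens = TRUE) {
  stopifnot(length(selections) == 4)
  coms <- lapply(selections, function(s) {
    sub <- if (is.list(s)) .select(atoms, s$residues, s$names)
           else .select(atoms, residues = s)
    center_of_mass(sub, exclude_hydrogens)
  })
  dihedral4(coms[[1]], coms[[2]], coms[[3]], coms[[4]])
}

#' Distance between two atoms or selection centers of mass
#'
#' Covers the N1-N3 distance (point-point) and the ring-ring distance
#' (COM-COM) through selection presets.
#'
#' @param atoms Atom table.
#' @param sel_a,sel_b Either a list(residues=, names=) selection or a single
#'   atom name paired with `res_a`/`res_b`.
#' @param res_a,res_b Residue indices when `sel_a`/`sel_b` are atom names.
#' @param com Use selection centers of mass instead of single atoms.
#' @return Distance in Angstrom.
#' @export
cv_distance <- function(atoms, sel_a, sel_b, res_a = NULL, res_b = NULL,
                        com = FALSE) {
  get_point <- function(sel, res) {
    if (is.list(sel)) {
      sub <- .select(atoms, sel$residues, sel$names)
      if (nrow(sub) == 0) stop("unresolvable selection")
      if (com || nrow(sub) > 1) center_of_mass(sub, exclude_hydrogens = TRUE)
      else c(sub$x, sub$y, sub$z)
    } else {
      sub <- .select(atoms, residues = res, names = sel)
      if (nrow(sub) == 0) stop("unresolvable atom name '", sel, "'")
      c(sub$x[1], sub$y[1], sub$z[1])
    }
  }
  .vnorm(get_point(sel_b, res_b) - get_point(sel_a, res_a))
}

#' N1-N3 distance of a base pair
#' @param atoms Atom table.
#' @param res_a,res_b Residue indices of the paired bases.
#' @return Distance in Angstrom between the WC-edge ring nitrogens
#'   (N1 of purines, N3 of pyrimidines).
#' @export
cv_d_n1n3 <- function(atoms, res_a, res_b) {
  wc_atom <- function(res) {
    b <- base_code(residue_atoms(atoms, res)$residue_name[1])
    if (b %in% .PURINES) "N1" else "N3"
  }
  cv_distance(atoms, wc_atom(res_a), wc_atom(res_b), res_a = res_a, res_b = res_b)
}

#' Ring-COM distance of a base pair
#' @param atoms Atom table.
#' @param res_a,res_b Residue indices.
#' @param six_membered Use only the six-membered ring atoms (default TRUE);
#'   otherwise all ring atoms.
#' @return Distance in Angstrom between base-ring centers of mass.
#' @export
cv_d_ring <- function(atoms, res_a, res_b, six_membered = TRUE) {
  ring_sel <- function(res) {
    b <- base_code(residue_atoms(atoms, res)$residue_name[1])
    nm <- .RING_ATOMS[[b]]
    if (six_membered && b %in% .PURINES) nm <- c("N1", "C2", "N3", "C4", "C5", "C6")
    list(residues = res, names = nm)
  }
  cv_distance(atoms, ring_sel(res_a), ring_sel(res_b), com = TRUE)
}

#' Define a collective variable
#'
#' @param name Identifier.
#' @param kind One of "opening", "shear", "distance_n1n3", "distance_ring",
#'   "pseudo_dihedral", "bend_angle", "rmsd_to_target".
#' @param selections Kind-specific selections (see the cv_* functions).
#' @param target Target atom table for "rmsd_to_target".
#' @param orientations Glycosidic orientations for opening/shear (NULL:
#'   classify from chi).
#' @return Object of class "cv_definition" with fields `periodic` and
#'   `units` filled in by kind.
#' @export
cv_definition <- function(name, kind, selections = NULL, target = NULL,
                          orientations = NULL) {
  kinds <- c("opening", "shear", "distance_n1n3", "distance_ring",
             "pseudo_dihedral", "bend_angle", "rmsd_to_target")
  if (!kind %in% kinds) stop("unknown CV kind: ", kind)
  periodic <- kind %in% c("opening", "pseudo_dihedral")
  units <- if (kind %in% c("opening", "pseudo_dihedral", "bend_angle")) "degrees" else "angstrom"
  structure(list(name = name, kind = kind, selections = selections,
                 target = target, orientations = orientations,
                 periodic = periodic, units = units),
            class = "cv_definition")
}

#' Evaluate a collective variable on one structure
#' @param cv A `cv_definition`.
#' @param atoms Atom table.
#' @return Numeric CV value in the CV's units.
#' @export
evaluate_cv <- function(cv, atoms) {
  s <- cv$selections
  switch(cv$kind,
    opening = measure_pair(atoms, s[[1]], s[[2]], cv$orientations)$params$opening,
    shear = measure_pair(atoms, s[[1]], s[[2]], cv$orientations)$params$shear,
    distance_n1n3 = cv_d_n1n3(atoms, s[[1]], s[[2]]),
    distance_ring = cv_d_ring(atoms, s[[1]], s[[2]]),
    pseudo_dihedral = cv_pseudo_dihedral(atoms, s),
    bend_angle = if (is.null(s)) cv_bend_angle(atoms) else cv_bend_angle(atoms, s),
    rmsd_to_target = cv_rmsd_to_target(atoms, cv$target,
                                       residues = s$residues, names = s$names)
  )
}

#' Evaluate a collective variable along a trajectory
#'
#' @param trajectory List of atom tables (frames).
#' @param cv A `cv_definition`.
#' @return data.frame: frame_index, value (periodic values wrapped); failing
#'   frames are reported together in an error naming their indices.
#' @export
evaluate_cv_series <- function(trajectory, cv) {
  n <- length(trajectory)
  vals <- rep(NA_real_, n)
  errs <- character(0)
  for (i in seq_len(n)) {
    v <- tryCatch(evaluate_cv(cv, trajectory[[i]]), error = function(e) e)
    if (inherits(v, "error")) errs <- c(errs, paste0("frame ", i, ": ", conditionMessage(v)))
    else vals[i] <- v
  }
  if (length(errs) > 0) stop("CV evaluation failed on ", length(errs), " frame(s):\n",
                             paste(errs, collapse = "\n"))
  if (cv$periodic) vals <- wrap_angle(vals)
  data.frame(frame_index = seq_len(n), value = vals)
}
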