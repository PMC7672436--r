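# Geometric hydrogen-bond detection between nucleobases.

#' Default hydrogen-bond donor/acceptor roles per base
#'
#' Amino and imino nitrogens as donors; carbonyl oxygens and unprotonated
#' ring nitrogens as acceptors.
#' @return Named list (A, C, G, T) of donor/acceptor atom-name vectors.
#' @export
hbond_roles <- function() .HB_ROLES

#' Detect hydrogen bonds between residues
#'
#' A donor-acceptor pair in different residues is reported when the
#' heavy-atom distance is at or below `dist_cutoff` and, when a hydrogen
#' bonded to the donor is present, the donor-H...acceptor angle is at least
#' `angle_cutoff`.  Without hydrogens (the usual case for built idealized
#' coordinates) only the distance criterion applies.
#'
#' The default distance cutoff is 3.1 Angstrom: the conventional
#' MD-trajectory default of 3.0 Angstrom sits exactly on the longest
#' Watson-Crick contacts of the rigid standard-base geometry (about
#' 3.00-3.02 Angstrom), so the package default adds a 0.1 Angstrom tolerance
#' for idealized coordinates.  Both cutoffs are configurable.
#'
#' @param atoms Atom table.
#' @param roles Donor/acceptor table as from [hbond_roles()].
#' @param dist_cutoff Heavy-atom distance cutoff, Angstrom.
#' @param angle_cutoff Donor-H...acceptor angle cutoff, degrees.
#' @return data.frame: donor_res, donor_atom, acceptor_res, acceptor_atom,
#'   heavy_distance, angle (NA when no hydrogen is present).
#' @export
detect_hbonds <- function(atoms, roles = hbond_roles(),
                          dist_cutoff = 3.1, angle_cutoff = 135) {
  if (length(roles) == 0) stop("empty donor/acceptor role table")
  res_ids <- unique(atoms$residue_index)
  out <- list()
  for (ri in res_ids) {
    ra <- atoms[atoms$residue_index == ri, , drop = FALSE]
    base_i <- base_code(ra$residue_name[1])
    donors <- intersect(roles[[base_i]]$donors, ra$name)
    if (length(donors) == 0) next
    for (rj in setdiff(res_ids, ri)) {
      rb <- atoms[atoms$residue_index == rj, , drop = FALSE]
      base_j <- base_code(rb$residue_name[1])
      acceptors <- intersect(roles[[base_j]]$acceptors, rb$name)
      for (dn in donors) {
        dpos <- .atom_xyz(ra, dn)
        # hydrogens covalently attached to this donor, if any
        hyd <- ra[ra$element == "H", , drop = FALSE]
        if (nrow(hyd) > 0) {
          hd <- sqrt((hyd$x - dpos[1])^2 + (hyd$y - dpos[2])^2 + (hyd$z - dpos[3])^2)
          hyd <- hyd[hd < 1.3, , drop = FALSE]
        }
        for (an in acceptors) {
          apos <- .atom_xyz(rb, an)
          dist <- .vnorm(apos - dpos)
          if (dist > dist_cutoff) next
          ang <- NA_real_
          if (nrow(hyd) > 0) {
            angs <- vapply(seq_len(nrow(hyd)), function(k) {
              angle3(dpos, c(hyd$x[k], hyd$y[k], hyd$z[k]), apos)
            }, numeric(1))
            ang <- max(angs)
            if (ang < angle_cutoff) next
          }
          out[[length(out) + 1]] <- data.frame(
            donor_res = ri, donor_atom = dn, acceptor_res = rj,
            acceptor_atom = an, heavy_distance = dist, angle = ang
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(donor_res = integer(), donor_atom = character(),
                      acceptor_res = integer(), acceptor_atom = character(),
                      heavy_distance = numeric(), angle = numeric()))
  }
  do.call(rbind, out)
}
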