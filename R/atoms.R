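# Atom tables: the package-wide structure container is a plain data.frame
# with one row per atom (columns: name, element, x, y, z, residue_index,
# residue_name, chain_id).  Multi-model trajectories are lists of such tables.

#' Build an atom table
#'
#' @param name Atom names (PDB convention, e.g. "N1", "C1'").
#' @param x,y,z Coordinates in Angstrom.
#' @param residue_index Integer residue identifiers.
#' @param residue_name Nucleotide codes (DA/DC/DG/DT or A/C/G/T).
#' @param chain_id Chain labels.
#' @param element Chemical elements; inferred from `name` when missing.
#' @return data.frame of class "atom_table".
#' @export
atom_table <- function(name, x, y, z, residue_index = 1L,
                       residue_name = "DA", chain_id = "A", element = NULL) {
  if (is.null(element)) element <- .element_from_name(name)
  pos <- cbind(x, y, z)
  if (!all(is.finite(pos))) stop("atom positions must be finite")
  df <- data.frame(
    name = as.character(name), element = as.character(element),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    residue_index = as.integer(residue_index),
    residue_name = as.character(residue_name),
    chain_id = as.character(chain_id),
    stringsAsFactors = FALSE
  )
  base_code(df$residue_name)  # validates residue names
  class(df) <- c("atom_table", "data.frame")
  df
}

.as_atom_table <- function(df) {
  class(df) <- c("atom_table", "data.frame")
  df
}

#' Coordinate matrix of an atom table
#' @param atoms An atom table.
#' @return n x 3 numeric matrix.
#' @export
coords <- function(atoms) {
  m <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(m) <- list(atoms$name, c("x", "y", "z"))
  m
}

.set_coords <- function(atoms, xyz) {
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

#' Select one residue from an atom table
#' @param atoms An atom table.
#' @param residue_index Residue number.
#' @param chain_id Optional chain label.
#' @return Atom table restricted to the residue.
#' @export
residue_atoms <- function(atoms, residue_index, chain_id = NULL) {
  keep <- atoms$residue_index == residue_index
  if (!is.null(chain_id)) keep <- keep & atoms$chain_id == chain_id
  out <- atoms[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("no atoms for residue ", residue_index,
         if (!is.null(chain_id)) paste0(" chain ", chain_id) else "")
  }
  .as_atom_table(out)
}

.atom_xyz <- function(atoms, name) {
  i <- which(atoms$name == name)
  if (length(i) == 0) stop("missing atom '", name, "' in residue ",
                           atoms$residue_index[1], " (", atoms$residue_name[1], ")")
  c(atoms$x[i[1]], atoms$y[i[1]], atoms$z[i[1]])
}

#' Apply a rigid-body transform to an atom table
#' @param atoms Atom table.
#' @param rotation 3x3 rotation matrix (applied as x %*% t(R)).
#' @param translation Length-3 shift, applied after rotation.
#' @return Transformed atom table.
#' @export
transform_atoms <- function(atoms, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- coords(atoms) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  .set_coords(atoms, xyz)
}
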