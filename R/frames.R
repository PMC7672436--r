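# Base reference frames: construction, least-squares fitting, and the
# syn transformation that keeps Opening/Shear meaningful for non-anti bases.

#' Construct a base reference frame
#'
#' A frame is an origin plus a right-handed orthonormal axis system.  The
#' `axes` matrix stores the x, y and z unit vectors as rows (laboratory
#' coordinates); the rotation taking frame-local coordinates to laboratory
#' coordinates is therefore `t(axes)`.
#'
#' @param origin Length-3 origin (Angstrom).
#' @param axes 3x3 matrix, rows = x, y, z unit vectors.
#' @param syn_transformed Logical: has the syn transformation been applied?
#' @return Object of class "base_frame".
#' @export
base_frame <- function(origin = c(0, 0, 0), axes = diag(3),
                       syn_transformed = FALSE) {
  if (!.is_rotation(t(axes))) {
    stop("frame axes must be orthonormal with determinant +1")
  }
  structure(list(origin = as.numeric(origin), axes = axes,
                 syn_transformed = isTRUE(syn_transformed)),
            class = "base_frame")
}

# local -> lab rotation matrix of a frame
.frame_rot <- function(frame) t(frame$axes)

.check_frame <- function(frame) {
  if (!inherits(frame, "base_frame")) stop("expected a base_frame")
  if (!.is_rotation(t(frame$axes))) stop("frame axes are not orthonormal")
  invisible(frame)
}

#' @export
print.base_frame <- function(x, ...) {
  cat("base_frame", if (x$syn_transformed) "(syn-transformed)" else "", "\n")
  cat("  origin:", sprintf("%.3f", x$origin), "\n")
  print(round(x$axes, 4))
  invisible(x)
}

# The fixed syn transformation: 180 degree rotation about the frame z-axis,
# composed on the right (about the frame's own axis) so that the y-axis of a
# syn base again points toward its pairing partner.
.SYN_ROT <- diag(c(-1, -1, 1))

#' Fit a base reference frame to observed coordinates
#'
#' Least-squares (Kabsch) superposition of the embedded standard reference
#' base onto the observed base ring heavy atoms.  For `orientation = "syn"`
#' the fitted standard frame is composed with a 180 degree rotation about the
#' frame z-axis and flagged, so that Opening and Shear of a pair involving a
#' syn base keep their geometric meaning.
#'
#' @param residue Atom table holding (at least) the base ring heavy atoms.
#' @param base_type Base code; default taken from the residue name.
#' @param orientation "anti" (default) or "syn".
#' @return A `base_frame`.
#' @export
fit_base_frame <- function(residue, base_type = NULL,
                           orientation = c("anti", "syn")) {
  orientation <- match.arg(orientation)
  if (is.null(base_type)) base_type <- residue$residue_name[1]
  base <- base_code(base_type)
  ring <- .RING_ATOMS[[base]]
  std <- .STD_BASE[[base]]
  obs <- matrix(NA_real_, length(ring), 3)
  for (i in seq_along(ring)) obs[i, ] <- .atom_xyz(residue, ring[i])
  fit <- .kabsch(std[ring, , drop = FALSE], obs)
  R <- fit$rotation
  if (orientation == "syn") R <- R %*% .SYN_ROT
  base_frame(origin = fit$translation, axes = t(R),
             syn_transformed = orientation == "syn")
}

#' Classify the glycosidic orientation of a nucleotide
#'
#' Computes the chi torsion (O4'-C1'-N9-C4 for purines, O4'-C1'-N1-C2 for
#' pyrimidines) and labels the residue syn when |chi| < 90 degrees, anti
#' otherwise.  Typical values are about -120 degrees (anti) and about +70
#' degrees (syn).
#'
#' @param residue Atom table with O4', C1' and the glycosidic base atoms.
#' @return List with `chi` (degrees, (-180, 180]) and `label` ("anti"/"syn").
#' @export
classify_glycosidic <- function(residue) {
  base <- base_code(residue$residue_name[1])
  at <- if (base %in% .PURINES) c("O4'", "C1'", "N9", "C4")
        else c("O4'", "C1'", "N1", "C2")
  p <- lapply(at, function(a) .atom_xyz(residue, a))
  chi <- dihedral4(p[[1]], p[[2]], p[[3]], p[[4]])
  list(chi = chi, label = if (abs(chi) < 90) "syn" else "anti")
}
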