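# Base-pair and step parameters via the hinge (mid-frame) decomposition, and
# its exact inverse used by the coordinate builder.

# 180 degree rotation about x: applied to the complementary-strand frame
# before combination (anti-parallel pairing convention).
.FLIP_X <- diag(c(1, -1, -1))

#' Base-pair parameter record
#' @param shear,stretch,stagger Translations in Angstrom.
#' @param buckle,propeller,opening Rotations in degrees.
#' @param simple Logical; TRUE for the simple (projection-based) scheme.
#' @return List of class "base_pair_params".
#' @export
base_pair_params <- function(shear = 0, stretch = 0, stagger = 0,
                             buckle = 0, propeller = 0, opening = 0,
                             simple = TRUE) {
  ang <- c(buckle = buckle, propeller = propeller, opening = opening)
  if (!all(is.finite(c(shear, stretch, stagger, ang)))) stop("non-finite parameter")
  structure(list(shear = shear, stretch = stretch, stagger = stagger,
                 buckle = wrap_angle(buckle), propeller = wrap_angle(propeller),
                 opening = wrap_angle(opening), simple = isTRUE(simple)),
            class = "base_pair_params")
}

#' Step parameter record
#' @param shift,slide,rise Translations in Angstrom.
#' @param tilt,roll,twist Rotations in degrees.
#' @return List of class "step_params".
#' @export
step_params <- function(shift = 0, slide = 0, rise = 3.38,
                        tilt = 0, roll = 0, twist = 36) {
  structure(list(shift = shift, slide = slide, rise = rise,
                 tilt = wrap_angle(tilt), roll = wrap_angle(roll),
                 twist = wrap_angle(twist)),
            class = "step_params")
}

# Core hinge decomposition of two frames (local->lab rotations R1, R2 and
# origins o1, o2) into a mid frame plus (about-x, about-y, about-z) rotations
# and mid-frame translations.  Exactly inverted by .compose_frames().
.decompose_frames <- function(R1, o1, R2, o2) {
  z1 <- R1[, 3]; z2 <- R2[, 3]
  cg <- max(-1, min(1, sum(z1 * z2)))
  gamma <- .rad2deg(acos(cg))
  if (gamma > 179) stop("frames are anti-aligned; decomposition undefined")
  cr <- pracma_cross(z1, z2)
  if (gamma > 1e-10 && .vnorm(cr) > 1e-12) {
    hinge <- .unit(cr)
    R1p <- rotation_about(hinge, +gamma / 2) %*% R1
    R2p <- rotation_about(hinge, -gamma / 2) %*% R2
  } else {
    hinge <- NULL
    R1p <- R1; R2p <- R2
  }
  zm <- .unit(R1p[, 3] + R2p[, 3])
  twist <- .signed_angle_about(R1p[, 2], R2p[, 2], zm)
  ym <- .unit(R1p[, 2] + R2p[, 2])
  # guard: ym must be orthogonal to zm (it is, both y's are in-plane)
  ym <- .unit(ym - sum(ym * zm) * zm)
  xm <- pracma_cross(ym, zm)
  Rm <- cbind(xm, ym, zm)
  if (is.null(hinge)) {
    rot_x <- 0; rot_y <- 0
  } else {
    hm <- as.vector(t(Rm) %*% hinge)
    hxy <- .unit(c(hm[1], hm[2], 0))
    rot_x <- gamma * hxy[1]
    rot_y <- gamma * hxy[2]
  }
  d <- as.vector(t(Rm) %*% (o2 - o1))
  list(Rm = Rm, om = (o1 + o2) / 2, d = d,
       rot_x = rot_x, rot_y = rot_y, rot_z = twist)
}

# Inverse of .decompose_frames: given the mid frame, rotations and
# translations, reconstruct the two frames.
.compose_frames <- function(Rm, om, d, rot_x, rot_y, rot_z) {
  gamma <- sqrt(rot_x^2 + rot_y^2)
  if (gamma > 1e-12) {
    h <- c(rot_x, rot_y, 0) / gamma
    B1 <- rotation_about(h, -gamma / 2)
    B2 <- rotation_about(h, +gamma / 2)
  } else {
    B1 <- diag(3); B2 <- diag(3)
  }
  R1m <- B1 %*% .rot_z(-rot_z / 2)
  R2m <- B2 %*% .rot_z(+rot_z / 2)
  dl <- as.vector(Rm %*% d)
  list(R1 = Rm %*% R1m, o1 = om - dl / 2,
       R2 = Rm %*% R2m, o2 = om + dl / 2)
}

#' Compute simple base-pair parameters from two base frames
#'
#' The complementary-strand frame (`frame_b`) is flipped 180 degrees about
#' its own x-axis, a mid frame is constructed by the hinge decomposition,
#' and the six parameters are read off: translations are the components of
#' the inter-origin vector (b minus a) in the mid frame; Opening is the
#' signed angle between the two y-axes about the mid-frame normal; Buckle
#' and Propeller are the x/y components of the residual hinge rotation.
#' Negative Opening corresponds to motion of the glycosidic edge toward the
#' minor groove.
#'
#' @param frame_a Frame of the strand-I base.
#' @param frame_b Frame of the complementary base (unflipped).
#' @return List with `mean_frame` (a `base_frame`) and `params`
#'   (a `base_pair_params` with `simple = TRUE`).
#' @export
pair_frames <- function(frame_a, frame_b) {
  .check_frame(frame_a); .check_frame(frame_b)
  R1 <- .frame_rot(frame_a)
  R2 <- .frame_rot(frame_b) %*% .FLIP_X
  dec <- .decompose_frames(R1, frame_a$origin, R2, frame_b$origin)
  list(
    mean_frame = base_frame(origin = dec$om, axes = t(dec$Rm)),
    params = base_pair_params(
      shear = dec$d[1], stretch = dec$d[2], stagger = dec$d[3],
      buckle = dec$rot_x, propeller = dec$rot_y, opening = dec$rot_z,
      simple = TRUE
    )
  )
}

#' Compute base-pair step parameters from two consecutive pair mean frames
#'
#' Same mid-frame algebra as [pair_frames()] without the x-flip.
#'
#' @param pair1_mean_frame,pair2_mean_frame Mean frames of consecutive pairs.
#' @return A `step_params` record.
#' @export
compute_step_params <- function(pair1_mean_frame, pair2_mean_frame) {
  .check_frame(pair1_mean_frame); .check_frame(pair2_mean_frame)
  dec <- .decompose_frames(.frame_rot(pair1_mean_frame), pair1_mean_frame$origin,
                           .frame_rot(pair2_mean_frame), pair2_mean_frame$origin)
  step_params(shift = dec$d[1], slide = dec$d[2], rise = dec$d[3],
              tilt = dec$rot_x, roll = dec$rot_y, twist = dec$rot_z)
}

# Given a pair mean frame and pair parameters, return the two base frames
# (frame_b unflipped, i.e. as it would be fitted on the complementary base).
.pair_to_frames <- function(mean_frame, params) {
  comp <- .compose_frames(.frame_rot(mean_frame), mean_frame$origin,
                          c(params$shear, params$stretch, params$stagger),
                          params$buckle, params$propeller, params$opening)
  list(frame_a = base_frame(origin = comp$o1, axes = t(comp$R1)),
       frame_b = base_frame(origin = comp$o2, axes = t(comp$R2 %*% .FLIP_X)))
}

# Propagate a pair mean frame through step parameters to the next pair
# mean frame.
.step_frame <- function(mean_frame, step) {
  Rm0 <- .frame_rot(mean_frame)
  gamma <- sqrt(step$tilt^2 + step$roll^2)
  if (gamma > 1e-12) {
    h <- c(step$tilt, step$roll, 0) / gamma
    B1 <- rotation_about(h, -gamma / 2)
    B2 <- rotation_about(h, +gamma / 2)
  } else {
    B1 <- diag(3); B2 <- diag(3)
  }
  R1m <- B1 %*% .rot_z(-step$twist / 2)
  R2m <- B2 %*% .rot_z(+step$twist / 2)
  # mean_frame plays the role of frame 1: R1 = Rmid %*% R1m  =>  Rmid = R1 %*% t(R1m)
  Rmid <- Rm0 %*% t(R1m)
  R2 <- Rmid %*% R2m
  d <- c(step$shift, step$slide, step$rise)
  o2 <- mean_frame$origin + as.vector(Rmid %*% d)
  base_frame(origin = o2, axes = t(R2))
}
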