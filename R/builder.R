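# Idealized B-DNA coordinate builder: the exact inverse of the frame /
# parameter algebra in pair-params.R, using the embedded standard bases.

.CHI_DEFAULT <- c(anti = -120, syn = 70)

# Place atom D bonded to C with bond length r, angle(B-C-D) = theta_deg and
# dihedral(A,B,C,D) = phi_deg (natural extension of internal coordinates).
.nerf_place <- function(A, B, C, r, theta_deg, phi_deg) {
  th <- .deg2rad(theta_deg); ph <- .deg2rad(phi_deg)
  bc <- .unit(C - B)
  ab <- .unit(B - A)
  n <- .unit(pracma_cross(ab, bc))
  m <- pracma_cross(n, bc)
  C + r * (-cos(th) * bc + sin(th) * (cos(ph) * m - sin(ph) * n))
}

# Standard-frame atom placement for one base given its *measured* frame
# (i.e. the frame fit_base_frame() would return, including the syn
# transformation when orientation == "syn").
.place_base <- function(base, frame, orientation = "anti",
                        residue_index = 1L, chain_id = "A",
                        chi = NULL) {
  base <- base_code(base)
  R <- .frame_rot(frame)
  if (orientation == "syn") R <- R %*% .SYN_ROT  # undo the syn transform
  std <- .STD_BASE[[base]]
  xyz <- std %*% t(R)
  xyz <- sweep(xyz, 2, frame$origin, "+")
  at <- atom_table(name = rownames(std), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   residue_index = residue_index,
                   residue_name = paste0("D", base), chain_id = chain_id)
  # O4' closes the glycosidic torsion so chi is well-defined on built output.
  if (is.null(chi)) chi <- .CHI_DEFAULT[[orientation]]
  gly <- if (base %in% .PURINES) c("C4", "N9") else c("C2", "N1")
  o4 <- .nerf_place(.atom_xyz(at, gly[1]), .atom_xyz(at, gly[2]),
                    .atom_xyz(at, "C1'"), r = 1.42, theta_deg = 108,
                    phi_deg = chi)
  rbind_atoms(at, atom_table(name = "O4'", x = o4[1], y = o4[2], z = o4[3],
                             residue_index = residue_index,
                             residue_name = paste0("D", base),
                             chain_id = chain_id))
}

#' Concatenate atom tables
#' @param ... Atom tables.
#' @return Combined atom table.
#' @export
rbind_atoms <- function(...) {
  .as_atom_table(do.call(rbind, lapply(list(...), as.data.frame)))
}

#' Build one base pair at prescribed simple parameters
#'
#' Exact inverse of [pair_frames()]: places the two standard bases so that
#' refitting their frames and recombining them reproduces the requested
#' parameters to machine precision.
#'
#' @param base_a Base on strand I ("A", "C", "G" or "T").
#' @param params A `base_pair_params` record (default: ideal Watson-Crick).
#' @param base_b Complementary-strand base; defaults to the WC complement.
#' @param orientations Length-2 character vector over "anti"/"syn" for the
#'   two bases.
#' @param mean_frame Placement of the pair mean frame (default: identity).
#' @param residue_index Length-2 residue numbers.
#' @param chain_id Length-2 chain labels.
#' @return Atom table with the two residues.
#' @export
build_base_pair <- function(base_a, params = base_pair_params(),
                            base_b = NULL,
                            orientations = c("anti", "anti"),
                            mean_frame = base_frame(),
                            residue_index = c(1L, 2L),
                            chain_id = c("A", "B")) {
  base_a <- base_code(base_a)
  if (is.null(base_b)) base_b <- .WC_COMPLEMENT[[base_a]]
  fr <- .pair_to_frames(mean_frame, params)
  rbind_atoms(
    .place_base(base_a, fr$frame_a, orientations[1], residue_index[1], chain_id[1]),
    .place_base(base_b, fr$frame_b, orientations[2], residue_index[2], chain_id[2])
  )
}

#' Measure the simple parameters of one base pair in a structure
#'
#' Fits frames to the two residues (with the syn transformation applied to
#' residues classified, or declared, as syn) and combines them.
#'
#' @param atoms Atom table.
#' @param res_a,res_b Residue indices of the strand-I and complementary base.
#' @param orientations Length-2 over "anti"/"syn", or NULL to classify from
#'   the chi torsion (requires O4' atoms).
#' @return As [pair_frames()].
#' @export
measure_pair <- function(atoms, res_a, res_b, orientations = NULL) {
  ra <- residue_atoms(atoms, res_a)
  rb <- residue_atoms(atoms, res_b)
  if (is.null(orientations)) {
    orientations <- c(classify_glycosidic(ra)$label, classify_glycosidic(rb)$label)
  }
  fa <- fit_base_frame(ra, orientation = orientations[1])
  fb <- fit_base_frame(rb, orientation = orientations[2])
  pair_frames(fa, fb)
}

#' Build an idealized B-DNA duplex
#'
#' Generates the complementary strand, then stacks base pairs along the helix
#' by propagating pair mean frames through the step parameters (fiber B-DNA
#' defaults: twist 36 degrees, rise 3.38 Angstrom) and placing each pair at
#' its base-pair parameters (default: ideal Watson-Crick, all zero).
#'
#' Chain A holds residues 1..n (5'->3'); chain B residues n+1..2n (5'->3'),
#' so pair i couples residue i with residue 2n+1-i.
#'
#' @param sequence Character string over A/C/G/T (strand I, 5'->3').
#' @param step A `step_params` record applied to every step, or a list of
#'   n-1 records.
#' @param pair_params A single `base_pair_params` for all pairs, or a list of
#'   n records.
#' @return Atom table with 2n residues on chains A and B.
#' @export
build_duplex <- function(sequence, step = step_params(),
                         pair_params = base_pair_params()) {
  seq_a <- strsplit(toupper(sequence), "")[[1]]
  if (!all(seq_a %in% c("A", "C", "G", "T"))) {
    stop("sequence must be over A/C/G/T, got: ", sequence)
  }
  n <- length(seq_a)
  if (inherits(step, "step_params")) step <- rep(list(step), max(n - 1, 0))
  if (inherits(pair_params, "base_pair_params")) pair_params <- rep(list(pair_params), n)
  stopifnot(length(step) == n - 1, length(pair_params) == n)
  frames <- vector("list", n)
  frames[[1]] <- base_frame()
  for (i in seq_len(n - 1)) frames[[i + 1]] <- .step_frame(frames[[i]], step[[i]])
  parts_a <- vector("list", n); parts_b <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- .pair_to_frames(frames[[i]], pair_params[[i]])
    j <- 2L * n + 1L - i
    parts_a[[i]] <- .place_base(seq_a[i], fr$frame_a, "anti", i, "A")
    parts_b[[j - n]] <- .place_base(.WC_COMPLEMENT[[seq_a[i]]], fr$frame_b,
                                    "anti", j, "B")
  }
  do.call(rbind_atoms, c(parts_a, parts_b))
}

#' Residue indices of the central base pair of a built duplex
#' @param atoms Atom table from [build_duplex()].
#' @return Length-2 integer vector (strand I residue, partner residue).
#' @export
central_pair_indices <- function(atoms) {
  n2 <- length(unique(atoms$residue_index))
  if (n2 %% 2 != 0) stop("duplex must have an even residue count")
  n <- n2 %/% 2
  i <- (n + 1L) %/% 2L + (n %% 2L == 0L)  # exact center for odd n
  c(i, 2L * n + 1L - i)
}

#' Rebuild the central pair of a duplex at requested Opening and Shear
#'
#' Only the two central residues are touched; the pair's current mean frame
#' and its remaining four parameters are preserved, so `(0, 0)` on a default
#' duplex is the identity.
#'
#' @param duplex Atom table from [build_duplex()].
#' @param opening Requested simple Opening (degrees).
#' @param shear Requested simple Shear (Angstrom).
#' @return Modified atom table.
#' @export
perturb_central_pair <- function(duplex, opening = 0, shear = 0) {
  idx <- central_pair_indices(duplex)
  ra <- residue_atoms(duplex, idx[1]); rb <- residue_atoms(duplex, idx[2])
  ori <- c(classify_glycosidic(ra)$label, classify_glycosidic(rb)$label)
  mp <- measure_pair(duplex, idx[1], idx[2], orientations = ori)
  p <- mp$params
  p$opening <- wrap_angle(opening); p$shear <- shear
  fr <- .pair_to_frames(mp$mean_frame, p)
  chi_a <- classify_glycosidic(ra)$chi; chi_b <- classify_glycosidic(rb)$chi
  new_a <- .place_base(base_code(ra$residue_name[1]), fr$frame_a, ori[1],
                       idx[1], ra$chain_id[1], chi = chi_a)
  new_b <- .place_base(base_code(rb$residue_name[1]), fr$frame_b, ori[2],
                       idx[2], rb$chain_id[1], chi = chi_b)
  out <- duplex
  for (res in list(new_a, new_b)) {
    for (k in seq_len(nrow(res))) {
      sel <- out$residue_index == res$residue_index[k] & out$name == res$name[k]
      out$x[sel] <- res$x[k]; out$y[sel] <- res$y[k]; out$z[sel] <- res$z[k]
    }
  }
  out
}

#' Simple base-pair parameters of every pair in a duplex
#'
#' @param duplex Atom table from [build_duplex()] (or compatible numbering).
#' @param orientations NULL to classify per residue from chi.
#' @return data.frame: pair_index, shear, stretch, stagger, buckle,
#'   propeller, opening, scheme.
#' @export
duplex_pair_params <- function(duplex, orientations = NULL) {
  n <- length(unique(duplex$residue_index)) %/% 2
  rows <- lapply(seq_len(n), function(i) {
    p <- measure_pair(duplex, i, 2L * n + 1L - i, orientations = orientations)$params
    data.frame(pair_index = i, shear = p$shear, stretch = p$stretch,
               stagger = p$stagger, buckle = p$buckle, propeller = p$propeller,
               opening = p$opening, scheme = if (p$simple) "simple" else "standard")
  })
  do.call(rbind, rows)
}
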