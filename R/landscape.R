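# Free-energy surface analysis: minima, thermodynamic states, reduction to
# 1D opening profiles, propensities and the discrimination gap.

# Neighbors of a linear bin index under the 8-neighborhood with periodic
# wrapping; NULL entries dropped.  Returns integer vector.
.neighbors <- function(spec, idx) {
  if (spec$dims == 1) {
    i <- idx
    out <- c(i - 1L, i + 1L)
    n <- spec$nbins[1]
    if (spec$periodic[1]) out <- ((out - 1L) %% n) + 1L
    out[out >= 1L & out <= n]
  } else {
    n1 <- spec$nbins[1]; n2 <- spec$nbins[2]
    i <- ((idx - 1L) %% n1) + 1L
    j <- ((idx - 1L) %/% n1) + 1L
    res <- integer(0)
    for (dj in -1:1) for (di in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (spec$periodic[1]) ii <- ((ii - 1L) %% n1) + 1L
      if (spec$periodic[2]) jj <- ((jj - 1L) %% n2) + 1L
      if (ii >= 1L && ii <= n1 && jj >= 1L && jj <= n2) {
        res <- c(res, (jj - 1L) * n1 + ii)
      }
    }
    unique(res)
  }
}

.is_boundary_bin <- function(spec, idx) {
  if (spec$dims == 1) {
    if (spec$periodic[1]) return(FALSE)
    idx == 1L | idx == spec$nbins[1]
  } else {
    n1 <- spec$nbins[1]
    i <- ((idx - 1L) %% n1) + 1L
    j <- ((idx - 1L) %/% n1) + 1L
    b <- rep(FALSE, length(idx))
    if (!spec$periodic[1]) b <- b | i == 1L | i == n1
    if (!spec$periodic[2]) b <- b | j == 1L | j == spec$nbins[2]
    b
  }
}

#' Find free-energy minima (thermodynamic-state candidates)
#'
#' Local minima are bins strictly lower than all unmasked 8-neighbors
#' (periodic wrap where applicable).  Shallow minima are pruned by
#' topological persistence: flooding the surface from below, a minimum whose
#' basin merges into a deeper one across a barrier lower than `min_depth`
#' is discarded.  Pure boundary minima on non-periodic edges are excluded
#' unless `include_boundary` is set.
#'
#' @param surface A `fe_surface` referenced to min = 0.
#' @param min_depth Pruning barrier in kcal/mol (default 0.5).
#' @param include_boundary Keep minima on non-periodic grid edges.
#' @return List of state stubs sorted ascending by value and labeled 1..K:
#'   each has `label`, `bin`, `location`, `value`.
#' @export
find_minima <- function(surface, min_depth = 0.5, include_boundary = FALSE) {
  spec <- surface$spec
  val <- surface$value
  ok <- !surface$mask
  ord <- order(val)
  ord <- ord[ok[ord]]
  parent <- seq_along(val)      # union-find
  comp_min <- integer(length(val))   # representative minimum bin per root
  persists <- logical(length(val))
  alive <- logical(length(val))      # processed?
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (b in ord) {
    nb <- .neighbors(spec, b)
    nb <- nb[alive[nb]]
    alive[b] <- TRUE
    if (length(nb) == 0) {
      comp_min[b] <- b
      next
    }
    roots <- unique(vapply(nb, find, integer(1)))
    # attach to the deepest (oldest) component
    births <- val[comp_min[roots]]
    main <- roots[which.min(births)]
    parent[b] <- main
    for (r in roots) {
      if (r == main) next
      # component r dies here; persistence = barrier height above its minimum
      if (val[b] - val[comp_min[r]] >= min_depth) persists[comp_min[r]] <- TRUE
      parent[r] <- main
    }
  }
  processed <- which(alive)
  if (length(processed) > 0) {
    global_root <- find(processed[which.min(val[processed])])
    persists[comp_min[global_root]] <- TRUE
  }
  cand <- which(persists)
  # require genuine local minimality against unmasked neighbors
  is_locmin <- vapply(cand, function(b) {
    nb <- .neighbors(spec, b)
    nb <- nb[!surface$mask[nb]]
    length(nb) > 0 && all(val[b] < val[nb])
  }, logical(1))
  cand <- cand[is_locmin]
  if (!include_boundary) cand <- cand[!.is_boundary_bin(spec, cand)]
  cand <- cand[order(val[cand])]
  centers <- .all_centers(spec)
  lapply(seq_along(cand), function(k) {
    list(label = k, bin = cand[k],
         location = as.numeric(centers[cand[k], ]),
         value = val[cand[k]])
  })
}

# Steepest-descent basin assignment: every bin maps to the bin index of the
# local minimum reached by repeatedly stepping to the lowest unmasked
# neighbor (ties broken by lowest bin index).
.basin_map <- function(surface) {
  spec <- surface$spec
  val <- surface$value
  val[surface$mask] <- Inf
  B <- length(val)
  dest <- integer(B)
  for (b in seq_len(B)) {
    if (!is.finite(val[b])) { dest[b] <- NA_integer_; next }
    cur <- b
    path <- integer(0)
    repeat {
      if (dest[cur] != 0L && !is.na(dest[cur])) { target <- dest[cur]; break }
      path <- c(path, cur)
      nb <- .neighbors(spec, cur)
      nb <- nb[is.finite(val[nb])]
      low <- nb[val[nb] < val[cur]]
      if (length(low) == 0) { target <- cur; break }
      cur <- min(low[val[low] == min(val[low])])
    }
    dest[path] <- target
  }
  dest[!is.finite(val)] <- NA_integer_
  dest
}

#' Extract a thermodynamic state around a free-energy minimum
#'
#' Members are trajectory frames whose bin lies in the minimum's
#' steepest-descent basin and whose free energy is at most `threshold` above
#' the minimum (default 0.5RT at 300 K = 0.298 kcal/mol).  When trajectory
#' coordinates are supplied, a representative structure is computed as the
#' arithmetic average of the member frames after superposing each onto the
#' first member (no force-field regularization).
#'
#' @param surface A referenced `fe_surface`.
#' @param cv_values Matrix/data.frame of per-frame CV values (d columns).
#' @param minimum A state stub from [find_minima()].
#' @param threshold Energy window above the minimum, kcal/mol.
#' @param trajectory Optional list of atom tables parallel to `cv_values`.
#' @return Object of class "thermo_state": label, location, value,
#'   member_frames, n_members, representative (atom table or NULL).
#' @export
extract_state <- function(surface, cv_values, minimum,
                          threshold = 0.5 * rt_kcal(300), trajectory = NULL) {
  cv_values <- as.matrix(as.data.frame(cv_values)[,
                 setdiff(colnames(as.data.frame(cv_values)), c("frame", "frame_index")),
                 drop = FALSE])
  stopifnot(ncol(cv_values) == surface$spec$dims)
  basins <- .basin_map(surface)
  bins <- .bin_index(surface$spec, cv_values)
  inside <- !is.na(bins)
  memb <- which(inside &
                  basins[ifelse(is.na(bins), 1L, bins)] == minimum$bin &
                  surface$value[ifelse(is.na(bins), 1L, bins)] <=
                    minimum$value + threshold)
  if (length(memb) == 0) {
    warning("empty state: no trajectory frames within the window")
  }
  rep_struct <- NULL
  if (!is.null(trajectory) && length(memb) > 0) {
    ref <- trajectory[[memb[1]]]
    ref_heavy <- ref[ref$element != "H", , drop = FALSE]
    acc <- coords(ref_heavy) * 0
    for (i in memb) {
      fr <- trajectory[[i]]
      fr <- fr[fr$element != "H", , drop = FALSE]
      fit <- .kabsch(coords(fr), coords(ref_heavy))
      acc <- acc + sweep(coords(fr) %*% t(fit$rotation), 2, fit$translation, "+")
    }
    rep_struct <- .set_coords(.as_atom_table(ref_heavy), acc / length(memb))
  }
  structure(list(label = minimum$label, bin = minimum$bin,
                 location = minimum$location, value = minimum$value,
                 member_frames = memb, n_members = length(memb),
                 representative = rep_struct, threshold = threshold),
            class = "thermo_state")
}

#' Reduce a 2D free-energy surface to a 1D profile by Boltzmann averaging
#'
#' DG_w(x) = -RT ln sum_y exp(-DG_r(x, y)/RT) w_y, evaluated by composite
#' trapezoid over the integrated dimension with a log-sum-exp, then
#' re-referenced to min = 0.  Uncertainty is propagated by the delta method
#' with normalized Boltzmann weights: stderr(x) = sqrt(sum_y w^2 stderr^2)
#' (stderrs stay on the 3-sigma scale throughout).
#'
#' @param surface A 2D `fe_surface`.
#' @param axis Dimension kept (1 or 2); the other is integrated out.
#' @param temperature Kelvin (default 300).
#' @return Object of class "fe_profile": axis, centers, value, stderr, mask,
#'   temperature.
#' @export
reduce_profile <- function(surface, axis = 1L, temperature = 300) {
  spec <- surface$spec
  if (spec$dims != 2) stop("reduce_profile needs a 2D surface")
  other <- 3L - axis
  RT <- rt_kcal(temperature)
  n_keep <- spec$nbins[axis]; n_int <- spec$nbins[other]
  V <- matrix(surface$value, spec$nbins[1], spec$nbins[2])
  S <- matrix(surface$stderr, spec$nbins[1], spec$nbins[2])
  M <- matrix(surface$mask, spec$nbins[1], spec$nbins[2])
  if (axis == 2L) { V <- t(V); S <- t(S); M <- t(M) }
  dy <- .bin_width(spec, other)
  wtrap <- rep(dy, n_int)
  if (!spec$periodic[other]) { wtrap[1] <- dy / 2; wtrap[n_int] <- dy / 2 }
  val <- numeric(n_keep); se <- numeric(n_keep); msk <- logical(n_keep)
  for (i in seq_len(n_keep)) {
    ok <- !M[i, ]
    if (!any(ok)) { msk[i] <- TRUE; val[i] <- NA_real_; se[i] <- NA_real_; next }
    a <- -V[i, ok] / RT + log(wtrap[ok])
    amax <- max(a)
    lse <- amax + log(sum(exp(a - amax)))
    val[i] <- -RT * lse
    w <- exp(a - lse)                     # normalized Boltzmann weights
    se[i] <- sqrt(sum((w * S[i, ok])^2))
  }
  prof <- structure(list(
    axis = spec$names[axis],
    centers = bin_centers(spec, axis),
    value = val, stderr = se, mask = msk,
    temperature = temperature,
    periodic = spec$periodic[axis]
  ), class = "fe_profile")
  reference_to_min(prof)
}

#' Sub-bin location of a profile's minimum
#'
#' Parabolic (three-point) interpolation around the lowest unmasked bin;
#' falls back to the bin center at the axis ends.
#'
#' @param profile A `fe_profile`.
#' @return Axis location of the interpolated minimum.
#' @export
profile_min_location <- function(profile) {
  ok <- which(!profile$mask)
  i <- ok[which.min(profile$value[ok])]
  if (i <= 1L || i >= length(profile$centers) ||
      profile$mask[i - 1L] || profile$mask[i + 1L]) {
    return(profile$centers[i])
  }
  y0 <- profile$value[i - 1L]; y1 <- profile$value[i]; y2 <- profile$value[i + 1L]
  denom <- y0 - 2 * y1 + y2
  if (denom <= 0) return(profile$centers[i])
  off <- 0.5 * (y0 - y2) / denom
  profile$centers[i] + off * (profile$centers[i + 1L] - profile$centers[i])
}

#' Shift a profile axis to relative Opening
#'
#' Re-expresses the profile on delta-sigma' = sigma' - sigma'(global
#' minimum); values are unchanged.
#'
#' @param profile A `fe_profile`.
#' @param reference Opening of the reference (global-minimum) state, same
#'   units as the axis.
#' @return The shifted profile (axis renamed with a "delta_" prefix once).
#' @export
relative_opening <- function(profile, reference) {
  rng <- range(profile$centers)
  if (reference < rng[1] || reference > rng[2]) {
    stop("reference ", reference, " outside the profile axis range")
  }
  profile$centers <- profile$centers - reference
  if (!startsWith(profile$axis, "delta_")) {
    profile$axis <- paste0("delta_", profile$axis)
  }
  profile
}

#' Interpolate a profile value (propensity) at a point
#'
#' Linear interpolation between the two adjacent bin centers; the standard
#' error is interpolated the same way.
#'
#' @param profile A `fe_profile`.
#' @param at Evaluation point on the profile axis (default -60 degrees, the
#'   average experimental opening into the minor groove).
#' @return List with `value` and `stderr` (kcal/mol, stderr at 3 sigma).
#' @export
propensity_at <- function(profile, at = -60) {
  x <- profile$centers
  if (at < min(x) || at > max(x)) stop("evaluation point outside axis range")
  hi <- which(x >= at)[1]
  if (x[hi] == at) {
    if (profile$mask[hi]) stop("evaluation point falls in a masked region")
    return(list(value = profile$value[hi], stderr = profile$stderr[hi], at = at))
  }
  lo <- hi - 1L
  if (lo < 1L) { lo <- hi; hi <- hi + 1L }
  if (profile$mask[lo] || profile$mask[hi]) {
    stop("evaluation point falls in a masked region")
  }
  t <- (at - x[lo]) / (x[hi] - x[lo])
  list(value = (1 - t) * profile$value[lo] + t * profile$value[hi],
       stderr = (1 - t) * profile$stderr[lo] + t * profile$stderr[hi],
       at = at)
}

#' Discrimination gap between canonical and mismatched opening propensities
#'
#' gap = canonical - mismatch, with the standard errors combined in
#' quadrature.  When several canonical propensities are supplied the
#' threshold variant min(canonical) is used.
#'
#' @param canonical A propensity (list with value/stderr) or list of them.
#' @param mismatch A single propensity.
#' @param delta_sigma Evaluation point annotation (degrees).
#' @return Object of class "gap_result": canonical, mismatch, gap, stderr,
#'   delta_sigma.
#' @export
discrimination_gap <- function(canonical, mismatch, delta_sigma = -60) {
  if (!is.null(canonical$value)) canonical <- list(canonical)
  vals <- vapply(canonical, function(p) p$value, numeric(1))
  errs <- vapply(canonical, function(p) p$stderr, numeric(1))
  k <- which.min(vals)
  structure(list(
    canonical = vals[k], canonical_stderr = errs[k],
    mismatch = mismatch$value, mismatch_stderr = mismatch$stderr,
    gap = vals[k] - mismatch$value,
    stderr = sqrt(errs[k]^2 + mismatch$stderr^2),
    delta_sigma = delta_sigma
  ), class = "gap_result")
}

#' @export
print.gap_result <- function(x, ...) {
  cat(sprintf("discrimination gap at delta-sigma' = %g: %.2f +/- %.2f kcal/mol\n",
              x$delta_sigma, x$gap, x$stderr))
  cat(sprintf("  canonical %.2f +/- %.2f | mismatch %.2f +/- %.2f\n",
              x$canonical, x$canonical_stderr, x$mismatch, x$mismatch_stderr))
  invisible(x)
}

#' Harmonic (Hookean) stiffness of a bending profile
#'
#' Weighted least-squares fit of DG = 0.5 k (alpha - alpha0)^2 over the
#' stated linear-elastic range; the fit is invariant to the profile's
#' additive reference because the quadratic is fit with a free constant.
#'
#' @param profile A `fe_profile` over the bending angle (degrees).
#' @param range Fit window, degrees (default c(130, 170)).
#' @return List with `k` (kcal/mol/deg^2), `alpha0` (deg), `n_bins`.
#' @export
fit_elastic_constant <- function(profile, range = c(130, 170)) {
  sel <- which(profile$centers >= range[1] & profile$centers <= range[2] &
                 !profile$mask)
  if (length(sel) < 5) stop("need >= 5 unmasked bins in the fit range")
  x <- profile$centers[sel]; y <- profile$value[sel]
  w <- profile$stderr[sel]
  w <- if (all(is.finite(w)) && all(w > 0)) 1 / w^2 else rep(1, length(sel))
  fit <- stats::lm(y ~ x + I(x^2), weights = w)
  a <- stats::coef(fit)[["I(x^2)"]]; b <- stats::coef(fit)[["x"]]
  k <- 2 * a
  if (k <= 0) warning("non-convex bending data: fitted k <= 0 (k = ",
                      signif(k, 3), ")")
  list(k = k, alpha0 = -b / (2 * a), n_bins = length(sel))
}

#' Project structures onto a free-energy surface
#'
#' Computes the simple Opening/Shear of the central pair of each structure
#' and reports the surface value at that location.
#'
#' @param surface A `fe_surface` over (Opening, Shear).
#' @param structures List of atom tables containing the central pair.
#' @param res_pairs List of length-2 residue-index vectors (default: the
#'   central pair of a built duplex).
#' @param orientations Per-structure orientations, or NULL to classify.
#' @return data.frame: opening, shear, value, masked, in_domain.
#' @export
overlay_structures <- function(surface, structures, res_pairs = NULL,
                               orientations = NULL) {
  rows <- lapply(seq_along(structures), function(i) {
    st <- structures[[i]]
    rp <- if (is.null(res_pairs)) central_pair_indices(st) else res_pairs[[i]]
    p <- measure_pair(st, rp[1], rp[2], orientations = orientations)$params
    bi <- .bin_index(surface$spec, matrix(c(p$opening, p$shear), 1))
    if (is.na(bi)) {
      data.frame(opening = p$opening, shear = p$shear, value = NA_real_,
                 masked = NA, in_domain = FALSE)
    } else {
      data.frame(opening = p$opening, shear = p$shear,
                 value = surface$value[bi], masked = surface$mask[bi],
                 in_domain = TRUE)
    }
  })
  do.call(rbind, rows)
}
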