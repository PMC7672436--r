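# Analytic model free-energy surfaces used in place of force-field
# landscapes: a bowl (optionally asymmetric along the Opening axis) plus
# Gaussian wells.  All archetypes share this one functional family so the
# sampler, the analytic gradient and the brute-force oracles agree:
#
#   V(x, y) = cx (x - x0)^2 A(x) + cy (y - y0)^2
#             - sum_i d_i exp(-((x - xi)^2 / (2 wxi^2) + (y - yi)^2 / (2 wyi^2)))
#   A(x)    = 1 + a (1 - tanh((x - x0)/tau)) / 2
#
# x is Opening (degrees), y is Shear (Angstrom); V in kcal/mol.

.surface_params <- function(archetype, dims) {
  wells <- function(...) {
    nm <- c("x", "y", "depth", "wx", "wy")
    if (...length() == 0) return(matrix(numeric(0), 0, 5, dimnames = list(NULL, nm)))
    m <- rbind(...)
    colnames(m) <- nm
    m
  }
  switch(archetype,
    quadratic = list(dims = dims, x0 = 0, y0 = 0, cx = 0.5, cy = 0.5,
                     asym = 0, tau = 1,
                     wells = wells()[0, , drop = FALSE],
                     domain = if (dims == 1) list(mins = -4, maxs = 4)
                              else list(mins = c(-4, -4), maxs = c(4, 4))),
    double_well = list(dims = dims, x0 = 0, y0 = 0, cx = 0.3,
                       cy = if (dims == 2) 0.5 else 0,
                       asym = 0, tau = 1,
                       wells = wells(c(-1.5, 0, 4, 0.5, 0.6),
                                     c( 1.5, 0, 4, 0.5, 0.6)),
                       domain = if (dims == 1) list(mins = -3.2, maxs = 3.2)
                                else list(mins = c(-3.2, -2.5), maxs = c(3.2, 2.5))),
    canonical_like = list(dims = 2, x0 = 0, y0 = 0, cx = 0.0012, cy = 0.6,
                          asym = 1.2, tau = 25,
                          wells = wells(c(0, 0, 6, 12, 0.5)),
                          domain = list(mins = c(-120, -3.5), maxs = c(90, 3.5))),
    mismatch_like = list(dims = 2, x0 = 0, y0 = 0, cx = 0.0006, cy = 0.5,
                         asym = 0, tau = 25,
                         wells = wells(c(  0,  0.0, 5.4, 10, 0.45),
                                       c(-30,  1.6, 3.2, 10, 0.45),
                                       c( 30,  1.6, 2.8, 10, 0.45),
                                       c(-65, -0.9, 2.6, 10, 0.45),
                                       c( 50, -1.2, 2.4, 10, 0.45)),
                         domain = list(mins = c(-120, -3.5), maxs = c(90, 3.5))),
    stop("unknown archetype: ", archetype)
  )
}

#' Construct an analytic model free-energy surface
#'
#' Archetypes: "quadratic" (harmonic bowl), "double_well" (two Gaussian
#' wells in a bowl), "canonical_like" (one deep anharmonic basin, steeper
#' toward negative Opening, i.e. the minor groove), "mismatch_like" (five
#' Gaussian-well basins whose Shear-separated groups are divided by a
#' barrier of roughly 5.4 kcal/mol above the global minimum), or "custom"
#' (pass the parameter list yourself).
#'
#' @param archetype Archetype name.
#' @param dims 1 or 2 (only "quadratic" and "double_well" support 1).
#' @param parameters Named overrides of the archetype parameter list
#'   (cx, cy, x0, y0, asym, tau, wells, domain).
#' @return Object of class "model_surface" with vectorized `V(x, y)` and
#'   `grad(x, y)` closures, the parameter list, the sampling `domain` and
#'   the designed `basins` (well centers).
#' @export
make_surface <- function(archetype = c("canonical_like", "mismatch_like",
                                       "quadratic", "double_well", "custom"),
                         dims = NULL, parameters = list()) {
  archetype <- match.arg(archetype)
  if (archetype == "custom") {
    p <- parameters
    if (is.null(p$dims)) stop("custom surfaces need an explicit parameter list")
  } else {
    if (is.null(dims)) dims <- if (archetype %in% c("double_well")) 1L else 2L
    p <- .surface_params(archetype, dims)
    p[names(parameters)] <- parameters
  }
  d <- p$dims
  V <- function(x, y = NULL) {
    if (d == 1 || is.null(y)) y <- rep(p$y0, length(x))
    ax <- 1 + p$asym * (1 - tanh((x - p$x0) / p$tau)) / 2
    v <- p$cx * (x - p$x0)^2 * ax + p$cy * (y - p$y0)^2
    if (nrow(p$wells) > 0) {
      for (i in seq_len(nrow(p$wells))) {
        w <- p$wells[i, ]
        v <- v - w["depth"] * exp(-((x - w["x"])^2 / (2 * w["wx"]^2) +
                                      (y - w["y"])^2 / (2 * w["wy"]^2)))
      }
    }
    unname(v)
  }
  grad <- function(x, y = NULL) {
    if (d == 1 || is.null(y)) y <- rep(p$y0, length(x))
    th <- tanh((x - p$x0) / p$tau)
    ax <- 1 + p$asym * (1 - th) / 2
    dax <- -p$asym * (1 - th^2) / (2 * p$tau)
    gx <- p$cx * (2 * (x - p$x0) * ax + (x - p$x0)^2 * dax)
    gy <- 2 * p$cy * (y - p$y0)
    if (nrow(p$wells) > 0) {
      for (i in seq_len(nrow(p$wells))) {
        w <- p$wells[i, ]
        e <- exp(-((x - w["x"])^2 / (2 * w["wx"]^2) +
                     (y - w["y"])^2 / (2 * w["wy"]^2)))
        gx <- gx + w["depth"] * e * (x - w["x"]) / w["wx"]^2
        gy <- gy + w["depth"] * e * (y - w["y"]) / w["wy"]^2
      }
    }
    if (d == 1) cbind(gx = unname(gx))
    else cbind(gx = unname(gx), gy = unname(gy))
  }
  structure(list(archetype = archetype, dims = d, params = p,
                 domain = p$domain, V = V, grad = grad,
                 basins = p$wells[, c("x", "y"), drop = FALSE]),
            class = "model_surface")
}

#' Locate the minima of a model surface by brute-force grid search
#'
#' Evaluates V on a fine grid over the domain and returns strict local
#' minima (8-neighborhood, interior only).  Used as an oracle.
#'
#' @param surface A `model_surface`.
#' @param dx Grid resolution along x (degrees; default 0.5).
#' @param dy Grid resolution along y (Angstrom; default 0.05).
#' @return data.frame of minima: x, y, value (ascending).
#' @export
surface_minima_bruteforce <- function(surface, dx = 0.5, dy = 0.05) {
  dom <- surface$domain
  xs <- seq(dom$mins[1], dom$maxs[1], by = dx)
  if (surface$dims == 1) {
    v <- surface$V(xs)
    idx <- which(diff(sign(diff(v))) == 2) + 1L
    return(data.frame(x = xs[idx], y = 0, value = v[idx])[order(v[idx]), ])
  }
  ys <- seq(dom$mins[2], dom$maxs[2], by = dy)
  V <- outer(xs, ys, function(a, b) surface$V(a, b))
  nx <- length(xs); ny <- length(ys)
  mins <- list()
  for (j in 2:(ny - 1)) for (i in 2:(nx - 1)) {
    v0 <- V[i, j]
    if (v0 < min(V[(i - 1):(i + 1), (j - 1):(j + 1)][-5])) {
      mins[[length(mins) + 1]] <- data.frame(x = xs[i], y = ys[j], value = v0)
    }
  }
  out <- do.call(rbind, mins)
  out[order(out$value), ]
}

#' Generate a noisy mean-force grid directly from an analytic surface
#'
#' Per bin, draws `n_per_bin` iid samples of the analytic mean force
#' (-grad V at the bin center) plus Normal(0, noise_sd^2) noise, and
#' accumulates them.  A direct test input for the GPR integrator.
#'
#' @param surface A `model_surface`.
#' @param spec A `grid_spec` with matching dimensionality.
#' @param n_per_bin Samples per bin (>= 1).
#' @param noise_sd Force noise standard deviation (kcal/mol per CV unit).
#' @param seed RNG seed (NULL: leave RNG state alone).
#' @return A `mean_force_grid`.
#' @export
noisy_gradient_field <- function(surface, spec, n_per_bin = 100, noise_sd = 0.5,
                                 seed = NULL) {
  stopifnot(n_per_bin >= 1, spec$dims == surface$dims)
  if (!is.null(seed)) set.seed(seed)
  centers <- .all_centers(spec)
  gv <- if (spec$dims == 2) surface$grad(centers[, 1], centers[, 2])
        else surface$grad(centers[, 1])
  force <- -gv
  B <- nrow(centers)
  grid <- .empty_grid(spec)
  grid$n <- rep.int(as.integer(n_per_bin), B)
  for (k in seq_len(spec$dims)) {
    noise <- matrix(stats::rnorm(B * n_per_bin, sd = noise_sd), B, n_per_bin)
    samples <- noise + force[, k]
    mu <- rowMeans(samples)
    grid$mean[, k] <- mu
    grid$m2[, k] <- rowSums((samples - mu)^2)
  }
  grid
}
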