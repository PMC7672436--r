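# CV grids and mean-force accumulation with multiple-walker merging.

#' Define a 1D or 2D CV grid
#'
#' @param mins,maxs Numeric vectors (length = dims) of grid bounds, CV units.
#' @param nbins Integer vector of bin counts per dimension (>= 2).
#' @param periodic Logical vector; periodic dimensions must span one period.
#' @param names Optional CV names per dimension.
#' @return Object of class "grid_spec".
#' @export
grid_spec <- function(mins, maxs, nbins, periodic = FALSE, names = NULL) {
  d <- length(mins)
  stopifnot(d %in% c(1L, 2L), length(maxs) == d)
  nbins <- as.integer(rep_len(nbins, d))
  periodic <- rep_len(periodic, d)
  if (any(nbins < 2)) stop("nbins must be >= 2")
  if (any(maxs <= mins)) stop("max must exceed min")
  if (is.null(names)) names <- paste0("cv", seq_len(d))
  structure(list(dims = d, mins = as.numeric(mins), maxs = as.numeric(maxs),
                 nbins = nbins, periodic = periodic, names = names),
            class = "grid_spec")
}

#' Bin centers of a grid dimension
#' @param spec A `grid_spec`.
#' @param dim Dimension index.
#' @return Numeric vector of bin centers.
#' @export
bin_centers <- function(spec, dim = 1) {
  w <- (spec$maxs[dim] - spec$mins[dim]) / spec$nbins[dim]
  spec$mins[dim] + (seq_len(spec$nbins[dim]) - 0.5) * w
}

.bin_width <- function(spec, dim = 1) (spec$maxs[dim] - spec$mins[dim]) / spec$nbins[dim]

.n_bins_total <- function(spec) prod(spec$nbins)

# Matrix (B x d) of all bin centers in column-major (dim-1 fastest) order.
.all_centers <- function(spec) {
  if (spec$dims == 1) matrix(bin_centers(spec, 1), ncol = 1)
  else as.matrix(expand.grid(bin_centers(spec, 1), bin_centers(spec, 2)))
}

# Map values (n x d matrix) to linear bin index; NA for out-of-range
# non-periodic values.  Periodic values are wrapped into [min, max).
.bin_index <- function(spec, values) {
  values <- as.matrix(values)
  idx <- matrix(NA_integer_, nrow(values), spec$dims)
  for (k in seq_len(spec$dims)) {
    v <- values[, k]
    span <- spec$maxs[k] - spec$mins[k]
    if (spec$periodic[k]) v <- spec$mins[k] + (v - spec$mins[k]) %% span
    i <- floor((v - spec$mins[k]) / .bin_width(spec, k)) + 1L
    i[v == spec$maxs[k]] <- spec$nbins[k]  # closed upper edge
    i[i < 1L | i > spec$nbins[k]] <- NA_integer_
    idx[, k] <- i
  }
  if (spec$dims == 1) idx[, 1]
  else (idx[, 2] - 1L) * spec$nbins[1] + idx[, 1]
}

.empty_grid <- function(spec) {
  B <- .n_bins_total(spec)
  structure(list(spec = spec,
                 n = integer(B),
                 mean = matrix(0, B, spec$dims),
                 m2 = matrix(0, B, spec$dims),
                 g = NULL,
                 out_of_range = 0L),
            class = "mean_force_grid")
}

#' Accumulate (CV value, instantaneous force) samples onto a grid
#'
#' Per-bin running mean and sum of squared deviations of the generalized
#' force components, via the numerically stable one-pass (Welford) scheme.
#' Out-of-range samples on non-periodic dimensions are counted in
#' `$out_of_range` but not binned.
#'
#' @param samples data.frame or matrix with d value columns followed by d
#'   force columns (e.g. x, fx for 1D; x, y, fx, fy for 2D), or output of
#'   [sample_langevin()].
#' @param spec A `grid_spec`.
#' @return Object of class "mean_force_grid" with per-bin `n`, `mean`
#'   (B x d, kcal/mol per CV unit) and `m2` (B x d squared-deviation sums).
#' @export
accumulate <- function(samples, spec) {
  d <- spec$dims
  m <- as.matrix(as.data.frame(samples)[, setdiff(colnames(as.data.frame(samples)),
                                                  c("frame", "walker")), drop = FALSE])
  if (ncol(m) < 2 * d) stop("expected ", d, " value and ", d, " force columns")
  values <- m[, seq_len(d), drop = FALSE]
  forces <- m[, d + seq_len(d), drop = FALSE]
  grid <- .empty_grid(spec)
  bi <- .bin_index(spec, values)
  oor <- is.na(bi)
  grid$out_of_range <- sum(oor)
  bi <- bi[!oor]
  forces <- forces[!oor, , drop = FALSE]
  if (length(bi) == 0) return(grid)
  ord <- order(bi)
  bi <- bi[ord]; forces <- forces[ord, , drop = FALSE]
  ub <- unique(bi)
  grp <- match(bi, ub)
  n_g <- tabulate(grp, nbins = length(ub))
  for (k in seq_len(d)) {
    s <- rowsum(forces[, k], grp)[, 1]
    mu <- s / n_g
    dev2 <- rowsum((forces[, k] - mu[grp])^2, grp)[, 1]
    grid$mean[ub, k] <- mu
    grid$m2[ub, k] <- dev2
  }
  grid$n[ub] <- n_g
  grid
}

#' Merge mean-force grids from multiple walkers
#'
#' Chan-Golub-LeVeque pooling of counts, means and squared-deviation sums;
#' commutative and associative up to floating-point rounding.
#'
#' @param grids List of `mean_force_grid` objects sharing one `grid_spec`.
#' @return Pooled `mean_force_grid`.
#' @export
merge_walkers <- function(grids) {
  if (inherits(grids, "mean_force_grid")) return(grids)
  stopifnot(length(grids) >= 1)
  spec <- grids[[1]]$spec
  for (g in grids) {
    if (!identical(g$spec[c("dims", "mins", "maxs", "nbins", "periodic")],
                   spec[c("dims", "mins", "maxs", "nbins", "periodic")])) {
      stop("grid specs differ; cannot merge walkers")
    }
  }
  out <- .empty_grid(spec)
  for (g in grids) {
    na <- out$n; nb <- g$n; nt <- na + nb
    upd <- nt > 0
    delta <- g$mean - out$mean
    w <- ifelse(nt > 0, nb / nt, 0)
    out$mean[upd, ] <- out$mean[upd, , drop = FALSE] +
      delta[upd, , drop = FALSE] * w[upd]
    corr <- delta^2 * ifelse(nt > 0, na * nb / nt, 0)
    out$m2[upd, ] <- out$m2[upd, , drop = FALSE] + g$m2[upd, , drop = FALSE] +
      corr[upd, , drop = FALSE]
    out$n <- nt
    out$out_of_range <- out$out_of_range + g$out_of_range
  }
  out
}

# Per-bin, per-component variance of the mean force sample mean (includes the
# statistical-inefficiency factor g).
.mean_force_noise <- function(grid, g = NULL) {
  if (is.null(g)) g <- if (is.null(grid$g)) 1 else grid$g
  n <- pmax(grid$n, 1L)
  varhat <- grid$m2 / pmax(grid$n - 1L, 1L)
  sweep(varhat, 1, g / n, "*")
}
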