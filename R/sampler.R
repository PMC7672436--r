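# R front end of the overdamped Langevin sampler.

#' Sampler configuration
#'
#' @param temperature Kelvin (default 300).
#' @param step_size Effective mobility step h (per dimension; scalar
#'   recycled).  The update is x' = x + h F + sqrt(2 RT h) xi.
#' @param n_steps Steps per walker.
#' @param seed Integer seed (required for reproducibility).
#' @param bias "none" or "abf_like".
#' @param n_walkers Number of walkers; with "abf_like" they share the
#'   accumulated mean-force estimate (multiple-walker style), run
#'   sequentially.
#' @param grid `grid_spec` used by the ABF-like bias (defaults to 32 bins
#'   per dimension over the surface domain).
#' @param n_ramp Samples per bin before the bias is applied at full
#'   strength (linear ramp, default 200).
#' @param force_noise_sd Std. dev. of the noise added to the recorded
#'   instantaneous force (kcal/mol per CV unit).
#' @param force_noise_ar1 Lag-1 autocorrelation of that noise in (0, 1).
#' @param x0 Initial point (default: domain center).
#' @param stride Record every `stride`-th step.
#' @return List of class "sampler_config".
#' @export
sampler_config <- function(temperature = 300, step_size = NULL, n_steps = 1e5,
                           seed = 1L, bias = c("none", "abf_like"),
                           n_walkers = 1L, grid = NULL, n_ramp = 200L,
                           force_noise_sd = 2, force_noise_ar1 = 0,
                           x0 = NULL, stride = 1L) {
  bias <- match.arg(bias)
  stopifnot(n_steps >= 1, n_walkers >= 1, stride >= 1,
            force_noise_ar1 >= 0, force_noise_ar1 < 1)
  structure(list(temperature = temperature, step_size = step_size,
                 n_steps = as.integer(n_steps), seed = as.integer(seed),
                 bias = bias, n_walkers = as.integer(n_walkers), grid = grid,
                 n_ramp = as.integer(n_ramp), force_noise_sd = force_noise_sd,
                 force_noise_ar1 = force_noise_ar1, x0 = x0,
                 stride = as.integer(stride)),
            class = "sampler_config")
}

# conservative default step sizes: h ~ 0.1 / max local curvature scale,
# approximated per archetype family from well depth / width^2.
.default_step <- function(surface) {
  p <- surface$params
  curv <- c(2 * p$cx * (1 + p$asym), 2 * p$cy)
  if (nrow(p$wells) > 0) {
    curv[1] <- max(curv[1], max(p$wells[, "depth"] / p$wells[, "wx"]^2))
    curv[2] <- max(curv[2], max(p$wells[, "depth"] / p$wells[, "wy"]^2))
  }
  h <- 0.1 / pmax(curv, 1e-6)
  h[seq_len(surface$dims)]
}

#' Sample a model surface with overdamped Langevin dynamics
#'
#' Euler-Maruyama integration of dx = h F dt + sqrt(2 RT h) dW at the
#' configured temperature, with reflecting (non-periodic) or wrapping
#' (periodic) domain boundaries.  The recorded instantaneous generalized
#' force is -grad V plus AR(1) noise (the synthetic stand-in for thermal
#' force fluctuations); with `bias = "abf_like"` the running per-bin mean of
#' those recorded forces is subtracted from the drift once a bin has been
#' visited, ramped linearly up to `n_ramp` samples.  Identical seeds give
#' bit-identical output.
#'
#' @param surface A `model_surface`.
#' @param config A `sampler_config`.
#' @return List of per-walker data.frames (frame, x[, y], fx[, fy]); the
#'   shared ABF accumulator is attached as attribute "abf".
#' @export
sample_langevin <- function(surface, config = sampler_config()) {
  d <- surface$dims
  dom <- surface$domain
  h <- config$step_size
  if (is.null(h)) h <- .default_step(surface)
  h <- rep_len(h, d)
  stopifnot(all(h > 0))
  RT <- rt_kcal(config$temperature)
  x0 <- config$x0
  if (is.null(x0)) x0 <- (dom$mins + dom$maxs) / 2
  periodic <- rep(FALSE, d)
  grid <- config$grid
  if (is.null(grid)) {
    grid <- grid_spec(dom$mins, dom$maxs, rep(32L, d), periodic = periodic)
  }
  abf <- config$bias == "abf_like"
  abf_n <- integer(.n_bins_total(grid))
  abf_sum <- matrix(0, .n_bins_total(grid), d)
  set.seed(config$seed)
  out <- vector("list", config$n_walkers)
  for (w in seq_len(config$n_walkers)) {
    nm <- matrix(stats::rnorm(config$n_steps * d), config$n_steps, d)
    nf <- matrix(stats::rnorm(config$n_steps * d), config$n_steps, d)
    res <- .langevin_cpp(config$n_steps, x0, h, RT, surface$params,
                         dom$mins, dom$maxs, periodic,
                         abf, grid$mins, grid$maxs, grid$nbins, config$n_ramp,
                         nm, nf, config$force_noise_sd, config$force_noise_ar1,
                         abf_n, abf_sum, config$stride)
    abf_n <- res$abf_n; abf_sum <- res$abf_sum
    df <- as.data.frame(res$values)
    names(df) <- c("x", "y")[seq_len(d)]
    ff <- as.data.frame(res$forces)
    names(ff) <- c("fx", "fy")[seq_len(d)]
    out[[w]] <- cbind(frame = seq_len(nrow(df)), df, ff)
  }
  attr(out, "abf") <- list(grid = grid, n = abf_n, sum = abf_sum)
  attr(out, "config") <- config
  out
}
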