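# Gaussian-process integration of mean-force grids into free-energy
# surfaces.  The latent potential G(x) carries an anisotropic
# squared-exponential prior (wrapped/periodic variant on periodic CV
# dimensions); the observations are bin-center mean forces, i.e. noisy
# derivative observations -dG/dx, with per-bin noise variances taken from
# the accumulated force variance inflated by the statistical inefficiency.

# Per-dimension kernel ingredients between point sets X1 (n1 x d) and
# X2 (n2 x d): s_k (exponent term), u_k = ds/dDelta, v_k = d2s/dDelta2.
.kern_parts <- function(X1, X2, ell, periodic, periods) {
  d <- ncol(X1)
  S <- vector("list", d); U <- vector("list", d); V <- vector("list", d)
  for (k in seq_len(d)) {
    D <- outer(X1[, k], X2[, k], "-")
    l2 <- ell[k]^2
    if (periodic[k]) {
      w <- 2 * pi / periods[k]
      S[[k]] <- (1 - cos(w * D)) / l2
      U[[k]] <- w * sin(w * D) / l2
      V[[k]] <- w^2 * cos(w * D) / l2
    } else {
      S[[k]] <- D^2 / (2 * l2)
      U[[k]] <- D / l2
      V[[k]] <- matrix(1 / l2, nrow(D), ncol(D))
    }
  }
  E <- exp(-Reduce(`+`, S))
  list(E = E, S = S, U = U, V = V)
}

# Derivative-derivative covariance (M x M, M = n * d) between observation
# points; blocks ordered by force component.
.k_dd <- function(parts, sigf2, d) {
  n1 <- nrow(parts$E); n2 <- ncol(parts$E)
  K <- matrix(0, n1 * d, n2 * d)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    blk <- parts$E * ((if (i == j) parts$V[[j]] else 0) - parts$U[[i]] * parts$U[[j]])
    K[(i - 1) * n1 + seq_len(n1), (j - 1) * n2 + seq_len(n2)] <- sigf2 * blk
  }
  K
}

# Function-derivative covariance (npred x M).
.k_fd <- function(parts, sigf2, d) {
  n1 <- nrow(parts$E); n2 <- ncol(parts$E)
  K <- matrix(0, n1, n2 * d)
  for (j in seq_len(d)) {
    K[, (j - 1) * n2 + seq_len(n2)] <- sigf2 * parts$E * parts$U[[j]]
  }
  K
}

.chol_jitter <- function(K, scale, ladder = 10^seq(-10, -6)) {
  for (j in c(0, ladder)) {
    L <- tryCatch(chol(K + diag(j * scale, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = j * scale))
  }
  stop("covariance not positive definite even at jitter ",
       format(max(ladder) * scale))
}

# Log marginal likelihood of derivative observations and its gradient with
# respect to (log signal_sd, log lengthscales).
.gpr_lml_core <- function(X, y, noise_var, ell, sigf, periodic, periods,
                          want_grad = TRUE) {
  d <- ncol(X); n <- nrow(X); M <- n * d
  parts <- .kern_parts(X, X, ell, periodic, periods)
  sigf2 <- sigf^2
  Kk <- .k_dd(parts, sigf2, d)
  scale <- mean(abs(diag(Kk))) + 1e-12
  K <- Kk + diag(noise_var, M)
  ch <- .chol_jitter(K, scale)
  L <- ch$L
  alpha <- backsolve(L, forwardsolve(t(L), y))
  lml <- -0.5 * sum(y * alpha) - sum(log(diag(L))) - 0.5 * M * log(2 * pi)
  if (!want_grad) return(list(lml = lml, L = L, alpha = alpha, jitter = ch$jitter))
  Kinv <- chol2inv(L)
  grad <- numeric(d + 1)
  # d/dlog sigf: kernel part scales as sigf^2
  grad[1] <- 0.5 * sum(alpha * (2 * Kk %*% alpha)) - 0.5 * sum(Kinv * (2 * Kk))
  for (m in seq_len(d)) {
    dK <- matrix(0, M, M)
    for (i in seq_len(d)) for (j in seq_len(d)) {
      base <- (if (i == j) parts$V[[j]] else 0) - parts$U[[i]] * parts$U[[j]]
      blk <- 2 * parts$S[[m]] * base
      if (j == m && i == j) blk <- blk - 2 * parts$V[[j]]
      extra <- ((i == m) + (j == m)) * parts$U[[i]] * parts$U[[j]]
      blk <- blk + 2 * extra
      dK[(i - 1) * n + seq_len(n), (j - 1) * n + seq_len(n)] <-
        sigf2 * parts$E * blk
    }
    grad[m + 1] <- 0.5 * sum(alpha * (dK %*% alpha)) - 0.5 * sum(Kinv * dK)
  }
  list(lml = lml, grad = grad, L = L, alpha = alpha, jitter = ch$jitter)
}

# Assemble training data from a mean-force grid.
.gpr_training <- function(grid, g = NULL, min_n = 2L) {
  spec <- grid$spec
  used <- which(grid$n >= max(min_n, 1L))
  if (length(used) < 10) stop("need at least 10 sampled bins to fit a GP")
  X <- .all_centers(spec)[used, , drop = FALSE]
  d <- spec$dims
  y <- as.vector(-grid$mean[used, , drop = FALSE])  # gradient of G = -mean force
  nv <- as.vector(.mean_force_noise(grid, g)[used, , drop = FALSE])
  periods <- spec$maxs - spec$mins
  list(X = X, y = y, noise_var = nv, used = used, d = d,
       periodic = spec$periodic, periods = periods, nbins = spec$nbins)
}

#' Log marginal likelihood (and gradient) of a GPR mean-force model
#'
#' Exposed mainly for validation: the analytic gradient with respect to the
#' log hyperparameters can be checked against finite differences.
#'
#' @param grid A `mean_force_grid`.
#' @param lengthscales Per-dimension kernel length scales (CV units).
#' @param signal_sd Signal standard deviation (kcal/mol).
#' @param g Statistical inefficiency used to inflate per-bin noise.
#' @param min_n Minimum per-bin sample count for a bin to enter the fit.
#' @return List with `lml` and `grad` (d/dlog signal_sd, d/dlog lengthscales).
#' @export
gpr_lml <- function(grid, lengthscales, signal_sd, g = NULL, min_n = 2L) {
  tr <- .gpr_training(grid, g, min_n)
  res <- .gpr_lml_core(tr$X, tr$y, tr$noise_var, lengthscales, signal_sd,
                       tr$periodic, tr$periods)
  list(lml = res$lml, grad = res$grad)
}

#' Fit GPR hyperparameters to a mean-force grid
#'
#' Maximizes the log marginal likelihood of the observed bin-mean forces
#' under the derivative-observation GP by multi-start L-BFGS-B on the log
#' hyperparameters (signal sd and per-dimension length scales); per-bin
#' noise variances are fixed at variance * g / n.
#'
#' @param grid A `mean_force_grid`.
#' @param g Statistical inefficiency (scalar) applied to all bins; default
#'   uses `grid$g` when set, else 1.
#' @param lengthscales,signal_sd Optional fixed hyperparameters; when both
#'   are given the optimization is skipped (useful to reuse a fit).
#' @param n_starts Number of optimizer starts.
#' @param maxit L-BFGS-B iteration cap per start.
#' @param min_n Minimum per-bin count for inclusion.
#' @return Object of class "gpr_model".
#' @export
fit_gpr <- function(grid, g = NULL, lengthscales = NULL, signal_sd = NULL,
                    n_starts = 2L, maxit = 60L, min_n = 2L) {
  tr <- .gpr_training(grid, g, min_n)
  d <- tr$d
  span <- tr$periods
  if (!is.null(lengthscales) && !is.null(signal_sd)) {
    theta <- log(c(signal_sd, lengthscales))
  } else {
    cache <- new.env(parent = emptyenv())
    evaluate <- function(th) {
      key <- paste(format(th, digits = 17), collapse = ",")
      if (!identical(cache$key, key)) {
        r <- .gpr_lml_core(tr$X, tr$y, tr$noise_var, exp(th[-1]), exp(th[1]),
                           tr$periodic, tr$periods)
        cache$key <- key; cache$val <- r
      }
      cache$val
    }
    fn <- function(th) -evaluate(th)$lml
    grad_fn <- function(th) -evaluate(th)$grad
    sc0 <- stats::sd(tr$y) * mean(span) / 5 + 1e-6
    starts <- list(log(c(sc0, span / 5)),
                   log(c(3 * sc0, span / 12)),
                   log(c(sc0 / 3, span / 3)))[seq_len(max(1L, n_starts))]
    lower <- log(c(sc0 * 1e-3, 0.5 * span / tr$nbins))
    upper <- log(c(sc0 * 1e3, span * 10))
    best <- NULL
    for (st in starts) {
      fit <- tryCatch(
        stats::optim(st, fn, grad_fn, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = maxit)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best)) stop("GPR hyperparameter optimization failed")
    theta <- best$par
  }
  final <- .gpr_lml_core(tr$X, tr$y, tr$noise_var, exp(theta[-1]), exp(theta[1]),
                         tr$periodic, tr$periods, want_grad = FALSE)
  structure(list(
    signal_sd = exp(theta[1]),
    lengthscales = exp(theta[-1]),
    log_marginal_likelihood = final$lml,
    jitter = final$jitter,
    training = tr,
    L = final$L,
    alpha = final$alpha
  ), class = "gpr_model")
}

#' @export
print.gpr_model <- function(x, ...) {
  cat("gpr_model: signal_sd =", signif(x$signal_sd, 4),
      "lengthscales =", signif(x$lengthscales, 4),
      "logML =", signif(x$log_marginal_likelihood, 6), "\n")
  invisible(x)
}

#' Integrate a mean-force grid into a free-energy surface
#'
#' Posterior mean of the latent potential given the derivative observations,
#' evaluated at all bin centers, referenced to its minimum over unmasked
#' bins.  Standard errors are reported at three posterior standard
#' deviations of the *referenced* value, i.e. of G(x) - G(x_min), so the
#' reference bin itself has zero error.
#'
#' @param grid A `mean_force_grid`.
#' @param model A `gpr_model` fitted on (a compatible view of) `grid`.
#' @param mask_min_eff Bins with fewer effective samples (n/g) are masked.
#' @param g Statistical inefficiency for the effective-sample mask.
#' @return Object of class "fe_surface": `spec`, `value` (kcal/mol, min 0),
#'   `stderr` (3 sigma), `mask` (TRUE = insufficiently sampled).
#' @export
integrate_gpr <- function(grid, model, mask_min_eff = 10, g = NULL) {
  spec <- grid$spec
  tr <- model$training
  Xp <- .all_centers(spec)
  parts <- .kern_parts(Xp, tr$X, model$lengthscales, tr$periodic, tr$periods)
  sigf2 <- model$signal_sd^2
  Kfd <- .k_fd(parts, sigf2, tr$d)
  mp <- as.vector(Kfd %*% model$alpha)
  if (is.null(g)) g <- if (is.null(grid$g)) 1 else grid$g
  n_eff <- grid$n / g
  mask <- n_eff < mask_min_eff
  if (all(mask)) stop("all bins masked: no sufficiently sampled region")
  A <- forwardsolve(t(model$L), t(Kfd))      # M x N
  var_f <- pmax(sigf2 - colSums(A^2), 0)
  ref <- which(!mask)[which.min(mp[!mask])]
  # covariance between each bin and the reference bin
  pr <- .kern_parts(Xp, Xp[ref, , drop = FALSE], model$lengthscales,
                    tr$periodic, tr$periods)
  cov_ref <- as.vector(sigf2 * pr$E) - as.vector(crossprod(A, A[, ref]))
  var_rel <- pmax(var_f + var_f[ref] - 2 * cov_ref, 0)
  surf <- structure(list(
    spec = spec,
    value = mp - mp[ref],
    stderr = 3 * sqrt(var_rel),
    mask = mask,
    n = grid$n
  ), class = "fe_surface")
  reference_to_min(surf)
}

#' Reference a free-energy surface to its minimum
#'
#' Subtracts the minimum over unmasked bins; idempotent.
#'
#' @param surface A `fe_surface` (or `fe_profile`).
#' @return The referenced object (minimum over unmasked bins exactly 0).
#' @export
reference_to_min <- function(surface) {
  ok <- !surface$mask
  if (!any(ok)) stop("empty surface: all bins masked")
  surface$value <- surface$value - min(surface$value[ok])
  surface
}
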