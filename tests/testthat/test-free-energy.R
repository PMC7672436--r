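# Mean-force grids, walker merging, statistical inefficiency, GPR
# integration and its uncertainty model.

test_that("accumulate computes per-bin moments and counts out-of-range", {
  spec <- grid_spec(0, 10, 10, names = "x")
  s <- data.frame(x = rep(0.5, 100), fx = rep(2, 100))
  g <- accumulate(s, spec)
  expect_equal(g$n[1], 100L)
  expect_equal(g$mean[1, 1], 2)
  expect_equal(g$m2[1, 1], 0)
  expect_equal(sum(g$n), 100L)
  # CLT bound on a seeded normal sample
  set.seed(1)
  s2 <- data.frame(x = rep(0.5, 10000), fx = rnorm(10000, -1, 0.5))
  g2 <- accumulate(s2, spec)
  expect_lt(abs(g2$mean[1, 1] + 1), 4 * 0.5 / sqrt(10000))
  # out-of-range samples are counted, not binned
  g3 <- accumulate(data.frame(x = c(0.5, 42), fx = c(1, 1)), spec)
  expect_equal(g3$out_of_range, 1L)
  expect_equal(sum(g3$n), 1L)
})

test_that("merge of walker grids equals accumulation of the concatenation", {
  spec <- grid_spec(c(-1, -1), c(1, 1), c(6, 5), names = c("x", "y"))
  set.seed(2)
  mk <- function(n) data.frame(x = runif(n, -1, 1), y = runif(n, -1, 1),
                               fx = rnorm(n), fy = rnorm(n, 1, 2))
  a <- mk(500); b <- mk(300); c3 <- mk(200)
  merged <- merge_walkers(list(accumulate(a, spec), accumulate(b, spec),
                               accumulate(c3, spec)))
  direct <- accumulate(rbind(a, b, c3), spec)
  expect_equal(merged$n, direct$n)
  expect_equal(merged$mean, direct$mean, tolerance = 1e-12)
  expect_equal(merged$m2, direct$m2, tolerance = 1e-10)
  # pairwise vs batched merge; empty grid is an identity
  pw <- merge_walkers(list(merge_walkers(list(accumulate(a, spec),
                                              accumulate(b, spec))),
                           accumulate(c3, spec)))
  expect_equal(pw$mean, merged$mean, tolerance = 1e-12)
  empty <- accumulate(mk(0), spec)
  with_empty <- merge_walkers(list(direct, empty))
  expect_equal(with_empty$mean, direct$mean)
  expect_equal(with_empty$n, direct$n)
  expect_error(merge_walkers(list(direct, accumulate(a, grid_spec(0, 1, 5)))),
               "specs differ")
})

test_that("statistical inefficiency recovers iid and AR(1) behaviour", {
  set.seed(12)
  expect_gt(statistical_inefficiency(rnorm(10000)), 0.8)
  expect_lt(statistical_inefficiency(rnorm(10000)), 1.3)
  expect_equal(statistical_inefficiency(rep(3, 100)), 1)
  expect_error(statistical_inefficiency(c(1, 2)), "short")
  set.seed(13)
  x <- as.numeric(arima.sim(list(ar = 0.9), 1e5))
  target <- (1 + 0.9) / (1 - 0.9)
  g_iact <- statistical_inefficiency(x)
  expect_lt(abs(g_iact - target) / target, 0.15)
  g_block <- statistical_inefficiency(x, method = "blocking")
  expect_lt(abs(log(g_block / g_iact)), log(2))  # within a factor of 2
})

test_that("analytic LML gradient matches central finite differences", {
  s <- make_surface("quadratic")
  spec <- grid_spec(c(-2, -2), c(2, 2), c(8, 8), names = c("x", "y"))
  grid <- noisy_gradient_field(s, spec, n_per_bin = 20, noise_sd = 0.5, seed = 5)
  set.seed(6)
  for (i in 1:20) {
    ell <- exp(runif(2, log(0.3), log(3)))
    sf <- exp(runif(1, log(0.3), log(5)))
    r <- gpr_lml(grid, ell, sf)
    th <- log(c(sf, ell)); h <- 1e-5
    fd <- vapply(1:3, function(k) {
      tp <- th; tp[k] <- tp[k] + h
      tm <- th; tm[k] <- tm[k] - h
      (gpr_lml(grid, exp(tp[-1]), exp(tp[1]))$lml -
         gpr_lml(grid, exp(tm[-1]), exp(tm[1]))$lml) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(r$grad - fd) / pmax(abs(fd), 1e-6)), 1e-4)
  }
})

test_that("GPR recovers a known kernel length scale (20 replicates)", {
  # draw gradient observations exactly from the derivative-GP model with
  # lengthscale 0.5, then refit
  sp <- grid_spec(-2, 2, 25, names = "x")
  X <- matrix(bin_centers(sp, 1), ncol = 1)
  parts <- pairscape:::.kern_parts(X, X, 0.5, FALSE, 4)
  Kdd <- pairscape:::.k_dd(parts, 2^2, 1)
  L <- t(chol(Kdd + 1e-8 * diag(25)))
  rec <- vapply(1:20, function(seed) {
    set.seed(200 + seed)
    gobs <- as.vector(L %*% rnorm(25)) + rnorm(25, sd = 0.1)
    grid <- pairscape:::.empty_grid(sp)
    grid$n <- rep(50L, 25)
    grid$mean[, 1] <- -gobs               # force = -gradient
    grid$m2[, 1] <- rep(0.1^2 * 50 * 49, 25)  # per-sample var so noise of mean = 0.1^2
    fit_gpr(grid, n_starts = 3, maxit = 60)$lengthscales
  }, numeric(1))
  expect_lt(abs(median(rec) - 0.5) / 0.5, 0.25)
})

test_that("doubling noise does not increase the fitted signal-to-noise ratio", {
  s <- make_surface("double_well", dims = 1)
  sp <- grid_spec(-3, 3, 25, names = "x")
  g1 <- noisy_gradient_field(s, sp, n_per_bin = 50, noise_sd = 0.5, seed = 3)
  g2 <- g1
  g2$m2 <- g2$m2 * 4  # doubled per-sample noise sd
  m1 <- fit_gpr(g1, n_starts = 2, maxit = 50)
  m2 <- fit_gpr(g2, n_starts = 2, maxit = 50)
  snr1 <- m1$signal_sd^2 / mean(pairscape:::.mean_force_noise(g1))
  snr2 <- m2$signal_sd^2 / mean(pairscape:::.mean_force_noise(g2))
  expect_lte(snr2, snr1 * 1.01)
})

test_that("integration reproduces curl-free fields (trapezoid oracle)", {
  sp <- grid_spec(c(0, 0), c(1, 1), c(21, 21), names = c("x", "y"))
  xs <- bin_centers(sp, 1); ys <- bin_centers(sp, 2)
  gx <- outer(xs, ys, function(x, y) 2 * cos(2 * x) + y)
  gy <- outer(xs, ys, function(x, y) x + y)
  grid <- pairscape:::.empty_grid(sp)
  grid$n <- rep(5L, 441)
  grid$mean[, 1] <- -as.vector(gx)
  grid$mean[, 2] <- -as.vector(gy)
  model <- fit_gpr(grid, n_starts = 1, maxit = 50)
  fes <- integrate_gpr(grid, model, mask_min_eff = 1)
  oracle <- line_integral_oracle(xs, ys, gx, gy)
  oracle <- as.vector(oracle) - min(oracle)
  expect_lt(max(abs(fes$value - oracle)), 1e-2)
  # flat-field sanity: zero forces with zero noise give a flat zero surface
  flat <- pairscape:::.empty_grid(sp)
  flat$n <- rep(5L, 441)
  mflat <- fit_gpr(flat, lengthscales = c(0.3, 0.3), signal_sd = 1)
  sflat <- integrate_gpr(flat, mflat, mask_min_eff = 1)
  expect_lt(max(abs(sflat$value)), 1e-8)
})

test_that("posterior stderr shrinks bin-wise with more samples", {
  s <- make_surface("double_well", dims = 2)
  sp <- grid_spec(s$domain$mins, s$domain$maxs, c(13, 11), names = c("x", "y"))
  g50 <- noisy_gradient_field(s, sp, n_per_bin = 50, noise_sd = 0.5, seed = 8)
  g500 <- noisy_gradient_field(s, sp, n_per_bin = 500, noise_sd = 0.5, seed = 8)
  m <- fit_gpr(g50, n_starts = 1, maxit = 40)
  f50 <- integrate_gpr(g50, m, mask_min_eff = 1)
  m2 <- fit_gpr(g500, lengthscales = m$lengthscales, signal_sd = m$signal_sd)
  f500 <- integrate_gpr(g500, m2, mask_min_eff = 1)
  # stderrs are relative to the global-minimum bin, which may move between
  # fits; exclude the two reference bins from the bin-wise comparison
  refs <- c(which.min(f50$value), which.min(f500$value))
  expect_true(all(f500$stderr[-refs] <= f50$stderr[-refs] + 1e-9))
  expect_lt(mean(f500$stderr), mean(f50$stderr))
})

test_that("reference_to_min is idempotent and exact", {
  sp <- grid_spec(0, 1, 5, names = "x")
  surf <- structure(list(spec = sp, value = c(3, 4, 5, 4, 3),
                         stderr = rep(0, 5), mask = rep(FALSE, 5)),
                    class = "fe_surface")
  r1 <- reference_to_min(surf)
  expect_identical(min(r1$value), 0)
  expect_equal(reference_to_min(r1)$value, r1$value)
  expect_equal(reference_to_min(structure(list(spec = sp, value = rep(2, 5),
                                               stderr = rep(0, 5),
                                               mask = rep(FALSE, 5)),
                                          class = "fe_surface"))$value, rep(0, 5))
  allmask <- surf; allmask$mask <- rep(TRUE, 5)
  expect_error(reference_to_min(allmask), "masked")
})
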