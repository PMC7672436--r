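# Minima, states, Boltzmann reduction, propensities, gap, stiffness.

test_that("find_minima locates analytic minima and prunes by persistence", {
  sp <- grid_spec(-2, 2, 101, names = "x")
  xs <- bin_centers(sp, 1)
  v <- (xs^2 - 1)^2
  surf <- structure(list(spec = sp, value = v - min(v), stderr = rep(0, 101),
                         mask = rep(FALSE, 101)), class = "fe_surface")
  mm <- find_minima(surf)
  expect_length(mm, 2)
  expect_equal(sort(abs(vapply(mm, function(m) m$location, numeric(1)))),
               c(0.990099, 0.990099), tolerance = 1e-6)
  expect_equal(vapply(mm, function(m) m$label, integer(1)), 1:2)
  # strictly monotone plane: no interior minima; one boundary candidate
  sp2 <- grid_spec(c(0, 0), c(1, 1), c(15, 15), names = c("x", "y"))
  ctr <- pairscape:::.all_centers(sp2)
  plane <- structure(list(spec = sp2, value = ctr[, 1] + 2 * ctr[, 2],
                          stderr = rep(0, 225), mask = rep(FALSE, 225)),
                     class = "fe_surface")
  plane <- reference_to_min(plane)
  expect_length(find_minima(plane), 0)
  expect_length(find_minima(plane, include_boundary = TRUE), 1)
  # shallow wiggles below the pruning barrier are dropped
  v2 <- 0.02 * sin(20 * xs) + (xs^2 - 1)^2
  surf2 <- structure(list(spec = sp, value = v2 - min(v2), stderr = rep(0, 101),
                          mask = rep(FALSE, 101)), class = "fe_surface")
  expect_length(find_minima(surf2, min_depth = 0.5), 2)
})

test_that("designed basin counts are recovered from noisy mean forces", {
  can <- make_surface("canonical_like")
  mis <- make_surface("mismatch_like")
  for (seed in 1:3) {
    for (arch in list(list(s = can, k = 1), list(s = mis, k = 5))) {
      sp <- grid_spec(arch$s$domain$mins, arch$s$domain$maxs, c(43, 29),
                      names = c("opening", "shear"))
      g <- noisy_gradient_field(arch$s, sp, n_per_bin = 60, noise_sd = 0.5,
                                seed = 4000 + seed)
      m <- fit_gpr(g, lengthscales = c(12, 0.5), signal_sd = 4)
      fes <- integrate_gpr(g, m, mask_min_eff = 1)
      mm <- find_minima(fes, include_boundary = TRUE)
      expect_length(mm, arch$k)
      # depth-ordered labels
      expect_equal(order(vapply(mm, function(x) x$value, numeric(1))),
                   seq_along(mm))
    }
  }
})

test_that("extract_state membership follows the analytic contour", {
  qs <- make_surface("quadratic")  # V = 0.5 (x^2 + y^2)
  sp <- grid_spec(c(-2, -2), c(2, 2), c(41, 41), names = c("x", "y"))
  surf <- surface_on_grid(qs, sp)
  mm <- find_minima(surf)
  expect_length(mm, 1)
  set.seed(17)
  cvs <- data.frame(x = runif(500, -2, 2), y = runif(500, -2, 2))
  st <- extract_state(surf, cvs, mm[[1]])
  thr <- 0.5 * rt_kcal(300)
  # membership should match the analytic iso-contour of the *binned* surface
  bins <- pairscape:::.bin_index(sp, as.matrix(cvs))
  want <- which(surf$value[bins] <= mm[[1]]$value + thr)
  expect_setequal(st$member_frames, want)
  # threshold 0 keeps only the minimum bin
  st0 <- suppressWarnings(extract_state(surf, cvs, mm[[1]], threshold = 0))
  expect_true(all(bins[st0$member_frames] == mm[[1]]$bin))
  # two-basin partition: no frame belongs to two states
  dw <- make_surface("double_well", dims = 2)
  sp2 <- grid_spec(dw$domain$mins, dw$domain$maxs, c(41, 21), names = c("x", "y"))
  surf2 <- surface_on_grid(dw, sp2)
  mm2 <- find_minima(surf2)
  expect_length(mm2, 2)
  cvs2 <- data.frame(x = runif(800, -3.2, 3.2), y = runif(800, -2.5, 2.5))
  s1 <- extract_state(surf2, cvs2, mm2[[1]], threshold = 2)
  s2 <- extract_state(surf2, cvs2, mm2[[2]], threshold = 2)
  expect_length(intersect(s1$member_frames, s2$member_frames), 0)
})

test_that("extract_state averages member structures after superposition", {
  dup <- build_duplex("GCG")
  traj <- list(transform_atoms(dup, rotation_about(c(0, 0, 1), 30), c(1, 0, 0)),
               transform_atoms(dup, rotation_about(c(1, 0, 0), -20), c(0, 5, 0)),
               dup)
  sp <- grid_spec(-1, 1, 5, names = "x")
  surf <- structure(list(spec = sp, value = c(0, 1, 2, 3, 4), stderr = rep(0, 5),
                         mask = rep(FALSE, 5)), class = "fe_surface")
  mm <- find_minima(surf, include_boundary = TRUE)
  st <- extract_state(surf, data.frame(x = c(-0.9, -0.9, -0.9)), mm[[1]],
                      trajectory = traj)
  expect_equal(st$n_members, 3)
  # all frames are rigid copies, so the average superposes exactly on any copy
  expect_lt(kabsch_oracle(coords(st$representative),
                          coords(dup))$rmsd, 1e-8)
})

test_that("Boltzmann reduction is exact on separable surfaces", {
  sp <- grid_spec(c(-2, -2), c(2, 2), c(25, 20), names = c("x", "y"))
  ctr <- pairscape:::.all_centers(sp)
  fx <- function(x) (x^2 - 1)^2
  gy <- function(y) 0.3 * y^2 + sin(y)
  surf <- structure(list(spec = sp, value = fx(ctr[, 1]) + gy(ctr[, 2]),
                         stderr = rep(0.1, 500), mask = rep(FALSE, 500)),
                    class = "fe_surface")
  surf <- reference_to_min(surf)
  prof <- reduce_profile(surf)
  want <- fx(bin_centers(sp, 1)); want <- want - min(want)
  expect_equal(prof$value, want, tolerance = 1e-12)
  # constant surface reduces to the zero profile
  const <- structure(list(spec = sp, value = rep(2, 500), stderr = rep(0, 500),
                          mask = rep(FALSE, 500)), class = "fe_surface")
  expect_equal(reduce_profile(reference_to_min(const))$value, rep(0, 25))
  # a fully masked column is masked in the profile
  surf$mask[ctr[, 1] == bin_centers(sp, 1)[3]] <- TRUE
  prof2 <- reduce_profile(surf)
  expect_true(prof2$mask[3])
  expect_false(any(prof2$mask[-3]))
})

test_that("softer Gaussian wells gain the RT ln(ratio)/2 entropic offset", {
  # two columns with stiffness k and k/4: soft column lower by RT ln 2
  sp <- grid_spec(c(0, -5), c(1, 5), c(2, 400), names = c("x", "y"))
  ctr <- pairscape:::.all_centers(sp)
  k <- ifelse(ctr[, 1] < 0.5, 4, 1)
  surf <- structure(list(spec = sp, value = 0.5 * k * ctr[, 2]^2,
                         stderr = rep(0, 800), mask = rep(FALSE, 800)),
                    class = "fe_surface")
  prof <- reduce_profile(reference_to_min(surf))
  expect_equal(diff(prof$value), -rt_kcal(300) * log(2), tolerance = 1e-4)
  expect_equal(rt_kcal(300) * log(2), 0.413, tolerance = 1e-3)
})

test_that("relative opening shifts the axis and round-trips", {
  prof <- structure(list(axis = "opening", centers = seq(-40, 40, 10),
                         value = abs(seq(-40, 40, 10) - 10) / 10,
                         stderr = rep(0.1, 9), mask = rep(FALSE, 9),
                         temperature = 300, periodic = FALSE),
                    class = "fe_profile")
  shifted <- relative_opening(prof, 10)
  expect_equal(shifted$centers, seq(-50, 30, 10))
  expect_equal(shifted$value, prof$value)
  expect_equal(relative_opening(prof, 0)$centers, prof$centers)
  back <- relative_opening(shifted, -10)
  expect_equal(back$centers, prof$centers)
  expect_error(relative_opening(prof, 99), "outside")
})

test_that("propensity interpolation is linear and bounded by neighbors", {
  centers <- seq(-100, 100, 10)
  prof <- structure(list(axis = "delta_opening", centers = centers,
                         value = abs(centers) / 10, stderr = abs(centers) / 100,
                         mask = rep(FALSE, length(centers)), temperature = 300,
                         periodic = FALSE), class = "fe_profile")
  p <- propensity_at(prof, -60)
  expect_equal(p$value, 6)
  expect_equal(p$stderr, 0.6)
  expect_equal(propensity_at(prof, -65)$value, 6.5)
  q <- propensity_at(prof, -63.7)
  expect_gte(q$value, 6); expect_lte(q$value, 6.5)
  expect_error(propensity_at(prof, 400), "outside")
  prof$mask[5] <- TRUE
  expect_error(propensity_at(prof, centers[5] + 1), "masked")
})

test_that("discrimination gap reproduces tabulated reference arithmetic", {
  # class I: aA:aT 8.36 +/- 0.08, aG:aC 10.21 +/- 0.10, aG/aT 5.25 +/- 0.11
  gt <- list(value = 5.25, stderr = 0.11)
  g1 <- discrimination_gap(list(value = 8.36, stderr = 0.08), gt)
  expect_equal(g1$gap, 3.11)
  expect_equal(round(g1$stderr, 2), 0.14)
  g2 <- discrimination_gap(list(value = 10.21, stderr = 0.10), gt)
  expect_equal(g2$gap, 4.96)
  # H1: aA:aT 10.03, aG/aT 8.08 -> 1.95; H3: 9.22 - 6.64 -> 2.58
  expect_equal(discrimination_gap(list(value = 10.03, stderr = 0.07),
                                  list(value = 8.08, stderr = 0.12))$gap, 1.95)
  expect_equal(discrimination_gap(list(value = 9.22, stderr = 0.06),
                                  list(value = 6.64, stderr = 0.08))$gap, 2.58)
  # min-over-canonicals threshold variant
  gmin <- discrimination_gap(list(list(value = 10.21, stderr = 0.10),
                                  list(value = 8.36, stderr = 0.08)), gt)
  expect_equal(gmin$gap, 3.11)
  # identical profiles: zero gap, sqrt(2) e
  same <- list(value = 4, stderr = 0.1)
  g0 <- discrimination_gap(same, same)
  expect_equal(g0$gap, 0)
  expect_equal(g0$stderr, sqrt(2) * 0.1)
})

test_that("elastic-constant fit recovers quadratic bending profiles", {
  centers <- seq(120, 180, 2)
  mkprof <- function(v, se = rep(0.01, length(centers))) {
    structure(list(axis = "alpha", centers = centers, value = v, stderr = se,
                   mask = rep(FALSE, length(centers)), temperature = 300,
                   periodic = FALSE), class = "fe_profile")
  }
  exact <- mkprof(0.5 * 0.01 * (centers - 160)^2)
  fit <- fit_elastic_constant(exact)
  expect_equal(fit$k, 0.01, tolerance = 1e-6)
  expect_equal(fit$alpha0, 160, tolerance = 1e-6)
  # additive reference invariance
  fit2 <- fit_elastic_constant(mkprof(0.5 * 0.01 * (centers - 160)^2 + 7))
  expect_equal(fit2$k, fit$k, tolerance = 1e-9)
  # noisy recovery: median over 20 seeds within 10%
  ks <- vapply(1:20, function(s) {
    set.seed(700 + s)
    fit_elastic_constant(mkprof(0.5 * 0.01 * (centers - 160)^2 +
                                  rnorm(length(centers), sd = 0.05),
                                se = rep(0.05, length(centers))))$k
  }, numeric(1))
  expect_lt(abs(median(ks) - 0.01) / 0.01, 0.1)
  # non-convex data warns
  expect_warning(fit_elastic_constant(mkprof(-0.001 * (centers - 150)^2)),
                 "k <= 0")
})

test_that("overlay maps structures onto the surface", {
  can <- make_surface("canonical_like")
  sp <- grid_spec(can$domain$mins, can$domain$maxs, c(42, 14),
                  names = c("opening", "shear"))
  surf <- surface_on_grid(can, sp)
  dup <- build_duplex("GGTTAAATTAACC")
  at_min <- overlay_structures(surf, list(dup))
  expect_true(at_min$in_domain)
  expect_equal(at_min$value, 0)  # ideal pair sits in the global-minimum bin
  opened <- perturb_central_pair(dup, opening = -60, shear = 0.5)
  ov <- overlay_structures(surf, list(opened))
  expect_equal(ov$opening, -60, tolerance = 1e-6)
  expect_gt(ov$value, 1)
  # out-of-domain structure is flagged
  wild <- perturb_central_pair(dup, opening = 150)
  expect_false(overlay_structures(surf, list(wild))$in_domain)
  # masked region is reported
  surf$mask[] <- TRUE
  expect_true(overlay_structures(surf, list(dup))$masked)
})
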