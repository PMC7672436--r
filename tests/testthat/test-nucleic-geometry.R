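# Base frames, pair/step parameters, glycosidic classification, H-bonds.

std_residue <- function(base = "G", rotation = diag(3), translation = c(0, 0, 0)) {
  std <- standard_base_coords(base)
  xyz <- sweep(std %*% t(rotation), 2, translation, "+")
  atom_table(name = rownames(std), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             residue_name = paste0("D", base))
}

test_that("fit_base_frame recovers rigid placements exactly", {
  # self-fit: base at its embedded reference coordinates
  f <- fit_base_frame(std_residue("G"))
  expect_equal(f$origin, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(f$axes, diag(3), tolerance = 1e-10)
  # rigid transform: 30 degrees about z plus translation
  R <- rotation_about(c(0, 0, 1), 30)
  f2 <- fit_base_frame(std_residue("G", R, c(1, 2, 3)))
  expect_equal(f2$origin, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(t(f2$axes), R, tolerance = 1e-9)
  # orthonormality invariant
  expect_lt(max(abs(crossprod(f2$axes) - diag(3))), 1e-8)
})

test_that("fit_base_frame is stable under small coordinate noise", {
  set.seed(101)
  R <- rand_rotation(); tr <- rnorm(3, sd = 4)
  clean <- std_residue("A", R, tr)
  for (i in 1:100) {
    noisy <- clean
    noisy$x <- noisy$x + rnorm(nrow(noisy), sd = 0.01)
    noisy$y <- noisy$y + rnorm(nrow(noisy), sd = 0.01)
    noisy$z <- noisy$z + rnorm(nrow(noisy), sd = 0.01)
    f <- fit_base_frame(noisy)
    expect_lt(sqrt(sum((f$origin - tr)^2)), 0.05)
    # rotation angle between fitted and true axes < 1 degree
    rel <- t(f$axes) %*% t(R)   # R_fit %*% R_true^T
    tr_angle <- acos(pmin(1, (sum(diag(rel)) - 1) / 2)) * 180 / pi
    expect_lt(tr_angle, 1)
  }
  # cross-check the fit against an independent quaternion Kabsch
  noisy <- clean
  noisy$x <- noisy$x + rnorm(nrow(noisy), sd = 0.01)
  f <- fit_base_frame(noisy)
  ring <- pairscape:::.RING_ATOMS$A
  or <- kabsch_oracle(standard_base_coords("A")[ring, ],
                      coords(noisy)[match(ring, noisy$name), ])
  expect_equal(t(f$axes), or$rotation, tolerance = 1e-8)
})

test_that("fit_base_frame reports missing and degenerate input", {
  res <- std_residue("G")
  expect_error(fit_base_frame(res[res$name != "N7", ]), "N7")
  flat <- res
  flat$y <- flat$x; flat$z <- flat$x  # collinear
  expect_error(fit_base_frame(flat), "degenerate|collinear")
})

test_that("pair_frames matches its constructive examples", {
  ideal_b <- base_frame(axes = t(diag(c(1, -1, -1))))  # flips to identity
  p0 <- pair_frames(base_frame(), ideal_b)$params
  expect_lt(max(abs(params_vec(p0))), 1e-8)
  # +20 degrees about the mean normal -> opening +20
  fb <- base_frame(axes = t(pairscape:::.rot_z(20) %*% diag(c(1, -1, -1))))
  p1 <- pair_frames(base_frame(), fb)$params
  expect_equal(p1$opening, 20, tolerance = 1e-9)
  expect_lt(abs(p1$shear), 1e-6)
  # +1.5 A along the mean x -> shear 1.5, opening unchanged
  fb2 <- base_frame(origin = c(1.5, 0, 0), axes = t(diag(c(1, -1, -1))))
  p2 <- pair_frames(base_frame(), fb2)$params
  expect_equal(p2$shear, 1.5, tolerance = 1e-9)
  expect_equal(p2$opening, 0, tolerance = 1e-9)
  # contract error on a non-orthonormal frame
  bad <- base_frame()
  bad$axes[1, 1] <- 2
  expect_error(pair_frames(bad, ideal_b), "orthonormal")
})

test_that("step parameters recover constructed steps and round-trip", {
  f1 <- base_frame()
  s <- compute_step_params(f1, base_frame(origin = c(0, 0, 3.4)))
  expect_equal(s$rise, 3.4, tolerance = 1e-9)
  expect_equal(c(s$shift, s$slide, s$tilt, s$roll, s$twist), rep(0, 5),
               tolerance = 1e-9)
  f3 <- base_frame(origin = c(0, 0, 3.4), axes = t(pairscape:::.rot_z(36)))
  expect_equal(compute_step_params(f1, f3)$twist, 36, tolerance = 1e-9)
  # fiber-parameter round trip through a built duplex
  dup <- build_duplex("GCGCAT", step = step_params(shift = 0.3, slide = -0.5,
                                                   rise = 3.3, tilt = 2,
                                                   roll = 5, twist = 34))
  m1 <- measure_pair(dup, 2, 11)$mean_frame
  m2 <- measure_pair(dup, 3, 10)$mean_frame
  st <- compute_step_params(m1, m2)
  expect_equal(unlist(st[c("shift", "slide", "rise", "tilt", "roll", "twist")]),
               c(shift = 0.3, slide = -0.5, rise = 3.3, tilt = 2, roll = 5,
                 twist = 34), tolerance = 1e-6)
})

test_that("geometry round trip recovers 200 random parameter sets to 1e-6", {
  set.seed(7)
  for (i in 1:200) {
    p <- random_pair_params()
    at <- build_base_pair(sample(c("A", "C", "G", "T"), 1), p)
    out <- measure_pair(at, 1, 2, orientations = c("anti", "anti"))$params
    expect_lt(max(abs(params_vec(out) - params_vec(p))), TOL6)
  }
})

test_that("strand swap negates shear and buckle, preserves the rest", {
  # note: with the rigid-motion-invariant simple scheme the pure-Opening
  # configuration is congruent to its own strand swap, so Opening cannot
  # change sign; only the x-axis components (Shear, Buckle) are odd.
  set.seed(11)
  for (i in 1:25) {
    p <- random_pair_params()
    fr <- pairscape:::.pair_to_frames(base_frame(), p)
    fwd <- params_vec(pair_frames(fr$frame_a, fr$frame_b)$params)
    rev <- params_vec(pair_frames(fr$frame_b, fr$frame_a)$params)
    expect_equal(rev[c("shear", "buckle")], -fwd[c("shear", "buckle")],
                 tolerance = 1e-8)
    expect_equal(rev[c("stretch", "stagger", "propeller", "opening")],
                 fwd[c("stretch", "stagger", "propeller", "opening")],
                 tolerance = 1e-8)
  }
})

test_that("glycosidic classification follows chi and is rigid-invariant", {
  gc <- build_base_pair("G")
  g <- residue_atoms(gc, 1)
  cls <- classify_glycosidic(g)
  expect_equal(cls$chi, -120, tolerance = 1e-6)  # anti default
  expect_identical(cls$label, "anti")
  syn_pair <- build_base_pair("G", base_b = "G", orientations = c("anti", "syn"))
  cls2 <- classify_glycosidic(residue_atoms(syn_pair, 2))
  expect_equal(cls2$chi, 70, tolerance = 1e-6)
  expect_identical(cls2$label, "syn")
  # antipodal case: chi = 180 is anti
  res180 <- pairscape:::.place_base("A", base_frame(), chi = 180)
  expect_identical(classify_glycosidic(res180)$label, "anti")
  expect_equal(abs(classify_glycosidic(res180)$chi), 180, tolerance = 1e-6)
  # rigid-body invariance
  set.seed(5)
  for (i in 1:10) {
    moved <- transform_atoms(g, rand_rotation(), rnorm(3, sd = 10))
    expect_equal(classify_glycosidic(moved)$chi, cls$chi, tolerance = 1e-8)
  }
  expect_error(classify_glycosidic(g[g$name != "O4'", ]), "O4'")
})

test_that("hydrogen-bond detection counts WC bonds on built pairs", {
  expect_equal(nrow(detect_hbonds(build_base_pair("G"))), 3)
  expect_equal(nrow(detect_hbonds(build_base_pair("A"))), 2)
  far <- rbind_atoms(pairscape:::.place_base("G", base_frame(), residue_index = 1L),
                     pairscape:::.place_base("C", base_frame(origin = c(15, 0, 0)),
                                             residue_index = 2L))
  expect_equal(nrow(detect_hbonds(far)), 0)
  expect_error(detect_hbonds(build_base_pair("G"), roles = list()), "role table")
  # all reported distances satisfy the cutoff
  hb <- detect_hbonds(build_base_pair("G"))
  expect_true(all(hb$heavy_distance <= 3.1))
})

test_that("pair parameter table export covers every pair", {
  dup <- build_duplex("GCGAT")
  tab <- duplex_pair_params(dup)
  expect_equal(tab$pair_index, 1:5)
  expect_lt(max(abs(as.matrix(tab[, 2:7]))), 1e-8)
  expect_true(all(tab$scheme == "simple"))
})
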