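test_that("equipartition stiffness recovers a planted harmonic constant", {
  ts <- gen_harmonic_series(k0 = 20, n = 5000, seed = 101)
  expect_equal(extensional_stiffness(ts), 20, tolerance = 0.05)
  ## inverse proportionality to the variance
  y <- ts$y
  doubled <- time_series(ts$t, mean(y) + sqrt(2) * (y - mean(y)), "nm")
  expect_equal(extensional_stiffness(doubled),
               extensional_stiffness(ts) / 2, tolerance = 1e-12)
  expect_error(extensional_stiffness(rep(3, 100)), "zero variance")
  expect_error(extensional_stiffness(1), "2 samples")
})

test_that("stiffness error shrinks roughly like n^(-1/2)", {
  rel_err <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      abs(extensional_stiffness(gen_harmonic_series(k0 = 35, n = n, seed = s)) - 35) / 35
    }, numeric(1)))
  }
  e_small <- rel_err(400, 1:30)
  e_big <- rel_err(25600, 1:30)
  ## n grows by 64, so the error should drop by ~8 (allow a wide band)
  ratio <- e_small / e_big
  expect_gt(ratio, 4)
  expect_lt(ratio, 16)
})

test_that("block averaging reports consistent per-block stiffness", {
  ts <- gen_harmonic_series(k0 = 12, n = 5000, dt = 0.01, seed = 7)
  est <- block_stiffness(ts, n_blocks = 5, block_len = 10)  # 10 ns, 1000 pts
  expect_s3_class(est, "stiffness_estimate")
  expect_length(est$k_blocks, 5)
  pooled <- extensional_stiffness(ts)
  ## block means scatter around the pooled estimate within sampling error
  expect_true(all(abs(est$k_blocks - pooled) / pooled < 0.2))
  expect_equal(est$mean, pooled, tolerance = 0.05)
  ## one block is the plain estimator
  expect_equal(block_stiffness(ts, n_blocks = 1)$mean, pooled)
  expect_error(block_stiffness(ts, n_blocks = 10, block_len = 10),
               "insufficient")
})

test_that("departure energy recovers analytic areas of synthetic pulling curves", {
  ## linear ramp to (10 nm, 100 pN): triangle area 500 pN nm
  tri <- gen_force_extension(rbind(c(0, 0), c(10, 100), c(12, 5)),
                             noise_sd = 0, n = 2000)
  e <- departure_energy(tri$force, tri$extension)
  expect_equal(as.numeric(e), 500, tolerance = 1e-3)
  expect_equal(attr(e, "peak_force"), 100, tolerance = 1e-3)

  ## two-segment sawtooth of known area up to the first peak
  saw <- gen_force_extension(rbind(c(0, 0), c(2, 60), c(5, 80), c(6, 10),
                                   c(9, 70)),
                             noise_sd = 0, n = 4000)
  e2 <- departure_energy(saw$force, saw$extension)
  expect_equal(as.numeric(e2), saw$area_to_vertex[3], tolerance = 0.01)
  ## linearity: doubling the force doubles the energy
  f2 <- time_series(saw$force$t, 2 * saw$force$y, "pN")
  e3 <- departure_energy(f2, saw$extension)
  expect_equal(as.numeric(e3), 2 * as.numeric(e2), tolerance = 1e-9)
})

test_that("departure energy stays within 1% on noisy curves and flags missing peaks", {
  saw <- gen_force_extension(rbind(c(0, 0), c(5, 80), c(6, 30), c(9, 60)),
                             noise_sd = 1.5, seed = 21, n = 4000)
  e <- departure_energy(saw$force, saw$extension)
  expect_equal(as.numeric(e), saw$area_to_vertex[2], tolerance = 0.01)
  ## monotone falling curve has no detectable peak above threshold
  flat <- gen_force_extension(rbind(c(0, 100), c(10, 1)), noise_sd = 0)
  expect_error(departure_energy(flat$force, flat$extension), "peak")
  ## mismatched time bases are rejected
  other <- time_series(saw$force$t + 0.5, saw$force$y, "pN")
  expect_error(departure_energy(other, saw$extension), "time base")
})

test_that("hydrogen-bond detection applies both geometric cutoffs", {
  mk <- function(r_da, dev_deg) {
    delta <- dev_deg * pi / 180
    coords <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(NA, NA, NA))
    ## place acceptor at the requested D-A distance and deviation
    f <- function(r_ha) {
      a <- c(0.1 + r_ha * cos(delta), r_ha * sin(delta), 0)
      sqrt(sum(a^2)) - r_da
    }
    r_ha <- uniroot(f, c(1e-4, 2))$root
    coords[3, ] <- c(0.1 + r_ha * cos(delta), r_ha * sin(delta), 0)
    toy_structure(coords, role = c("donor", "hydrogen", "acceptor"),
                  residue_id = c(1L, 1L, 2L),
                  dh_pairs = cbind(hydrogen = 2L, donor = 1L))
  }
  expect_equal(nrow(detect_hbonds(mk(0.34, 10))), 1)  # both criteria met
  expect_equal(nrow(detect_hbonds(mk(0.36, 0))), 0)   # distance fails
  expect_equal(nrow(detect_hbonds(mk(0.30, 40))), 0)  # angle fails
})

test_that("hydrogen-bond detection is invariant under rigid motion", {
  st <- gen_hbond_set(4, 3, 3, seed = 5)
  base <- detect_hbonds(st)
  set.seed(99)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  st2 <- st
  st2$coords <- st$coords %*% t(Q) + matrix(c(5, -3, 2), nrow(st$coords), 3,
                                            byrow = TRUE)
  moved <- detect_hbonds(st2)
  expect_equal(moved[c("donor", "hydrogen", "acceptor")],
               base[c("donor", "hydrogen", "acceptor")])
})

test_that("radius of gyration matches closed-form geometries", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  two <- rbind(c(0, 0, 0), c(4, 0, 0))
  expect_equal(radius_of_gyration(two), 2)  # d/2 for equal masses
  th <- 2 * pi * (0:999) / 1000
  ring <- cbind(3 * cos(th), 3 * sin(th), 0)
  expect_equal(radius_of_gyration(ring), 3, tolerance = 0.01)
  expect_error(radius_of_gyration(two, masses = c(1, -1)), "positive")
})

test_that("inertia-axis angles recover planted rotations", {
  rod <- function(dir) {
    s <- seq(-5, 5, length.out = 200)
    outer(s, dir) + matrix(rnorm(600, 0, 0.01), 200, 3)
  }
  set.seed(4)
  a <- rod(c(1, 0, 0))
  expect_lt(inertia_axis_angle(a, coords_b = rod(c(1, 0, 0))), 0.5)
  expect_equal(inertia_axis_angle(a, coords_b = rod(c(0, 1, 0))), 90,
               tolerance = 0.5)
  ## known 37 degree rotation about z
  th <- 37 * pi / 180
  b <- rod(c(cos(th), sin(th), 0))
  expect_equal(inertia_axis_angle(a, coords_b = b), 37, tolerance = 0.1)
  ## spherically symmetric body has no principal axis
  set.seed(8)
  blob <- matrix(rnorm(3000), 1000, 3)
  expect_error(inertia_axis_angle(blob, coords_b = a), "degenerate")
})

test_that("obtuse planted angles need the directed (reference) convention", {
  st <- gen_two_domain(151.4, n_atoms = 400, seed = 3)
  i1 <- st$residue_id == 1L
  ang <- inertia_axis_angle(st$coords[i1, ], st$masses[i1],
                            st$coords[!i1, ], st$masses[!i1],
                            ref_a = attr(st, "axis_a"),
                            ref_b = attr(st, "axis_b"))
  expect_equal(ang, 151.4, tolerance = 1)
  ## folded convention reports the supplement
  folded <- inertia_axis_angle(st$coords[i1, ], st$masses[i1],
                               st$coords[!i1, ], st$masses[!i1])
  expect_equal(folded, 180 - 151.4, tolerance = 1)
})

test_that("punctual stress sums absolute Coulomb pair forces per residue", {
  ## two unit charges 1 nm apart in different residues
  st <- toy_structure(rbind(c(0, 0, 0), c(1, 0, 0)), charges = c(1, 1),
                      residue_id = c(1L, 2L))
  ps <- punctual_stress(st, cutoff = 1.2)
  expect_equal(unname(ps), rep(138.935458, 2), tolerance = 1e-6)
  ## 1/r^2 scaling for an isolated pair
  st2 <- toy_structure(rbind(c(0, 0, 0), c(0.5, 0, 0)), charges = c(1, 1),
                       residue_id = c(1L, 2L))
  expect_equal(unname(punctual_stress(st2))[1], 138.935458 / 0.25,
               tolerance = 1e-6)
  ## mirror-symmetric charge configuration gives equal stresses
  st3 <- toy_structure(rbind(c(-0.5, 0, 0), c(-0.3, 0, 0),
                             c(0.3, 0, 0), c(0.5, 0, 0)),
                       charges = c(0.4, -0.2, -0.2, 0.4),
                       residue_id = c(1L, 1L, 2L, 2L))
  ps3 <- punctual_stress(st3)
  expect_equal(ps3[["1"]], ps3[["2"]])
  ## neutral structures carry no stress; coincident atoms are an error
  st4 <- toy_structure(rbind(c(0, 0, 0), c(1, 0, 0)),
                       residue_id = c(1L, 2L))
  expect_equal(unname(punctual_stress(st4)), c(0, 0))
  st5 <- toy_structure(rbind(c(0, 0, 0), c(0, 0, 0)), charges = c(1, 1),
                       residue_id = c(1L, 2L))
  expect_error(punctual_stress(st5), "r = 0")
})

test_that("condition comparison runs KS normality plus the paired signed-rank test", {
  set.seed(12)
  a <- rnorm(100, 10, 1)
  same <- compare_conditions(a, a)
  expect_false(same$different)
  expect_equal(same$wilcoxon_p, 1)
  shifted <- compare_conditions(a, a + 5)
  expect_true(shifted$different)
  expect_lt(shifted$wilcoxon_p, 0.05)
  ## clearly non-normal sample flagged by the KS branch
  skew <- compare_conditions(exp(rnorm(100, 0, 1.5)), a)
  expect_lt(skew$ks_p_a, 0.05)
  expect_error(compare_conditions(a, a, alpha = 1.2), "alpha")
  expect_error(compare_conditions(1:3, 1:3), "n < 5")
  expect_error(compare_conditions(1:10, 1:9), "equal-length")
})
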