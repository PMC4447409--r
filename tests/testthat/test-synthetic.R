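test_that("label volumes carry one distinct code per ellipsoid", {
  labs <- make_label_volume(c(20, 20, 10), list(
    ellipsoid_spec("T_RFA", c(5, 5, 5), c(2, 2, 2)),
    ellipsoid_spec("T_RESIDUAL", c(14, 5, 5), c(2, 2, 2)),
    ellipsoid_spec("T_CONTROL", c(5, 14, 5), c(2, 2, 2)),
    ellipsoid_spec("NORMAL", c(14, 14, 5), c(2, 2, 2))))
  expect_setequal(setdiff(unique(as.vector(labs)), 0L), 1:4)
  expect_identical(dim(labs), c(20L, 20L, 10L))
})

test_that("empty, overlapping and out-of-bounds geometry are handled", {
  expect_identical(make_label_volume(c(5, 5, 5)), array(0L, dim = c(5, 5, 5)))
  expect_error(make_label_volume(c(20, 20, 10), list(
    ellipsoid_spec("T_RFA", c(5, 5, 5), c(3, 3, 3)),
    ellipsoid_spec("T_RESIDUAL", c(7, 5, 5), c(3, 3, 3)))), "overlap")
  expect_error(make_label_volume(c(10, 10, 5), list(
    ellipsoid_spec("T_RFA", c(1, 5, 3), c(2, 2, 2)))), "outside")
  expect_error(make_label_volume(c(0, 5, 5)), "positive")
})

test_that("rician noise contract: identity at sigma 0, Rayleigh mean at 0 signal", {
  x <- matrix(runif(20, 1, 5), 4)
  expect_identical(rician(x, 0), x)
  set.seed(1)
  m <- mean(rician(rep(0, 1e6), 1))
  # Rayleigh mean = sigma * sqrt(pi/2); SE of the sample mean ~ 6.5e-4
  expect_lt(abs(m - sqrt(pi / 2)), 3e-3)
  expect_error(rician(x, -1), "non-negative")
  expect_error(rician(-x, 1), "non-negative")
  set.seed(42); a <- rician(x, 0.5)
  set.seed(42); b <- rician(x, 0.5)
  expect_identical(a, b)
  expect_true(all(a >= 0))
})

test_that("simulated subjects honour the acquisition contract", {
  proto <- noiseless_protocol()
  s <- simulate_subject(protocol = proto, sampling_mode = "FIXED_MEAN",
                        shape = c(16L, 16L, 8L),
                        geometry = default_geometry(c(16L, 16L, 8L), c(2, 2, 1.5)))
  expect_equal(dim(s$dwi$BEFORE)[4], length(proto$b_values))
  expect_true(all(s$dwi$AFTER >= 0))
  # every labelled code appears in the realized truth
  codes <- setdiff(unique(as.vector(s$labels)), 0L)
  expect_setequal(names(tissue_classes())[match(codes, tissue_classes())],
                  unique(s$truth$class))
  # noiseless b=0 voxel signal equals S0 exactly
  b0 <- s$dwi$AFTER[, , , 1]
  expect_true(all(b0[s$labels > 0] == s$truth$S0[1]))
  # realized Kep obeys the Tofts identity
  expect_equal(s$truth$Kep, s$truth$Ktrans / s$truth$Ve, tolerance = 1e-12)
})

test_that("sampling mode and seed rules are enforced", {
  expect_error(simulate_subject(sampling_mode = "SAMPLED", seed = NULL),
               "seed is required")
  expect_error(simulate_subject(protocol = default_protocol(),
                                sampling_mode = "FIXED_MEAN", seed = NULL),
               "seed is required")  # noise on still needs a seed
  expect_error(simulate_subject(sampling_mode = "BOGUS", seed = 1),
               "arg")
})

test_that("cohorts are deterministic in the master seed", {
  geom <- default_geometry(c(16L, 16L, 8L), c(2, 2, 1.5))
  c1 <- simulate_cohort(2, shape = c(16L, 16L, 8L), geometry = geom,
                        master_seed = 3L)
  c2 <- simulate_cohort(2, shape = c(16L, 16L, 8L), geometry = geom,
                        master_seed = 3L)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  expect_length(c1, 2)
  # single-subject cohort equals simulate_subject at the derived seed
  c3 <- simulate_cohort(1, shape = c(16L, 16L, 8L), geometry = geom,
                        master_seed = 3L)
  s <- simulate_subject(shape = c(16L, 16L, 8L), geometry = geom,
                        sampling_mode = "SAMPLED",
                        seed = ivimablate:::subject_seed(3L, 1),
                        subject_id = "subj01")
  expect_identical(serialize(c3[[1]], NULL), serialize(s, NULL))
  expect_error(simulate_cohort(0), "n_subjects")
})

test_that("SAMPLED per-class means converge to the table means across subjects", {
  gt <- default_ground_truth()
  set.seed(2)
  n <- 400
  f <- draw_parameter(gt, "T_CONTROL", "BEFORE", "f", n)
  e <- gt_lookup(gt, "T_CONTROL", "BEFORE", "f")
  expect_lt(abs(mean(f) - e$mean), 3 * e$sd / sqrt(n))
})
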