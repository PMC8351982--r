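test_that("bundled parameter table reproduces the published values", {
  specs <- default_specs()
  expect_s3_class(specs, "cea_parameters")
  expect_equal(nrow(specs), 25L)
  expect_equal(specs$id, 1:25)
  expect_equal(specs$mean[specs$id == 1], 0.048)
  expect_equal(specs$se[specs$id == 1], 0.005944)
  expect_equal(specs$dist_family[specs$id == 1], "beta")
  expect_equal(specs$mean[specs$id == 4], 0.244)
  expect_equal(specs$source_duration_years[specs$id == 4], 6)
  expect_equal(specs$mean[specs$id == 18], 93440)
  expect_equal(specs$dist_family[specs$id == 18], "gamma")
  expect_equal(specs$mean[specs$id == 22], -0.07)
  expect_equal(specs$mean[specs$id == 25], 10000)
  expect_equal(specs$dist_family[specs$id == 25], "deterministic")
})

test_that("parameter table validation flags broken schemas", {
  specs <- as.data.frame(default_specs())
  expect_error(coilcea:::validate_parameter_table(specs[-3, ]),
               "25 rows")
  dup <- specs
  dup$id[2] <- 1
  expect_error(coilcea:::validate_parameter_table(dup), "duplicate id")
  bad <- specs
  bad$mean[bad$id == 4] <- "high"
  expect_error(coilcea:::validate_parameter_table(bad), "non-numeric")
  bad <- specs
  bad$mean[bad$id == 7] <- 1.4
  expect_error(coilcea:::validate_parameter_table(bad), "outside")
  expect_error(load_parameter_table("no/such/file.csv"), "not found")
})

test_that("beta moment matching hits the printed mean and variance", {
  ab <- beta_from_moments(0.5, 0.05)
  expect_equal(unname(ab), c(49.5, 49.5))
  ab <- beta_from_moments(0.048, 0.005944)
  expect_equal(ab[["alpha"]], 62.03, tolerance = 0.01)
  expect_equal(ab[["beta"]], 1230.3, tolerance = 0.01)
  # oracle: recover both moments by numerical integration of the density
  mom <- function(k) {
    integrate(function(x) x^k * dbeta(x, ab[["alpha"]], ab[["beta"]]),
              0, 1, rel.tol = 1e-10)$value
  }
  expect_equal(mom(1), 0.048, tolerance = 1e-7)
  expect_equal(mom(2) - mom(1)^2, 0.005944^2, tolerance = 1e-9)
  expect_error(beta_from_moments(0.2, 0.5), "infeasible")
  expect_error(beta_from_moments(1.2, 0.1), "mean")
})

test_that("gamma moment matching hits the printed mean and variance", {
  gp <- gamma_from_moments(1, 1)
  expect_equal(unname(gp), c(1, 1))
  gp <- gamma_from_moments(93440, 539)
  expect_equal(gp[["shape"]], 30053.02, tolerance = 1e-4)
  expect_equal(gp[["scale"]], 3.109172, tolerance = 1e-6)
  set.seed(1)
  x <- rgamma(2e5, shape = gp[["shape"]], scale = gp[["scale"]])
  expect_lt(abs(mean(x) - 93440), 4 * 539 / sqrt(2e5))
  expect_error(gamma_from_moments(10, 0), "must be > 0")
})

test_that("cycle conversion of quoted probabilities is exact and monotone", {
  expect_equal(per_cycle_probability(0, 6), 0)
  expect_equal(per_cycle_probability(0.244, 6), 0.0230399,
               tolerance = 1e-5)
  expect_equal(per_cycle_probability(0.014, 1), 0.0070247,
               tolerance = 1e-5)
  # quoted period equal to the cycle: identity
  expect_identical(per_cycle_probability(0.3, 0.5), 0.3)
  # per-event probabilities pass through unchanged
  expect_identical(per_cycle_probability(0.124, 0), 0.124)
  # monotone in p and in cycle length
  p <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(per_cycle_probability(p, 6)) > 0))
  expect_lt(per_cycle_probability(0.244, 6, 0.25),
            per_cycle_probability(0.244, 6, 0.5))
  # two half-cycles compose to the one-cycle probability
  half <- per_cycle_probability(0.244, 6, 0.25)
  full <- per_cycle_probability(0.244, 6, 0.5)
  expect_equal(1 - (1 - half)^2, full, tolerance = 1e-12)
  expect_error(per_cycle_probability(1, 6), "degenerate")
})

test_that("truncated-normal sampling preserves printed marginal means", {
  specs <- default_specs()
  set.seed(11)
  # the fatal-complication cost has SE comparable to its mean, so naive
  # truncation at 0 would inflate its mean by ~20%
  grp <- specs[specs$order_group %in% "coil_cost", ]
  x <- sample_ordered_truncated_normal_group(grp, 4e4, method = "quantile")
  for (j in seq_len(3)) {
    expect_lt(abs(mean(x[, j]) - grp$mean[order(grp$order_rank)][j]),
              4 * grp$se[order(grp$order_rank)][j] / sqrt(4e4))
  }
})

test_that("group ordering is enforced by rejection and by shared quantiles", {
  specs <- default_specs()
  set.seed(12)
  x <- sample_ordered_truncated_normal_group(
    specs[specs$order_group %in% "coil_cost", ], 5e3,
    method = "rejection")
  expect_true(all(x[, 1] <= x[, 2] & x[, 2] <= x[, 3]))
  # utilities: quantile curves never cross in practice
  u <- sample_ordered_truncated_normal_group(
    specs[specs$order_group %in% "utility", ], 2e4, method = "quantile")
  expect_true(all(u[, 1] <= u[, 2] & u[, 2] <= u[, 3]))
  # degenerate group (all SEs zero) returns the means
  degen <- specs[specs$order_group %in% "care_cost", ]
  degen$se <- 0
  d <- sample_ordered_truncated_normal_group(degen, 5)
  expect_true(all(d == rep(sort(degen$mean), each = 5)))
  expect_error(sample_ordered_truncated_normal_group(
    specs[specs$id %in% c(12, 15), ], 5), "single order_group")
})

test_that("joint draws match every printed moment and invariant", {
  specs <- default_specs()
  set.seed(21)
  d <- sample_draws(specs, hti_efficacy("uniform01"), 1e5)
  for (id in c(1:11, 18)) {
    key <- paste0("v", id)
    sp <- specs[specs$id == id, ]
    expect_lt(abs(mean(d[[key]]) - sp$mean), 4 * sp$se / sqrt(1e5))
  }
  # disutility: negative decrement with Beta magnitude of mean 0.07
  expect_true(all(d$v22 <= 0))
  expect_lt(abs(mean(d$v22) + 0.07), 4 * 0.04082 / sqrt(1e5))
  expect_true(all(d$v22 >= -1))
  # base-case efficacy: uniform on [0, 1] with expectation 1/2
  expect_true(all(d$rrr >= 0 & d$rrr <= 1))
  expect_lt(abs(mean(d$rrr) - 0.5), 0.003)
  # probability draws live in [0, 1]; joint outcome splits feasible
  for (id in 1:11) expect_true(all(d[[paste0("v", id)]] >= 0 &
                                     d[[paste0("v", id)]] <= 1))
  expect_true(all(d$v1 + d$v2 + d$v3 < 1))
  expect_true(all(d$v9 + d$v10 + d$v11 < 1))
  # ordered utility group holds jointly
  expect_true(all(d$v21 <= d$v20 & d$v20 <= d$v19))
})

test_that("efficacy specs sample their stated supports", {
  expect_true(all(coilcea:::sample_rrr(hti_efficacy("fixed",
                                                    fixed_value = 0),
                                       100) == 0))
  set.seed(3)
  x <- coilcea:::sample_rrr(hti_efficacy("bounded_normal", mu = 0.1,
                                         sigma = 0.2), 2e4)
  expect_true(all(x >= 0 & x <= 1))
  expect_error(hti_efficacy("bounded_normal", sigma = -1), "sigma")
  expect_error(hti_efficacy("fixed", fixed_value = 2), "fixed_value")
})

test_that("draws are reproducible and overrides are applied", {
  specs <- default_specs()
  d1 <- sample_draw(specs, hti_efficacy("uniform01"), seed = 5)
  d2 <- sample_draw(specs, hti_efficacy("uniform01"), seed = 5)
  expect_identical(d1, d2)
  set.seed(6)
  d <- sample_draws(specs, hti_efficacy("uniform01"), 50,
                    fixed = list(v4 = 0.3158, rrr = 0.25))
  expect_true(all(d$v4 == 0.3158))
  expect_true(all(d$rrr == 0.25))
  expect_error(sample_draws(specs, hti_efficacy("uniform01"), 5,
                            fixed = list(v99 = 1)), "unknown variable")
})
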