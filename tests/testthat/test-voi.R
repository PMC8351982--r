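test_that("the ICER is the ratio of mean increments", {
  # arm means mirroring the published base-case table
  psa <- make_psa(cost_std = c(313490, 313490),
                  qaly_std = c(18.130, 18.130),
                  cost_hti = c(320673, 320673),
                  qaly_hti = c(18.282, 18.282))
  expect_equal(icer(psa), 7183 / 0.152, tolerance = 1e-9)
  # identical arms: undefined, with a dominance diagnosis
  same <- make_psa(1, 1, 1, 1)
  expect_warning(v <- icer(same), "identical")
  expect_true(is.na(v))
  dominated <- make_psa(1, 1, 2, 1)
  expect_warning(icer(dominated), "dominated")
  # equal costs with a QALY gain: ICER collapses to zero
  free <- make_psa(10, 1, 10, 2)
  expect_equal(icer(free), 0)
})

test_that("CEAC points count strictly positive net benefit", {
  psa <- make_psa(cost_std = c(0, 0, 0), qaly_std = c(0, 0, 0),
                  cost_hti = c(10, 20, 30), qaly_hti = c(1, 1, 1))
  expect_equal(ceac_point(psa, 0), 0)           # dC > 0 everywhere
  expect_equal(ceac_point(psa, 1e9), 1)         # dE > 0 everywhere
  # a tie (NMB exactly zero) is not cost-effective
  tie <- make_psa(0, 0, 50, 1)
  expect_equal(ceac_point(tie, 50), 0)
  expect_equal(ceac_point(tie, 51), 1)
  expect_error(ceac_point(psa, -1), ">= 0")
})

test_that("EVPI matches hand-enumerated two-strategy examples", {
  # NMB pairs {0, -1} and {0, +1}: perfect information is worth 0.5
  psa <- make_psa(cost_std = c(0, 0), qaly_std = c(0, 0),
                  cost_hti = c(1, -1), qaly_hti = c(0, 0))
  expect_equal(evpi_per_person(psa, 1), 0.5)
  # no parameter uncertainty: zero value of information
  flat <- make_psa(rep(5, 4), rep(1, 4), rep(4, 4), rep(1, 4))
  expect_equal(evpi_per_person(flat, 1000), 0)
  # never negative on random inputs
  set.seed(41)
  r <- make_psa(rnorm(200), rnorm(200), rnorm(200), rnorm(200))
  expect_true(all(evpi_per_person(r, c(0, 1, 10)) >= -1e-12))
})

test_that("population scaling is the plain product", {
  expect_equal(scale_to_population(1), 159250)
  expect_equal(scale_to_population(0), 0)
  pop <- population_spec(1000, 5)
  expect_equal(scale_to_population(2.5, pop), 12500)
  expect_equal(scale_to_population(12500, pop) / (1000 * 5), 12500)
  expect_error(population_spec(-1, 10), "positive")
})

test_that("EVPPI is bounded by EVPI and vanishes for fixed variables", {
  specs <- default_specs()
  cfg <- model_config()
  hti <- hti_efficacy("bounded_normal", mu = 0.5, sigma = 0.15)
  expect_warning(ev0 <- evppi(specs, hti, cfg, focal_id = 25L,
                              n_outer = 5, n_inner = 5),
                 "deterministic")
  expect_equal(ev0$per_person, 0)
  ev <- evppi(specs, hti, cfg, focal_id = 4L, n_outer = 30,
              n_inner = 120, lambda = c(50000, 150000), seed = 42)
  psa <- run_psa(specs, hti, cfg, 3000, seed = 43)
  evpi_ref <- evpi_per_person(psa, c(50000, 150000))
  mc_slack <- 3 * 200  # generous Monte Carlo allowance at this size
  expect_true(all(ev$per_person >= -1e-9))
  expect_true(all(ev$per_person <= evpi_ref + mc_slack))
  expect_equal(ev$population, ev$per_person * 159250)
  expect_error(evppi(specs, hti, cfg, focal_id = 99L), "unknown")
})

test_that("tornado entries move the ICER in the published direction", {
  specs <- default_specs()
  cfg <- model_config()
  to <- tornado_one_way(specs, hti_efficacy("uniform01"), cfg,
                        n_iterations = 600, seed = 44,
                        ids = c(4L, 17L, 22L))
  expect_equal(sort(to$id), c(4L, 17L, 22L))
  # more recanalization risk makes the adjunct better value
  r4 <- to[to$id == 4L, ]
  expect_lt(r4$icer_at_high, r4$icer_at_low)
  # costlier disability care likewise lowers the ICER
  r17 <- to[to$id == 17L, ]
  expect_lt(r17$icer_at_high, r17$icer_at_low)
  # a larger disutility magnitude (more negative value) lowers the ICER
  r22 <- to[to$id == 22L, ]
  expect_lt(r22$icer_at_high, r22$icer_at_low)
  expect_true(all(diff(to$span) <= 1e-9))  # sorted by span
})

test_that("the ICER rises with the discount rate on this model", {
  specs <- default_specs()
  cfg <- model_config()
  ds <- discount_rate_scenarios(specs, hti_efficacy("uniform01"), cfg,
                                rates = c(0, 0.015, 0.05),
                                n_iterations = 800, seed = 45)
  expect_equal(ds$rate, c(0, 0.015, 0.05))
  expect_true(all(diff(ds$icer) > 0))
  expect_error(discount_rate_scenarios(specs, hti_efficacy("uniform01"),
                                       cfg, rates = -0.01), ">= 0")
})

test_that("scenario ICERs fall as the expected efficacy rises", {
  specs <- default_specs()
  cfg <- model_config()
  sc <- scenario_rrr(specs, cfg, n_iterations = 700, seed = 46)
  expect_named(sc, c("10 (2)", "30 (5)", "50 (15)"))
  icers <- vapply(sc, `[[`, numeric(1), "icer")
  expect_true(all(diff(icers) < 0))
  # the low-efficacy scenario is (almost) never cost-effective at $50k
  expect_lt(sc[["10 (2)"]]$ceac$probability[1], 0.02)
  for (s in sc) {
    expect_true(all(s$ceac$probability >= 0 & s$ceac$probability <= 1))
    expect_true(all(s$evpi$per_person >= -1e-9))
  }
})

test_that("CEAC is non-decreasing in the threshold under common draws", {
  specs <- default_specs()
  cfg <- model_config()
  psa <- run_psa(specs, hti_efficacy("uniform01"), cfg, 800, seed = 47)
  lam <- seq(0, 200000, by = 20000)
  expect_true(all(diff(ceac_point(psa, lam)) >= 0))
})
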