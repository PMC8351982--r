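test_that("state enumeration is deterministic with one absorbing state", {
  cfg <- model_config()
  st <- enumerate_states(cfg)
  lay <- coilcea:::state_layout(cfg)
  expect_equal(nrow(st), lay$n_states)  # 12 cycles at risk + mature
  expect_equal(nrow(st), 12L * 13L + 12L + 12L + 1L)
  expect_equal(sum(st$kind == "dead"), 1L)
  expect_true("coiled(1,mRS0,0)" %in% st$label)  # the entry state
  expect_false(anyDuplicated(st$label) > 0)
  expect_identical(st, enumerate_states(cfg))
  # a lifelong-hazard configuration collapses the age dimension
  st_inf <- enumerate_states(model_config(recan_window_years = Inf))
  expect_equal(nrow(st_inf), 4L * 3L * 2L + 12L + 1L)
})

test_that("transition rows are stochastic for random draws and cycles", {
  specs <- default_specs()
  cfg <- model_config()
  set.seed(31)
  for (j in 1:5) {
    draw <- sample_draw(specs, hti_efficacy("uniform01"))
    for (cyc in c(0L, 21L, 59L)) {
      for (arm in c("standard", "hti")) {
        M <- build_transition_matrix(draw, cfg, cyc, arm)
        expect_true(all(M >= 0 & M <= 1))
        expect_equal(rowSums(M), setNames(rep(1, nrow(M)), rownames(M)),
                     tolerance = 1e-12)
        expect_equal(unname(M["dead", "dead"]), 1)
      }
    }
  }
  expect_error(build_transition_matrix(means_draw(), cfg, 60L), "cycle")
})

test_that("cohort propagation agrees with the transition matrix", {
  # one cycle of the vectorized engine must equal occupancy %*% matrix
  specs <- default_specs()
  cfg <- model_config(background_mortality = FALSE)
  draw <- sample_draw(specs, hti_efficacy("uniform01"), seed = 32)
  res <- run_cohort(draw, cfg, "hti")
  M <- build_transition_matrix(draw, cfg, 0L, "hti")
  expect_equal(unname(res$trace[2, ]), unname(res$trace[1, ] %*% M)[1, ],
               tolerance = 1e-12)
})

test_that("full recanalization protection empties the index-coil risk edge", {
  draw <- means_draw()
  draw$values[["v6"]] <- 0  # isolate recanalization from de novo risk
  cfg <- model_config()
  draw$rrr <- 1
  draw$values[["rrr"]] <- 1
  M <- build_transition_matrix(draw, cfg, 0L, "hti")
  expect_equal(unname(M["coiled(1,mRS0,0)", "unsecured(1,mRS0)"]), 0)
  # the standard arm keeps its recanalization risk
  M0 <- build_transition_matrix(draw, cfg, 0L, "standard")
  expect_gt(M0["coiled(1,mRS0,0)", "unsecured(1,mRS0)"], 0.009)
})

test_that("event-free cohort reproduces the closed-form annuity", {
  draw <- zero_event_draw()
  cfg <- flat_cfg()
  out <- run_cohort(draw, cfg, "standard")$outcome
  expect_equal(out$qaly, 30 * 0.87, tolerance = 1e-9)
  expect_equal(out$cost, 30013 + 30 * 11197, tolerance = 1e-9)
  expect_equal(out$qaly, out$qaly_undiscounted)
  # with discounting the totals can only shrink
  cfg2 <- model_config(discount_rate = 0.015,
                       background_mortality = FALSE,
                       utility_band_offsets = c(0, 0, 0, 0))
  out2 <- run_cohort(draw, cfg2, "standard")$outcome
  expect_lt(out2$qaly, out2$qaly_undiscounted)
  expect_lt(out2$cost, out2$cost_undiscounted)
})

test_that("discount factors and age-banded utilities follow their rules", {
  expect_equal(discount_factor(0, 0.015), 1)
  expect_equal(discount_factor(2, 0.015, 0.5), 1 / 1.015)
  expect_equal(discount_factor(0:10, 0), rep(1, 11))
  expect_error(discount_factor(1, -0.01), ">= 0")
  draw <- means_draw()
  expect_equal(age_band_utility(45, draw), 0.87)
  expect_equal(age_band_utility(54.9, draw), 0.87)
  expect_equal(age_band_utility(55, draw), 0.85)   # half-open bands
  expect_equal(age_band_utility(65, draw), 0.86)
  expect_equal(age_band_utility(80, draw), 0.84)
})

test_that("arms are identical to machine precision without the adjunct", {
  specs <- default_specs()
  cfg <- model_config()
  set.seed(33)
  d <- sample_draws(specs, hti_efficacy("fixed", fixed_value = 0), 50)
  std <- coilcea:::propagate_cohort(d, cfg, "standard", price = 0)
  adj <- coilcea:::propagate_cohort(d, cfg, "hti", price = 0)
  expect_identical(std$cost, adj$cost)
  expect_identical(std$qaly, adj$qaly)
})

test_that("the adjunct dominates under common random numbers at zero price", {
  specs <- default_specs()
  cfg <- model_config()
  set.seed(34)
  d <- sample_draws(specs, hti_efficacy("uniform01"), 400)
  std <- coilcea:::propagate_cohort(d, cfg, "standard", price = 0)
  adj <- coilcea:::propagate_cohort(d, cfg, "hti", price = 0)
  expect_true(all(adj$qaly >= std$qaly))
  expect_true(all(adj$cost <= std$cost))
})

test_that("cohort mass is conserved and death is absorbing", {
  specs <- default_specs()
  cfg <- model_config()
  set.seed(35)
  for (j in 1:8) {
    tab <- if (j <= 4) specs else random_parameter_table()
    draw <- sample_draw(tab, hti_efficacy("uniform01"))
    res <- run_cohort(draw, cfg, sample(c("standard", "hti"), 1))
    expect_true(all(abs(rowSums(res$trace) - 1) < 1e-10))
    expect_true(all(res$trace >= -1e-15))
    dead <- res$trace[, ncol(res$trace)]
    expect_true(all(diff(dead) >= -1e-12))
  }
})

test_that("discounted totals are non-increasing in the discount rate", {
  draw <- means_draw()
  rates <- c(0, 0.015, 0.05)
  outs <- lapply(rates, function(r) {
    run_cohort(draw, model_config(discount_rate = r), "hti")$outcome
  })
  expect_true(all(diff(vapply(outs, `[[`, numeric(1), "qaly")) < 0))
  expect_true(all(diff(vapply(outs, `[[`, numeric(1), "cost")) < 0))
  # undiscounted totals are unchanged by the rate
  expect_equal(outs[[1]]$qaly_undiscounted, outs[[3]]$qaly_undiscounted)
})

test_that("configuration validation rejects out-of-range settings", {
  expect_error(model_config(discount_rate = -0.01), ">= 0")
  expect_error(model_config(cycle_years = 0), "> 0")
  expect_error(model_config(thresholds = c(0, 50000)), "positive")
  expect_error(model_config(recan_window_years = 0), "> 0")
  expect_error(model_config(max_procedures = 3), "max_procedures")
  lt <- load_life_table()
  expect_true(all(diff(lt$age_low) > 0))
  bad <- lt
  bad$annual_mortality_probability[1] <- 1.2
  tf <- tempfile(fileext = ".csv")
  write.csv(bad, tf, row.names = FALSE)
  expect_error(load_life_table(tf), "probabilities")
})
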