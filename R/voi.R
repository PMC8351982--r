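# Cost-effectiveness and value-of-information analytics: ICER, CEAC,
# EVPI/EVPPI, population scaling, tornado and scenario analyses.

#' Target population for value-of-information scaling
#'
#' Defaults to the US estimate of 15,925 UIA coiling procedures per year
#' with a 10-year technology horizon; population scaling is an
#' undiscounted multiplication.
#'
#' @param procedures_per_year Annual number of index procedures.
#' @param horizon_years Years the technology would be used.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(procedures_per_year = 15925,
                            horizon_years = 10) {
  if (procedures_per_year <= 0 || horizon_years <= 0) {
    stop("population spec must be positive")
  }
  structure(list(procedures_per_year = procedures_per_year,
                 horizon_years = horizon_years),
            class = "population_spec")
}

#' Incremental cost-effectiveness ratio of a PSA
#'
#' Mean incremental discounted cost divided by mean incremental discounted
#' QALYs (HTI arm minus standard arm). When the mean incremental QALY is
#' (numerically) zero the ICER is undefined and `NA` is returned with a
#' warning reporting the dominance status.
#'
#' @param psa A [run_psa()] result.
#' @return USD per QALY (scalar).
#' @export
icer <- function(psa) {
  dc <- mean(psa$cost_hti) - mean(psa$cost_std)
  de <- mean(psa$qaly_hti) - mean(psa$qaly_std)
  scale <- max(mean(psa$qaly_std), 1)
  if (abs(de) < 1e-12 * scale) {
    status <- if (abs(dc) < 1e-9 * max(mean(psa$cost_std), 1)) {
      "arms are identical"
    } else if (dc > 0) "HTI arm is dominated (costlier, equal QALYs)"
    else "HTI arm dominates (cheaper, equal QALYs)"
    warning("ICER undefined: zero incremental QALYs; ", status)
    return(NA_real_)
  }
  dc / de
}

#' Probability of cost-effectiveness at a threshold
#'
#' Fraction of PSA iterations with positive incremental net monetary
#' benefit, `lambda * dQALY - dCost > 0` (ties count as not
#' cost-effective).
#'
#' @param psa A [run_psa()] result.
#' @param lambda Willingness-to-pay threshold(s), USD/QALY, >= 0.
#' @return Probability (vectorized over `lambda`).
#' @export
ceac_point <- function(psa, lambda) {
  if (any(lambda < 0)) stop("lambda must be >= 0")
  de <- psa$qaly_hti - psa$qaly_std
  dc <- psa$cost_hti - psa$cost_std
  vapply(lambda, function(l) mean(l * de - dc > 0), numeric(1))
}

#' Per-person expected value of perfect information
#'
#' `E[max_s NMB_s] - max_s E[NMB_s]` over the PSA iterations, with
#' `NMB_s = lambda * QALY_s - cost_s`. Non-negative up to floating error.
#'
#' @inheritParams ceac_point
#' @return USD per person (vectorized over `lambda`).
#' @export
evpi_per_person <- function(psa, lambda) {
  if (any(lambda < 0)) stop("lambda must be >= 0")
  vapply(lambda, function(l) {
    nmb_s <- l * psa$qaly_std - psa$cost_std
    nmb_h <- l * psa$qaly_hti - psa$cost_hti
    mean(pmax(nmb_s, nmb_h)) - max(mean(nmb_s), mean(nmb_h))
  }, numeric(1))
}

#' Scale a per-person value to the treated population
#'
#' Undiscounted multiplication by procedures per year and the technology
#' horizon.
#'
#' @param per_person USD per person.
#' @param pop A [population_spec()].
#' @export
scale_to_population <- function(per_person, pop = population_spec()) {
  per_person * pop$procedures_per_year * pop$horizon_years
}

#' Summarize a PSA into reportable cost-effectiveness outputs
#'
#' @param psa A [run_psa()] result.
#' @param config A [model_config()] (supplies thresholds).
#' @param pop A [population_spec()].
#' @return List of class `cea_summary`: per-arm means, ICER, CEAC and
#'   EVPI (per person and population-scaled) at each threshold.
#' @export
cea_summary <- function(psa, config, pop = population_spec()) {
  ev <- evpi_per_person(psa, config$thresholds)
  structure(list(
    cost_hti = mean(psa$cost_hti), cost_std = mean(psa$cost_std),
    qaly_hti = mean(psa$qaly_hti), qaly_std = mean(psa$qaly_std),
    icer = suppressWarnings(icer(psa)),
    ceac = data.frame(threshold = config$thresholds,
                      probability = ceac_point(psa, config$thresholds)),
    evpi = data.frame(threshold = config$thresholds, per_person = ev,
                      population = scale_to_population(ev, pop))),
    class = "cea_summary")
}

#' @export
print.cea_summary <- function(x, ...) {
  cat(sprintf("Mean discounted cost: HTI $%.0f | standard $%.0f\n",
              x$cost_hti, x$cost_std))
  cat(sprintf("Mean discounted QALY: HTI %.3f | standard %.3f\n",
              x$qaly_hti, x$qaly_std))
  cat(sprintf("ICER: $%.0f per QALY\n", x$icer))
  cat("CEAC:\n"); print(x$ceac, row.names = FALSE)
  cat("EVPI:\n"); print(x$evpi, row.names = FALSE)
  invisible(x)
}

#' Expected value of partial perfect information for one variable
#'
#' Brute-force two-level nested Monte Carlo. Outer loop: draws of the
#' focal variable from its own distribution. Inner loop: a PSA of
#' `n_inner` iterations conditional on the focal value (all other
#' variables stochastic, RRR from `hti`). Per-person EVPPI at threshold
#' lambda is `E_outer[max_s E_inner NMB_s] - max_s E[NMB_s]`; one nested
#' simulation is shared across all requested thresholds. For the
#' headline analysis the focal variable is the baseline recanalization
#' probability and the RRR follows a bounded normal with mean 0.50 and
#' SD 0.15.
#'
#' @inheritParams run_psa
#' @param focal_id Integer id of the focal variable (must be stochastic).
#' @param n_outer,n_inner Nested sample sizes (>= 2).
#' @param lambda Willingness-to-pay threshold(s), USD/QALY.
#' @param pop A [population_spec()].
#' @return `data.frame(lambda, per_person, population)` of class
#'   `evppi_result`, with attributes `focal_id`, `n_outer`, `n_inner`.
#' @export
evppi <- function(specs, hti, config, focal_id = 4L, n_outer = 500L,
                  n_inner = 500L, lambda = 50000, seed = NULL,
                  pop = population_spec()) {
  stopifnot(n_outer >= 2, n_inner >= 2)
  sp <- specs[specs$id == focal_id, , drop = FALSE]
  if (nrow(sp) != 1L) stop("unknown focal variable id ", focal_id)
  out <- data.frame(lambda = lambda, per_person = 0, population = 0)
  attr(out, "focal_id") <- focal_id
  attr(out, "n_outer") <- n_outer
  attr(out, "n_inner") <- n_inner
  class(out) <- c("evppi_result", "data.frame")
  if (sp$dist_family == "deterministic" || sp$se == 0) {
    warning("focal variable is deterministic; EVPPI is 0")
    return(out)
  }
  if (!is.null(seed)) set.seed(seed)
  outer_vals <- switch(
    sp$dist_family,
    beta = {
      m <- abs(sp$mean)
      ab <- beta_from_moments(m, sp$se)
      x <- rbeta(n_outer, ab[["alpha"]], ab[["beta"]])
      if (sp$mean < 0) -x else x
    },
    gamma = {
      gp <- gamma_from_moments(sp$mean, sp$se)
      rgamma(n_outer, shape = gp[["shape"]], scale = gp[["scale"]])
    },
    truncated_ordered_normal = {
      b <- natural_bounds(sp$group)
      rtruncnorm(n_outer, truncnorm_location(sp$mean, sp$se, b[1], b[2]),
                 sp$se, b[1], b[2])
    },
    uniform = runif(n_outer),
    stop("unsupported focal family: ", sp$dist_family)
  )
  key <- paste0("v", focal_id)
  # chunk the outer loop so one engine call covers many conditional PSAs;
  # per-outer means of cost/QALY per arm are kept so every threshold can
  # be evaluated from the same nested simulation
  chunk <- max(1L, min(n_outer, floor(50000 / n_inner)))
  mcs <- mqs <- mch <- mqh <- numeric(n_outer)
  o <- 1L
  while (o <= n_outer) {
    idx <- o:min(o + chunk - 1L, n_outer)
    fx <- setNames(list(rep(outer_vals[idx], each = n_inner)), key)
    psa <- run_psa(specs, hti, config,
                   n_iterations = length(idx) * n_inner, fixed = fx)
    g <- rep(seq_along(idx), each = n_inner)
    mcs[idx] <- tapply(psa$cost_std, g, mean)
    mqs[idx] <- tapply(psa$qaly_std, g, mean)
    mch[idx] <- tapply(psa$cost_hti, g, mean)
    mqh[idx] <- tapply(psa$qaly_hti, g, mean)
    o <- o + chunk
  }
  for (j in seq_along(lambda)) {
    nmb_s <- lambda[j] * mqs - mcs
    nmb_h <- lambda[j] * mqh - mch
    out$per_person[j] <- mean(pmax(nmb_s, nmb_h)) -
      max(mean(nmb_s), mean(nmb_h))
  }
  out$population <- scale_to_population(out$per_person, pop)
  out
}

#' Probabilistic one-way (tornado) sensitivity analysis
#'
#' For each variable with sensitivity bounds, reruns the full PSA twice
#' with that variable fixed at its lower and upper bound while all other
#' variables remain stochastic, and records both ICERs. Entries are
#' sorted by the ICER span.
#'
#' @inheritParams run_psa
#' @param ids Variable ids to perturb; default all rows with bounds.
#' @return `data.frame(id, name, low_value, high_value, icer_at_low,
#'   icer_at_high, span)` of class `tornado_entries`.
#' @export
tornado_one_way <- function(specs, hti, config, n_iterations = 2000L,
                            seed = NULL, ids = NULL) {
  has_b <- !is.na(specs$sens_low) & !is.na(specs$sens_high)
  if (is.null(ids)) ids <- specs$id[has_b]
  ids <- intersect(ids, specs$id[has_b])
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- setNames(sample.int(.Machine$integer.max - 1L,
                                   2L * length(ids)), NULL)
  out <- data.frame(id = ids, name = specs$name[match(ids, specs$id)],
                    low_value = specs$sens_low[match(ids, specs$id)],
                    high_value = specs$sens_high[match(ids, specs$id)],
                    icer_at_low = NA_real_, icer_at_high = NA_real_)
  for (j in seq_along(ids)) {
    key <- paste0("v", ids[j])
    lo <- run_psa(specs, hti, config, n_iterations,
                  seed = sub_seeds[2L * j - 1L],
                  fixed = setNames(list(out$low_value[j]), key))
    hi <- run_psa(specs, hti, config, n_iterations,
                  seed = sub_seeds[2L * j],
                  fixed = setNames(list(out$high_value[j]), key))
    out$icer_at_low[j] <- suppressWarnings(icer(lo))
    out$icer_at_high[j] <- suppressWarnings(icer(hi))
  }
  out$span <- abs(out$icer_at_high - out$icer_at_low)
  out <- out[order(-out$span), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tornado_entries", "data.frame")
  out
}

#' ICERs under alternative discount rates
#'
#' Reruns the PSA with each annual discount rate applied to both costs
#' and QALYs, everything else unchanged (the same seed gives common
#' draws across rates).
#'
#' @inheritParams run_psa
#' @param rates Annual discount rates.
#' @return `data.frame(rate, icer)`.
#' @export
discount_rate_scenarios <- function(specs, hti, config,
                                    rates = c(0, 0.03, 0.05),
                                    n_iterations = 7000L, seed = NULL) {
  if (any(rates < 0)) stop("rates must be >= 0")
  out <- data.frame(rate = rates, icer = NA_real_)
  for (j in seq_along(rates)) {
    cfg <- config
    cfg$discount_rate <- rates[j]
    psa <- run_psa(specs, hti, cfg, n_iterations, seed = seed)
    out$icer[j] <- suppressWarnings(icer(psa))
  }
  out
}

#' Scenario analyses over adjunct-efficacy distributions
#'
#' Reruns the PSA for each RRR distribution (by default bounded normals
#' with mean/SD 10\%/2\%, 30\%/5\% and 50\%/15\%), holding the adjunct
#' price at its configured value.
#'
#' @inheritParams run_psa
#' @param scenarios Named list of [hti_efficacy()] specs.
#' @param pop A [population_spec()].
#' @return Named list of [cea_summary()] objects.
#' @export
scenario_rrr <- function(specs, config,
                         scenarios = list(
                           "10 (2)" = hti_efficacy("bounded_normal",
                                                   mu = 0.10, sigma = 0.02),
                           "30 (5)" = hti_efficacy("bounded_normal",
                                                   mu = 0.30, sigma = 0.05),
                           "50 (15)" = hti_efficacy("bounded_normal",
                                                    mu = 0.50, sigma = 0.15)),
                         n_iterations = 7000L, seed = NULL,
                         pop = population_spec()) {
  out <- vector("list", length(scenarios))
  names(out) <- names(scenarios)
  for (j in seq_along(scenarios)) {
    psa <- run_psa(specs, scenarios[[j]], config, n_iterations, seed = seed)
    out[[j]] <- cea_summary(psa, config, pop)
  }
  out
}
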