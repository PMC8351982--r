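# Independent patient-level microsimulation and synthetic parameter
# tables: the verification layer for the cohort engine. The simulator
# re-derives the per-cycle outcome distributions and accrual rules with
# its own code (sharing only the probability time-scale conversion and
# the parameter draw), and steps individual patients instead of
# propagating expectations, so a structural bug must be introduced twice
# - once in the cohort engine and once here - to escape the cross-check.

#' Simulate individual patients through the state dynamics
#'
#' An individual-level Monte Carlo simulator with the same per-cycle
#' transition probabilities and accrual rules as the cohort engine, but
#' an independent implementation: each patient carries their procedure
#' count, functional status and cycles-since-last-procedure, and samples
#' a path over the full horizon. Used to validate [run_cohort()] (the
#' microsimulation mean converges to the cohort expectation).
#'
#' @param draw A `parameter_draw`.
#' @param config A [model_config()].
#' @param strategy `"standard"` or `"hti"`.
#' @param n_patients Number of simulated patients.
#' @param seed Optional integer seed.
#' @param price Price at cycle 0; defaults as in [run_cohort()].
#' @return List: `mean_cost`, `mean_qaly`, `se_cost`, `se_qaly`,
#'   `n_patients`.
#' @export
simulate_patients <- function(draw, config,
                              strategy = c("standard", "hti"),
                              n_patients = 10000L, seed = NULL,
                              price = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(n_patients >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(price)) price <- if (strategy == "hti") config$hti_price else 0
  v <- as_draws(draw)
  stopifnot(nrow(v) == 1L)
  n <- as.integer(n_patients)
  cy <- config$cycle_years
  rate <- config$discount_rate
  m_cyc <- cycle_mortality(config)
  w <- if (is.infinite(config$recan_window_years)) Inf else
    max(1L, as.integer(round(config$recan_window_years / cy)))
  dur <- attr(v, "durations")
  dget <- function(key, default) {
    if (!is.null(dur) && key %in% names(dur)) dur[[key]] else default
  }
  conv <- if (identical(config$probability_conversion, "constant_hazard"))
    per_cycle_probability
  else
    function(p, duration, cycle_years) p * cycle_years / duration
  recan <- conv(v$v4, dget("v4", 6), cy)
  denovo <- conv(v$v6, dget("v6", 1), cy)
  rupture <- conv(v$v7, dget("v7", 1), cy)
  ret_q <- if (config$retreat_conditional) {
    min(v$v5 / max(v$v4, 1e-12), 1)
  } else {
    v$v5
  }
  retreat <- conv(ret_q, dget("v5", 6), cy)
  split4 <- c(1 - v$v1 - v$v2 - v$v3, v$v1, v$v2, v$v3)
  proc_cost <- c(v$v12, v$v13, v$v13, v$v14)
  asah_p <- c(v$v8 + (1 - v$v8) * v$v9,
              (1 - v$v8) * (1 - v$v9 - v$v10 - v$v11),
              (1 - v$v8) * v$v10, (1 - v$v8) * v$v11)
  care <- c(v$v15, v$v16, v$v17) * cy
  h <- function(p) -log1p(-p)

  # patient state: kind 1 coiled / 2 unsecured / 3 aSAH tunnel / 4 dead
  kind <- rep(1L, n)
  i <- rep(1L, n)
  ap <- rep(0L, n)  # cycles since last procedure
  o <- sample.int(4L, n, replace = TRUE, prob = split4)
  s <- c(1L, 2L, 3L, 1L)[o]
  kind[o == 4L] <- 4L
  cost <- price + proc_cost[o]
  qaly <- numeric(n)

  for (k in 0:(config$n_cycles - 1L)) {
    band <- utility_band(config$start_age + k * cy)
    u3 <- c(v$v19 + config$utility_band_offsets[band], v$v20, v$v21)
    df_k <- (1 + rate)^(-k * cy)
    df_k1 <- (1 + rate)^(-(k + 1L) * cy)
    ic <- kind == 1L
    iu <- kind == 2L
    it <- kind == 3L
    qaly[ic] <- qaly[ic] + df_k * cy * u3[s[ic]]
    qaly[iu] <- qaly[iu] + df_k * cy * (u3[s[iu]] + v$v22)
    qaly[it] <- qaly[it] + df_k * cy * v$v23
    cost[ic | iu] <- cost[ic | iu] + df_k * care[s[ic | iu]]
    # expected hospital cost per rupture (pre-hospital deaths incur none)
    cost[it] <- cost[it] + df_k * (1 - v$v8) * v$v18
    m <- m_cyc[k + 1L]
    nk <- kind; ni <- i; ns <- s; nap <- ap

    idx <- which(ic)
    if (length(idx)) {
      at_risk <- is.infinite(w) | ap[idx] < w
      rrr_eff <- if (strategy == "hti") v$rrr else 0
      r_later <- if (config$recan_later_procedures) recan else 0
      r <- ifelse(i[idx] == 1L, recan * (1 - rrr_eff), r_later) * at_risk
      he <- h(r) + h(denovo)
      hm <- h(m)
      H <- he + hm
      P <- -expm1(-H)
      p_ev <- ifelse(H > 0, P * he / H, 0)
      p_die <- ifelse(H > 0, P * hm / H, 0)
      uu <- runif(length(idx))
      go_u <- uu < p_ev
      go_d <- !go_u & uu < p_ev + p_die
      nk[idx[go_u]] <- 2L
      nk[idx[go_d]] <- 4L
      nap[idx] <- ap[idx] + 1L
    }
    idx <- which(iu)
    if (length(idx)) {
      can <- i[idx] < config$max_procedures
      hb <- h(rupture)
      ht <- ifelse(can, h(retreat), 0)
      hm <- h(m)
      H <- hb + ht + hm
      P <- -expm1(-H)
      p_b <- P * hb / H
      p_t <- P * ht / H
      p_d <- P * hm / H
      uu <- runif(length(idx))
      go_b <- uu < p_b
      go_t <- !go_b & uu < p_b + p_t
      go_d <- !go_b & !go_t & uu < p_b + p_t + p_d
      nk[idx[go_b]] <- 3L
      jt <- idx[go_t]
      if (length(jt)) {
        o2 <- sample.int(4L, length(jt), replace = TRUE, prob = split4)
        dead2 <- o2 == 4L
        nk[jt[dead2]] <- 4L
        nk[jt[!dead2]] <- 1L
        ni[jt] <- i[jt] + 1L
        ns[jt[!dead2]] <- pmax(s[jt[!dead2]],
                               c(1L, 2L, 3L, 1L)[o2[!dead2]])
        nap[jt] <- 0L
        cost[jt] <- cost[jt] + df_k1 * proc_cost[o2]
      }
      nk[idx[go_d]] <- 4L
    }
    idx <- which(it)
    if (length(idx)) {
      o3 <- sample.int(4L, length(idx), replace = TRUE, prob = asah_p) - 1L
      nk[idx[o3 == 0L]] <- 4L
      sv <- idx[o3 > 0L]
      nk[sv] <- 1L
      ni[sv] <- pmin(i[sv] + 1L, config$max_procedures)
      ns[sv] <- pmax(s[sv], o3[o3 > 0L])
      nap[sv] <- 0L
    }
    kind <- nk; i <- ni; s <- ns; ap <- nap
  }
  list(mean_cost = mean(cost), mean_qaly = mean(qaly),
       se_cost = sd(cost) / sqrt(n), se_qaly = sd(qaly) / sqrt(n),
       n_patients = n)
}

#' Cross-validate the cohort engine against the microsimulation
#'
#' Runs both arms through [run_cohort()] and [simulate_patients()] for
#' one draw and flags any cost/QALY deviation beyond
#' `tolerance_in_se` Monte Carlo standard errors.
#'
#' @inheritParams simulate_patients
#' @param tolerance_in_se Allowed deviation in microsimulation SEs.
#' @return `data.frame(arm, metric, cohort, microsim, se, z, pass)` with
#'   attribute `pass` (all rows within tolerance).
#' @export
cohort_vs_microsim_check <- function(draw, config, n_patients = 20000L,
                                     tolerance_in_se = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (arm in c("standard", "hti")) {
    co <- run_cohort(draw, config, arm)$outcome
    ms <- simulate_patients(draw, config, arm, n_patients)
    rows[[arm]] <- data.frame(
      arm = arm, metric = c("cost", "qaly"),
      cohort = c(co$cost, co$qaly),
      microsim = c(ms$mean_cost, ms$mean_qaly),
      se = c(ms$se_cost, ms$se_qaly))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$z <- abs(out$cohort - out$microsim) / out$se
  out$pass <- out$z <= tolerance_in_se
  attr(out, "pass") <- all(out$pass)
  out
}

#' Generate a random valid parameter table
#'
#' Produces a synthetic 25-row table with the same ids, distribution
#' families, groups and quoted periods as the bundled default, but
#' randomized means and standard errors within family-feasible ranges
#' (Beta moment feasibility, positive costs, ordered group means,
#' rejection-reachable order gaps). Always loadable by
#' [load_parameter_table()] validation and sampleable by
#' [sample_draws()]; used for property-style testing of the pipeline.
#'
#' @param seed Optional integer seed.
#' @return A `cea_parameters` table.
#' @export
random_parameter_table <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- load_parameter_table()
  jitter_prob <- function(m, lo = 0.002, hi = 0.6) {
    pmin(pmax(m * runif(length(m), 0.6, 1.5), lo), hi)
  }
  is_beta_prob <- tab$group == "probability"
  tab$mean[is_beta_prob] <- jitter_prob(tab$mean[is_beta_prob])
  # keep joint outcome splits feasible with headroom
  for (ids in list(1:3, 9:11)) {
    s <- sum(tab$mean[tab$id %in% ids])
    if (s > 0.8) tab$mean[tab$id %in% ids] <-
        tab$mean[tab$id %in% ids] * 0.8 / s
  }
  m <- tab$mean[is_beta_prob]
  tab$se[is_beta_prob] <- sqrt(m * (1 - m)) * runif(sum(is_beta_prob),
                                                    0.02, 0.15)
  # ordered cost groups: ascending means, SEs capped by the gap so the
  # ordering rejection terminates quickly
  for (g in c("coil_cost", "care_cost")) {
    i <- which(tab$order_group %in% g)
    mu <- sort(runif(3, 4000, 90000))
    tab$mean[i] <- mu
    gap <- min(diff(mu))
    tab$se[i] <- pmin(mu * runif(3, 0.05, 0.3), gap)
  }
  tab$mean[tab$id == 18] <- runif(1, 40000, 150000)
  tab$se[tab$id == 18] <- tab$mean[tab$id == 18] * runif(1, 0.005, 0.1)
  # utilities: descending in severity, SEs capped by the gaps
  u <- sort(runif(3, 0.15, 0.95), decreasing = TRUE)
  iu <- match(19:21, tab$id)
  tab$mean[iu] <- u
  gaps <- c(u[1] - u[2], min(u[1] - u[2], u[2] - u[3]), u[2] - u[3])
  tab$se[iu] <- pmin(runif(3, 0.005, 0.05), gaps / 2)
  mag <- runif(1, 0.01, 0.12)
  tab$mean[tab$id == 22] <- -mag
  tab$se[tab$id == 22] <- sqrt(mag * (1 - mag)) * runif(1, 0.1, 0.4)
  tab$mean[tab$id == 23] <- runif(1, 0.2, 0.8)
  tab$se[tab$id == 23] <- runif(1, 0.01, 0.08)
  tab$mean[tab$id == 25] <- runif(1, 0, 20000)
  # refresh sensitivity bounds to bracket the new means
  stoch <- tab$dist_family %in% c("beta", "gamma",
                                  "truncated_ordered_normal")
  tab$sens_low[stoch] <- ifelse(tab$id[stoch] == 22, 0,
                                tab$mean[stoch] - 2 * tab$se[stoch])
  tab$sens_high[stoch] <- ifelse(tab$id[stoch] == 22,
                                 tab$mean[stoch] - 2 * tab$se[stoch],
                                 tab$mean[stoch] + 2 * tab$se[stoch])
  tab$sens_low[stoch & tab$group == "probability"] <-
    pmax(tab$sens_low[stoch & tab$group == "probability"], 0)
  tab$sens_low[stoch & tab$group == "cost"] <-
    pmax(tab$sens_low[stoch & tab$group == "cost"], 0)
  validate_parameter_table(tab)
}
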