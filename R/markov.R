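# Markov cohort engine: state enumeration, per-cycle transition
# construction, propagation over the horizon, discounted cost/QALY accrual.
#
# Health states. Patients enter after the index coiling at age 45 and are
# tracked by: procedure count i (1-4), functional status (mRS 0 / 1-2 /
# 3-5), and - for coiled patients - the number of cycles since the most
# recent procedure. Recanalization risk is confined to the quoted 6-year
# window following each coiling (the "0.244 per 6 years" per-procedure
# risk); after the window the coil is considered durably occluded and only
# de novo aneurysm formation can reopen exposure. A recanalized or de novo
# aneurysm puts the patient in an "unsecured" state (rupture risk,
# disutility) until retreatment; rupture passes through a one-cycle aSAH
# tunnel state that attaches the hospitalization cost and acute utility.
#
# The engine is vectorized across parameter draws: every transition
# probability is an n-vector and the occupancy is an n x S matrix, so one
# pass propagates a whole PSA.

STATUS_LABELS <- c("mRS0", "mRS1_2", "mRS3_5")

# printed offsets of the mRS 0 utility age bands relative to ages 45-54
UTILITY_BAND_OFFSETS <- c(0, -0.02, -0.01, -0.03)

#' Model run configuration
#'
#' Holds the cohort-model settings: half-year cycles over a 30-year
#' horizon, entry at age 45, 1.5\%/year discounting of costs and QALYs,
#' willingness-to-pay thresholds, the adjunct price, background
#' (all-cause) mortality from a bundled abridged life table, and the
#' recanalization/retreatment structure. No half-cycle correction is
#' applied: state flows accrue at cycle start with that cycle's discount
#' factor; event costs on transitions use the arrival cycle's factor.
#'
#' @param cycle_years Cycle length in years.
#' @param n_cycles Number of cycles.
#' @param start_age Cohort entry age in years.
#' @param discount_rate Annual discount rate (costs and QALYs).
#' @param max_procedures Maximum lifetime number of coiling procedures.
#' @param hti_price Adjunct price per index procedure, USD.
#' @param thresholds Willingness-to-pay thresholds, USD/QALY.
#' @param background_mortality Apply all-cause mortality from `life_table`?
#' @param life_table `data.frame(age_low, age_high,
#'   annual_mortality_probability)`; `NULL` loads the bundled table.
#' @param utility_band_offsets Offsets of the mRS 0 utility for age bands
#'   55-64, 65-74 and 75+ relative to the drawn 45-54 value (all four
#'   bands move together within a draw).
#' @param recan_window_years Years after each procedure during which the
#'   quoted recanalization risk applies (the period the probability is
#'   quoted over); `Inf` applies it as a lifelong constant hazard.
#' @param retreat_conditional If `TRUE` (default) the quoted retreatment
#'   probability is read as marginal over all coiled patients and is
#'   conditioned on harbouring an untreated aneurysm (ratio to the
#'   recanalization probability); if `FALSE` it is applied directly to
#'   unsecured patients.
#' @param recan_later_procedures If `TRUE`, every coiling procedure
#'   (re-treatments and post-aSAH coils) re-enters the recanalization
#'   risk window; if `FALSE` (default) only the index coil carries
#'   recanalization risk and later coils are exposed to de novo
#'   formation only.
#' @param probability_conversion How probabilities quoted over a period
#'   are rescaled to the cycle length: `"linear"` (default) divides the
#'   probability proportionally to time, `"constant_hazard"` uses
#'   `1 - (1 - p)^(cycle / period)` (see [per_cycle_probability()]).
#'   Linear rescaling is standard spreadsheet practice and is what the
#'   printed results reflect; the two differ by at most ~13\% for the
#'   bundled probabilities.
#' @return An object of class `cea_config`.
#' @export
model_config <- function(cycle_years = 0.5, n_cycles = 60L, start_age = 45,
                         discount_rate = 0.015, max_procedures = 4L,
                         hti_price = 10000,
                         thresholds = c(50000, 100000, 150000),
                         background_mortality = TRUE, life_table = NULL,
                         utility_band_offsets = UTILITY_BAND_OFFSETS,
                         recan_window_years = 6,
                         retreat_conditional = TRUE,
                         recan_later_procedures = FALSE,
                         probability_conversion = c("linear",
                                                    "constant_hazard")) {
  probability_conversion <- match.arg(probability_conversion)
  if (cycle_years <= 0) stop("cycle_years must be > 0")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (discount_rate < 0) stop("discount_rate must be >= 0")
  if (hti_price < 0) stop("hti_price must be >= 0")
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  if (max_procedures != 4L) {
    stop("the state space is enumerated for max_procedures = 4")
  }
  if (recan_window_years <= 0) stop("recan_window_years must be > 0")
  if (is.finite(recan_window_years) &&
        recan_window_years < cycle_years) {
    stop("recan_window_years must cover at least one cycle")
  }
  if (is.null(life_table)) life_table <- load_life_table()
  structure(list(cycle_years = cycle_years, n_cycles = as.integer(n_cycles),
                 start_age = start_age, discount_rate = discount_rate,
                 max_procedures = 4L, hti_price = hti_price,
                 thresholds = thresholds,
                 background_mortality = isTRUE(background_mortality),
                 life_table = life_table,
                 utility_band_offsets = utility_band_offsets,
                 recan_window_years = recan_window_years,
                 retreat_conditional = isTRUE(retreat_conditional),
                 recan_later_procedures = isTRUE(recan_later_procedures),
                 probability_conversion = probability_conversion),
            class = "cea_config")
}

# number of at-risk age levels; coiled states carry one extra "mature"
# level when the window is finite
window_cycles <- function(config) {
  if (is.infinite(config$recan_window_years)) return(Inf)
  max(1L, as.integer(round(config$recan_window_years / config$cycle_years)))
}

state_layout <- function(config) {
  w <- window_cycles(config)
  A <- if (is.finite(w)) w + 1L else 1L  # age levels per coiled (i, s)
  list(w = w, A = A, n_coiled = 12L * A,
       n_states = 12L * A + 12L + 12L + 1L)
}

col_coiled <- function(i, s, a, A) ((i - 1L) * 3L + (s - 1L)) * A + a + 1L
col_unsec <- function(i, s, A) 12L * A + (i - 1L) * 3L + s
col_tunnel <- function(i, s, A) 12L * A + 12L + (i - 1L) * 3L + s
col_dead <- function(A) 12L * A + 25L

#' Load an abridged life table
#'
#' The bundled default is a representative both-sex abridged period life
#' table (5-year age bands of annual death probabilities at a US-like
#' 2018 level, constructed for this package) used for background
#' mortality.
#'
#' @param path CSV path, or `NULL` for the bundled table.
#' @return `data.frame(age_low, age_high, annual_mortality_probability)`.
#' @export
load_life_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "life_table.csv",
                        package = "coilcea", mustWork = TRUE)
  }
  lt <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_low", "age_high", "annual_mortality_probability")
  if (!all(need %in% names(lt))) {
    stop("life table must have columns ", paste(need, collapse = ", "))
  }
  if (any(lt$annual_mortality_probability < 0 |
            lt$annual_mortality_probability >= 1)) {
    stop("annual mortality probabilities must lie in [0, 1)")
  }
  lt[order(lt$age_low), , drop = FALSE]
}

annual_mortality_at <- function(age, life_table) {
  i <- findInterval(age, life_table$age_low)
  if (any(i < 1) || any(age >= max(life_table$age_high))) {
    stop("life table does not cover the requested ages")
  }
  life_table$annual_mortality_probability[i]
}

# per-cycle background mortality for cycles 0..n_cycles-1
cycle_mortality <- function(config) {
  if (!config$background_mortality) return(rep(0, config$n_cycles))
  ages <- config$start_age +
    (seq_len(config$n_cycles) - 1L) * config$cycle_years
  q <- annual_mortality_at(ages, config$life_table)
  1 - (1 - q)^config$cycle_years
}

#' Per-cycle discount factor
#'
#' `(1 + rate)^(-cycle * cycle_years)`; cycle 0 maps to 1.
#'
#' @param cycle Cycle index (0-based, vectorized).
#' @param rate Annual discount rate, >= 0.
#' @param cycle_years Cycle length in years.
#' @export
discount_factor <- function(cycle, rate, cycle_years = 0.5) {
  if (rate < 0) stop("discount rate must be >= 0")
  (1 + rate)^(-cycle * cycle_years)
}

utility_band <- function(age) {
  findInterval(age, c(-Inf, 55, 65, 75))
}

#' Age-banded utility for coiled patients with good function
#'
#' Returns the draw's mRS 0 utility for the age band containing `age`
#' (half-open bands 45-54, 55-64, 65-74, 75+). All bands share the drawn
#' 45-54 value plus the printed band offsets.
#'
#' @param age Current cohort age, years.
#' @param draw A `parameter_draw` (or single-row draws data.frame).
#' @param offsets Band offsets, see [model_config()].
#' @export
age_band_utility <- function(age, draw, offsets = UTILITY_BAND_OFFSETS) {
  d <- as_draws(draw)
  d$v19[1] + offsets[utility_band(age)]
}

#' Enumerate the health-state space
#'
#' States are `coiled(i, status, a)` (aneurysm secured after `i` coiling
#' procedures, `a` cycles since the most recent one, with `a = mature`
#' once past the recanalization window), `unsecured(i, status)` (a
#' recanalized or de novo aneurysm present and untreated), one-cycle aSAH
#' tunnel states `asah(i, status)` entered on rupture, and absorbing
#' `dead`. `i` runs 1-4 and `status` is mRS 0 / mRS 1-2 / mRS 3-5.
#' Ordering is deterministic and stable across runs.
#'
#' @param config A [model_config()].
#' @return `data.frame(index, kind, procedures, status,
#'   cycles_since_procedure, label)`.
#' @export
enumerate_states <- function(config = model_config()) {
  lay <- state_layout(config)
  A <- lay$A
  rows <- vector("list", lay$n_states)
  for (i in 1:4) for (s in 1:3) for (a in 0:(A - 1L)) {
    age_lab <- if (is.finite(lay$w) && a == lay$w) "mature" else
      as.character(a)
    idx <- col_coiled(i, s, a, A)
    rows[[idx]] <- data.frame(
      index = idx, kind = "coiled", procedures = i,
      status = STATUS_LABELS[s], cycles_since_procedure = age_lab,
      label = paste0("coiled(", i, ",", STATUS_LABELS[s], ",", age_lab,
                     ")"))
  }
  for (i in 1:4) for (s in 1:3) {
    idx <- col_unsec(i, s, A)
    rows[[idx]] <- data.frame(
      index = idx, kind = "unsecured", procedures = i,
      status = STATUS_LABELS[s], cycles_since_procedure = NA,
      label = paste0("unsecured(", i, ",", STATUS_LABELS[s], ")"))
    idx <- col_tunnel(i, s, A)
    rows[[idx]] <- data.frame(
      index = idx, kind = "asah", procedures = i,
      status = STATUS_LABELS[s], cycles_since_procedure = NA,
      label = paste0("asah(", i, ",", STATUS_LABELS[s], ")"))
  }
  rows[[col_dead(A)]] <- data.frame(
    index = col_dead(A), kind = "dead", procedures = NA, status = NA,
    cycles_since_procedure = NA, label = "dead")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# hazard of a per-cycle probability
phaz <- function(p) -log1p(-p)

# per-cycle event probabilities derived from a draws data.frame
cycle_event_probs <- function(d, config) {
  cy <- config$cycle_years
  dur <- attr(d, "durations")
  dur_of <- function(key, default) {
    if (!is.null(dur) && key %in% names(dur)) dur[[key]] else default
  }
  conv <- if (identical(config$probability_conversion, "constant_hazard"))
    per_cycle_probability
  else
    function(p, duration, cycle_years) p * cycle_years / duration
  ret_q <- if (config$retreat_conditional) {
    pmin(d$v5 / pmax(d$v4, 1e-12), 1)
  } else {
    d$v5
  }
  list(
    recan = conv(d$v4, dur_of("v4", 6), cy),
    denovo = conv(d$v6, dur_of("v6", 1), cy),
    rupture = conv(d$v7, dur_of("v7", 1), cy),
    retreat = conv(ret_q, dur_of("v5", 6), cy),
    c1 = d$v1, c2 = d$v2, c3 = d$v3, c0 = 1 - d$v1 - d$v2 - d$v3,
    asah_dead = d$v8 + (1 - d$v8) * d$v9,
    asah_s0 = (1 - d$v8) * (1 - d$v9 - d$v10 - d$v11),
    asah_s12 = (1 - d$v8) * d$v10,
    asah_s35 = (1 - d$v8) * d$v11,
    rrr = d$rrr
  )
}

# Competing risks within a cycle: per-cycle probabilities are converted
# to hazards, the total transition probability 1 - exp(-sum of hazards)
# is allocated proportionally to each hazard, and the residual stays in
# state, so no residual can go negative.
crisk_alloc <- function(hazards) {
  H <- Reduce(`+`, hazards)
  total <- -expm1(-H)
  w <- ifelse(H > 0, total / H, 0)
  lapply(hazards, function(h) w * h)
}

# allocation sets reused by the propagation loop; m is the scalar
# per-cycle background mortality, all other entries n-vectors
transition_blocks <- function(P, m, strategy, config, n) {
  hm <- rep(phaz(m), n)
  coiled_alloc <- function(recan_haz) {
    al <- crisk_alloc(list(ev = recan_haz + phaz(P$denovo), m = hm))
    list(ev = al$ev, die = al$m, stay = 1 - al$ev - al$m)
  }
  r1 <- if (strategy == "hti") P$recan * (1 - P$rrr) else P$recan
  r2 <- if (config$recan_later_procedures) P$recan else rep(0, n)
  blocks <- list(
    risk1 = coiled_alloc(phaz(r1)),      # index coil within the window
    risk2 = coiled_alloc(phaz(r2)),      # later coils within the window
    mature = coiled_alloc(rep(0, n))     # past the window: de novo only
  )
  al <- crisk_alloc(list(b = phaz(P$rupture), t = phaz(P$retreat), m = hm))
  blocks$unsec_re <- list(tun = al$b, ret = al$t, die = al$m,
                          stay = 1 - al$b - al$t - al$m)
  al <- crisk_alloc(list(b = phaz(P$rupture), m = hm))
  blocks$unsec_last <- list(tun = al$b, die = al$m,
                            stay = 1 - al$b - al$m)
  blocks
}

# n x S per-cycle state cost matrix (care costs by status; aSAH hospital
# cost charged per tunnel-cycle occupancy)
state_cost_matrix <- function(d, config, lay, n) {
  cy <- config$cycle_years
  Cst <- matrix(0, n, lay$n_states)
  care <- cbind(d$v15, d$v16, d$v17) * cy
  for (i in 1:4) for (s in 1:3) {
    Cst[, col_coiled(i, s, 0:(lay$A - 1L), lay$A)] <- care[, s]
    Cst[, col_unsec(i, s, lay$A)] <- care[, s]
    # hospital care can only be incurred by patients who reach hospital;
    # charged as its expectation over pre-hospital survival
    Cst[, col_tunnel(i, s, lay$A)] <- (1 - d$v8) * d$v18
  }
  Cst
}

# n x S utility matrix for one age band
state_utility_matrix <- function(d, config, lay, band, n) {
  U <- matrix(0, n, lay$n_states)
  u <- cbind(d$v19 + config$utility_band_offsets[band], d$v20, d$v21)
  for (i in 1:4) for (s in 1:3) {
    U[, col_coiled(i, s, 0:(lay$A - 1L), lay$A)] <- u[, s]
    U[, col_unsec(i, s, lay$A)] <- u[, s] + d$v22
    U[, col_tunnel(i, s, lay$A)] <- d$v23
  }
  U
}

#' Build the per-cycle transition matrix for one draw
#'
#' Assembles the full stochastic matrix over [enumerate_states()] for a
#' given cycle (which fixes the background-mortality level through the
#' cohort age) and strategy. Rows sum to 1 by construction; competing
#' per-cycle risks are combined on the hazard scale and allocated
#' proportionally, so no residual can go negative.
#'
#' @param draw A `parameter_draw`.
#' @param config A [model_config()].
#' @param cycle 0-based cycle index in `[0, n_cycles)`.
#' @param strategy `"standard"` or `"hti"`.
#' @return A square matrix with state labels as dimnames.
#' @export
build_transition_matrix <- function(draw, config, cycle = 0L,
                                    strategy = c("standard", "hti")) {
  strategy <- match.arg(strategy)
  if (cycle < 0 || cycle >= config$n_cycles) {
    stop("cycle must lie in [0, n_cycles)")
  }
  d <- as_draws(draw)
  stopifnot(nrow(d) == 1L)
  lay <- state_layout(config)
  A <- lay$A
  P <- cycle_event_probs(d, config)
  if (P$c0 < 0 || P$asah_s0 < 0) {
    stop("infeasible draw: outcome probabilities sum past 1")
  }
  m <- cycle_mortality(config)[cycle + 1L]
  B <- transition_blocks(P, m, strategy, config, 1L)
  S <- lay$n_states
  M <- matrix(0, S, S)
  dead <- col_dead(A)
  for (i in 1:4) for (s in 1:3) {
    for (a in 0:(A - 1L)) {
      from <- col_coiled(i, s, a, A)
      at_risk <- is.infinite(lay$w) || a < lay$w
      bl <- if (!at_risk) B$mature else if (i == 1L) B$risk1 else B$risk2
      M[from, col_unsec(i, s, A)] <- bl$ev
      M[from, dead] <- M[from, dead] + bl$die
      to_a <- if (is.finite(lay$w)) min(a + 1L, lay$w) else a
      to <- col_coiled(i, s, to_a, A)
      M[from, to] <- M[from, to] + bl$stay
    }
    from <- col_unsec(i, s, A)
    if (i < config$max_procedures) {
      bl <- B$unsec_re
      M[from, col_tunnel(i, s, A)] <- bl$tun
      j <- i + 1L
      add <- function(to, p) M[from, to] <<- M[from, to] + p
      add(col_coiled(j, s, 0L, A), bl$ret * P$c0)
      add(col_coiled(j, max(s, 2L), 0L, A), bl$ret * P$c1)
      add(col_coiled(j, 3L, 0L, A), bl$ret * P$c2)
      add(dead, bl$ret * P$c3 + bl$die)
      add(from, bl$stay)
    } else {
      bl <- B$unsec_last
      M[from, col_tunnel(i, s, A)] <- bl$tun
      M[from, dead] <- M[from, dead] + bl$die
      M[from, from] <- M[from, from] + bl$stay
    }
    from <- col_tunnel(i, s, A)
    j <- min(i + 1L, config$max_procedures)
    add <- function(to, p) M[from, to] <<- M[from, to] + p
    add(dead, P$asah_dead)
    add(col_coiled(j, s, 0L, A), P$asah_s0)
    add(col_coiled(j, max(s, 2L), 0L, A), P$asah_s12)
    add(col_coiled(j, 3L, 0L, A), P$asah_s35)
  }
  M[dead, dead] <- 1
  labs <- enumerate_states(config)$label
  dimnames(M) <- list(labs, labs)
  if (any(M < -1e-12) || any(abs(rowSums(M) - 1) > 1e-12)) {
    stop("infeasible draw: invalid transition row(s)")
  }
  M
}

# Core engine: propagate n draws through the cohort model.
# d: draws data.frame (v1..v23, v25, rrr); price charged at cycle 0.
propagate_cohort <- function(d, config, strategy = c("standard", "hti"),
                             price = 0, trace = FALSE) {
  strategy <- match.arg(strategy)
  n <- nrow(d)
  cy <- config$cycle_years
  rate <- config$discount_rate
  K <- config$n_cycles
  lay <- state_layout(config)
  A <- lay$A
  w <- lay$w
  dead <- col_dead(A)
  P <- cycle_event_probs(d, config)
  if (any(P$c0 < 0) || any(P$asah_s0 < 0)) {
    stop("infeasible draw: outcome probabilities sum past 1")
  }

  occ <- matrix(0, n, lay$n_states)
  # index procedure at cycle 0: complication split and procedure cost,
  # plus the adjunct price (HTI arm), all undiscounted
  occ[, col_coiled(1L, 1L, 0L, A)] <- P$c0
  occ[, col_coiled(1L, 2L, 0L, A)] <- P$c1
  occ[, col_coiled(1L, 3L, 0L, A)] <- P$c2
  occ[, dead] <- P$c3
  cost_d <- price + P$c0 * d$v12 + (P$c1 + P$c2) * d$v13 + P$c3 * d$v14
  cost_u <- cost_d
  qaly_d <- numeric(n)
  qaly_u <- numeric(n)

  Cst <- state_cost_matrix(d, config, lay, n)
  m_cyc <- cycle_mortality(config)
  B <- NULL
  cur_m <- NA_real_
  U <- NULL
  cur_band <- NA_integer_
  proc_cost <- cbind(d$v12, d$v13, d$v13, d$v14)  # by outcome 0/1-2/3-5/death

  if (trace) {
    occ_trace <- matrix(NA_real_, K + 1L, lay$n_states)
    tallies <- data.frame(cycle = seq_len(K) - 1L, procedures = NA_real_,
                          ruptures = NA_real_, admissions = NA_real_)
  }

  for (k in 0:(K - 1L)) {
    band <- utility_band(config$start_age + k * cy)
    if (!identical(band, cur_band)) {
      U <- state_utility_matrix(d, config, lay, band, n)
      cur_band <- band
    }
    df_k <- (1 + rate)^(-k * cy)
    sc <- rowSums(occ * Cst)
    su <- rowSums(occ * U)
    cost_d <- cost_d + df_k * sc
    cost_u <- cost_u + sc
    qaly_d <- qaly_d + df_k * cy * su
    qaly_u <- qaly_u + cy * su
    if (is.na(cur_m) || m_cyc[k + 1L] != cur_m) {
      cur_m <- m_cyc[k + 1L]
      B <- transition_blocks(P, cur_m, strategy, config, n)
    }
    if (trace) occ_trace[k + 1L, ] <- occ[1L, ]
    new <- matrix(0, n, lay$n_states)
    evc <- numeric(n)
    dead_in <- occ[, dead]
    tally_proc <- tally_rupt <- 0
    for (i in 1:4) {
      blr <- if (i == 1L) B$risk1 else B$risk2
      for (s in 1:3) {
        cols <- col_coiled(i, s, 0:(A - 1L), A)
        if (is.finite(w)) {
          ob <- occ[, cols[seq_len(w)], drop = FALSE]
          risk_mass <- rowSums(ob)
          mat_mass <- occ[, cols[A]]
          new[, col_unsec(i, s, A)] <-
            risk_mass * blr$ev + mat_mass * B$mature$ev
          dead_in <- dead_in + risk_mass * blr$die + mat_mass * B$mature$die
          # aging shift: at-risk level a stays into a + 1 (level w - 1
          # matures); mature stays mature
          new[, cols[2:A]] <- new[, cols[2:A]] + ob * blr$stay
          new[, cols[A]] <- new[, cols[A]] + mat_mass * B$mature$stay
        } else {
          mass <- occ[, cols[1L]]
          new[, col_unsec(i, s, A)] <- mass * blr$ev
          dead_in <- dead_in + mass * blr$die
          new[, cols[1L]] <- new[, cols[1L]] + mass * blr$stay
        }
      }
    }
    for (i in 1:4) {
      for (s in 1:3) {
        from <- col_unsec(i, s, A)
        mass <- occ[, from]
        if (i < config$max_procedures) {
          bl <- B$unsec_re
          tun_in <- mass * bl$tun
          new[, col_tunnel(i, s, A)] <- tun_in
          ret <- mass * bl$ret
          j <- i + 1L
          new[, col_coiled(j, s, 0L, A)] <-
            new[, col_coiled(j, s, 0L, A)] + ret * P$c0
          cto <- col_coiled(j, max(s, 2L), 0L, A)
          new[, cto] <- new[, cto] + ret * P$c1
          cto <- col_coiled(j, 3L, 0L, A)
          new[, cto] <- new[, cto] + ret * P$c2
          dead_in <- dead_in + ret * P$c3 + mass * bl$die
          evc <- evc + ret * (P$c0 * proc_cost[, 1L] +
                                P$c1 * proc_cost[, 2L] +
                                P$c2 * proc_cost[, 3L] +
                                P$c3 * proc_cost[, 4L])
          new[, from] <- new[, from] + mass * bl$stay
          if (trace) tally_proc <- tally_proc + ret[1L]
        } else {
          bl <- B$unsec_last
          tun_in <- mass * bl$tun
          new[, col_tunnel(i, s, A)] <- tun_in
          dead_in <- dead_in + mass * bl$die
          new[, from] <- new[, from] + mass * bl$stay
        }
        if (trace) tally_rupt <- tally_rupt + tun_in[1L]
      }
    }
    for (i in 1:4) {
      j <- min(i + 1L, config$max_procedures)
      for (s in 1:3) {
        mass <- occ[, col_tunnel(i, s, A)]
        dead_in <- dead_in + mass * P$asah_dead
        new[, col_coiled(j, s, 0L, A)] <-
          new[, col_coiled(j, s, 0L, A)] + mass * P$asah_s0
        cto <- col_coiled(j, max(s, 2L), 0L, A)
        new[, cto] <- new[, cto] + mass * P$asah_s12
        cto <- col_coiled(j, 3L, 0L, A)
        new[, cto] <- new[, cto] + mass * P$asah_s35
      }
    }
    new[, dead] <- dead_in
    df_k1 <- (1 + rate)^(-(k + 1L) * cy)
    cost_d <- cost_d + df_k1 * evc
    cost_u <- cost_u + evc
    occ <- new
    if (trace) {
      tallies$procedures[k + 1L] <- tally_proc
      tallies$ruptures[k + 1L] <- tally_rupt
      tallies$admissions[k + 1L] <- tally_rupt * (1 - d$v8[1L])
    }
  }
  out <- data.frame(cost = cost_d, qaly = qaly_d,
                    cost_undiscounted = cost_u, qaly_undiscounted = qaly_u)
  if (trace) {
    occ_trace[K + 1L, ] <- occ[1L, ]
    attr(out, "occupancy") <- occ_trace
    attr(out, "tallies") <- tallies
  }
  out
}

#' Run the cohort model for one draw
#'
#' Propagates a unit cohort (entering at age `start_age` immediately
#' after the index coiling procedure) through `n_cycles` cycles and
#' accrues discounted and undiscounted costs and QALYs. The index
#' procedure's complication split and cost, and the adjunct price in the
#' HTI arm, are charged at cycle 0.
#'
#' @param draw A `parameter_draw` (or single-row [sample_draws()] frame).
#' @param config A [model_config()].
#' @param strategy `"standard"` or `"hti"`.
#' @param price Price charged at cycle 0; defaults to `config$hti_price`
#'   for the HTI arm and 0 otherwise.
#' @return List of class `cohort_result`: `outcome` (one-row data.frame
#'   with discounted/undiscounted cost and QALY), `trace` (occupancy over
#'   cycles, rows summing to 1), and `tallies` (per-cycle retreatment
#'   procedures, ruptures, hospital admissions).
#' @export
run_cohort <- function(draw, config, strategy = c("standard", "hti"),
                       price = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(price)) price <- if (strategy == "hti") config$hti_price else 0
  d <- as_draws(draw)
  stopifnot(nrow(d) == 1L)
  res <- propagate_cohort(d, config, strategy, price = price, trace = TRUE)
  structure(list(outcome = data.frame(res),
                 trace = attr(res, "occupancy"),
                 tallies = attr(res, "tallies"),
                 strategy = strategy),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("Cohort run (", x$strategy, " arm)\n", sep = "")
  cat(sprintf("  discounted cost: $%.0f  discounted QALY: %.3f\n",
              x$outcome$cost, x$outcome$qaly))
  cat(sprintf("  undiscounted cost: $%.0f  undiscounted QALY: %.3f\n",
              x$outcome$cost_undiscounted, x$outcome$qaly_undiscounted))
  invisible(x)
}
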