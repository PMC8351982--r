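# Probabilistic sensitivity analysis: Monte Carlo runs, replication-based
# credible intervals, and convergence diagnostics.

#' Run a probabilistic sensitivity analysis
#'
#' Draws `n_iterations` joint parameter realizations and propagates each
#' through both strategy arms with common random numbers (one draw feeds
#' both arms), returning per-iteration discounted costs and QALYs. The
#' adjunct price is charged in the HTI arm only.
#'
#' @param specs A [load_parameter_table()] table.
#' @param hti An [hti_efficacy()] spec.
#' @param config A [model_config()].
#' @param n_iterations Number of Monte Carlo iterations.
#' @param seed Optional integer seed (full run is reproducible given it).
#' @param price Adjunct price charged in the HTI arm; defaults to
#'   `config$hti_price`. Set to 0 for price-exclusive net benefits (the
#'   elasticity analysis).
#' @param fixed Optional named overrides, see [sample_draws()].
#' @return A `data.frame` of class `psa_samples` with columns `iteration`,
#'   `rrr`, `cost_std`, `qaly_std`, `cost_hti`, `qaly_hti`.
#' @export
run_psa <- function(specs, hti, config, n_iterations = 7000L, seed = NULL,
                    price = NULL, fixed = NULL) {
  stopifnot(n_iterations >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(price)) price <- config$hti_price
  d <- sample_draws(specs, hti, n_iterations, fixed = fixed)
  std <- propagate_cohort(d, config, "standard", price = 0)
  adj <- propagate_cohort(d, config, "hti", price = price)
  out <- data.frame(iteration = seq_len(n_iterations), rrr = d$rrr,
                    cost_std = std$cost, qaly_std = std$qaly,
                    cost_hti = adj$cost, qaly_hti = adj$qaly)
  attr(out, "seed") <- seed
  attr(out, "price") <- price
  attr(out, "n_redrawn") <- attr(d, "n_redrawn")
  class(out) <- c("psa_samples", "data.frame")
  out
}

psa_stats <- function(psa, thresholds, pop = population_spec()) {
  dc <- mean(psa$cost_hti) - mean(psa$cost_std)
  de <- mean(psa$qaly_hti) - mean(psa$qaly_std)
  stats <- c(cost_hti = mean(psa$cost_hti), cost_std = mean(psa$cost_std),
             qaly_hti = mean(psa$qaly_hti), qaly_std = mean(psa$qaly_std),
             icer = dc / de)
  for (l in thresholds) {
    stats[paste0("ceac_", l)] <- ceac_point(psa, l)
    ev <- evpi_per_person(psa, l)
    stats[paste0("evpi_pp_", l)] <- ev
    stats[paste0("evpi_pop_", l)] <- scale_to_population(ev, pop)
  }
  stats
}

#' Replicate the PSA and summarize with credible intervals
#'
#' Repeats [run_psa()] `n_replicates` times on independent substreams of
#' the master seed. Each replicate yields the per-arm means, the ICER, and
#' the CEAC/EVPI at the configured thresholds; the summary reports the
#' replicate mean (the expected value) and the 2.5th/97.5th replicate
#' percentiles (the 95\% credible interval) for each statistic.
#'
#' @inheritParams run_psa
#' @param n_replicates Number of independent replications (>= 2).
#' @param pop A [population_spec()] used for population-scaled EVPI.
#' @return List of class `replicate_summary`: `replicates` (one row per
#'   replicate) and `summary` (`statistic`, `mean`, `cri_low`,
#'   `cri_high`).
#' @export
replicate_psa <- function(specs, hti, config, n_iterations = 7000L,
                          n_replicates = 100L, seed = NULL,
                          pop = population_spec(), fixed = NULL) {
  stopifnot(n_replicates >= 2)
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    psa <- run_psa(specs, hti, config, n_iterations, seed = sub_seeds[r],
                   fixed = fixed)
    rows[[r]] <- psa_stats(psa, config$thresholds, pop)
  }
  reps <- as.data.frame(do.call(rbind, rows))
  reps <- cbind(replicate = seq_len(n_replicates), reps)
  sm <- data.frame(
    statistic = setdiff(names(reps), "replicate"),
    mean = vapply(setdiff(names(reps), "replicate"),
                  function(s) mean(reps[[s]]), numeric(1)),
    cri_low = vapply(setdiff(names(reps), "replicate"),
                     function(s) unname(quantile(reps[[s]], 0.025)),
                     numeric(1)),
    cri_high = vapply(setdiff(names(reps), "replicate"),
                      function(s) unname(quantile(reps[[s]], 0.975)),
                      numeric(1)),
    row.names = NULL)
  structure(list(replicates = reps, summary = sm,
                 n_iterations = n_iterations, seed = seed),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat("PSA:", max(x$replicates$replicate), "replicates of",
      x$n_iterations, "iterations\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Look up one statistic from a replicate summary
#'
#' @param rs A [replicate_psa()] result.
#' @param statistic Statistic name as it appears in `rs$summary`.
#' @return One-row data.frame with `mean`, `cri_low`, `cri_high`.
#' @export
summary_value <- function(rs, statistic) {
  i <- match(statistic, rs$summary$statistic)
  if (is.na(i)) stop("unknown statistic: ", statistic)
  rs$summary[i, c("mean", "cri_low", "cri_high")]
}

#' Running-statistic convergence profile
#'
#' Runs one PSA at `max_iterations` and reports the running ICER and mean
#' incremental net monetary benefit (at the first configured threshold) at
#' each checkpoint. A checkpoint is flagged stable when the running ICER
#' changes by less than `tolerance` (relative) from the previous
#' checkpoint.
#'
#' @inheritParams run_psa
#' @param max_iterations Total iterations simulated.
#' @param checkpoints Increasing iteration counts at which to evaluate.
#' @param tolerance Relative-change stability criterion.
#' @return `data.frame(iterations, icer, mean_inmb, stable)`.
#' @export
convergence_profile <- function(specs, hti, config, max_iterations = 10000L,
                                checkpoints = seq(500L, 10000L, by = 500L),
                                seed = NULL, tolerance = 0.01) {
  if (is.unsorted(checkpoints, strictly = TRUE)) {
    stop("checkpoints must be strictly increasing")
  }
  if (max(checkpoints) > max_iterations) {
    stop("checkpoints exceed max_iterations")
  }
  psa <- run_psa(specs, hti, config, max_iterations, seed = seed)
  lambda <- config$thresholds[1]
  out <- data.frame(iterations = checkpoints, icer = NA_real_,
                    mean_inmb = NA_real_, stable = NA)
  prev <- NA_real_
  for (j in seq_along(checkpoints)) {
    h <- psa[seq_len(checkpoints[j]), , drop = FALSE]
    dc <- mean(h$cost_hti) - mean(h$cost_std)
    de <- mean(h$qaly_hti) - mean(h$qaly_std)
    out$icer[j] <- dc / de
    out$mean_inmb[j] <- lambda * de - dc
    out$stable[j] <- !is.na(prev) &&
      abs(out$icer[j] - prev) < tolerance * abs(prev)
    prev <- out$icer[j]
  }
  out
}
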