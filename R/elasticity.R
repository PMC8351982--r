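# Price-versus-efficacy threshold analysis: the maximum adjunct price
# keeping the probability of cost-effectiveness >= 0.5, swept over the
# relative risk reduction, with a through-origin line fit.

#' Maximum cost-effective adjunct price for a price-exclusive PSA
#'
#' Given PSA samples generated with the adjunct price excluded from
#' costs, returns the largest price `p` such that the fraction of
#' iterations with `lambda * dQALY - dCost - p > 0` is at least 0.5.
#' Because the price enters the incremental cost additively, once, at
#' cycle 0, undiscounted, this is the median over iterations of
#' `lambda * dQALY - dCost`, floored at 0.
#'
#' @param psa A [run_psa()] result produced with `price = 0`.
#' @param lambda Willingness-to-pay threshold, USD/QALY.
#' @return USD per procedure.
#' @export
max_price_at <- function(psa, lambda) {
  if (!is.null(attr(psa, "price")) && attr(psa, "price") != 0) {
    stop("max_price_at expects PSA samples with the adjunct price excluded",
         " (run_psa(..., price = 0))")
  }
  nb0 <- lambda * (psa$qaly_hti - psa$qaly_std) -
    (psa$cost_hti - psa$cost_std)
  max(0, median(nb0))
}

#' Maximum cost-effective price as a function of efficacy
#'
#' Sweeps the RRR over `rrr_grid` (default 0 to 1 in 1\% steps). One set
#' of parameter draws (price excluded) is shared across the whole grid:
#' the standard arm is propagated once and the HTI arm re-propagated per
#' RRR value, so the curve is smooth under common random numbers. The
#' through-origin least-squares slope of price versus RRR is attached.
#'
#' @inheritParams run_psa
#' @param lambda Willingness-to-pay threshold, USD/QALY.
#' @param rrr_grid RRR values to evaluate.
#' @return List of class `elasticity_curve`: `points`
#'   (`data.frame(rrr, max_price)`), `fitted_slope` (USD per unit RRR),
#'   `lambda`, `n_iterations`.
#' @export
elasticity_curve <- function(specs, config, lambda = 50000,
                             n_iterations = 2000L, seed = NULL,
                             rrr_grid = seq(0, 1, by = 0.01)) {
  if (!is.null(seed)) set.seed(seed)
  d <- sample_draws(specs, hti_efficacy("fixed", fixed_value = 0),
                    n_iterations)
  std <- propagate_cohort(d, config, "standard", price = 0)
  nmb_std <- lambda * std$qaly - std$cost
  pts <- data.frame(rrr = rrr_grid, max_price = NA_real_)
  for (j in seq_along(rrr_grid)) {
    d$rrr <- rep(rrr_grid[j], n_iterations)
    adj <- propagate_cohort(d, config, "hti", price = 0)
    nb0 <- (lambda * adj$qaly - adj$cost) - nmb_std
    pts$max_price[j] <- max(0, median(nb0))
  }
  structure(list(points = pts,
                 fitted_slope = fit_through_origin(pts[, c("rrr",
                                                           "max_price")]),
                 lambda = lambda, n_iterations = n_iterations),
            class = "elasticity_curve")
}

#' @export
print.elasticity_curve <- function(x, ...) {
  cat(sprintf(
    "Maximum cost-effective price vs RRR at $%s/QALY (%d points)\n",
    format(x$lambda, big.mark = ","), nrow(x$points)))
  cat(sprintf("  fitted through-origin slope: $%.0f per unit RRR\n",
              x$fitted_slope))
  invisible(x)
}

#' Least-squares slope through the origin
#'
#' `sum(x y) / sum(x^2)` for points `(x, y)`.
#'
#' @param points Two-column data.frame or matrix (x, y), >= 2 rows.
#' @return Slope.
#' @export
fit_through_origin <- function(points) {
  points <- as.data.frame(points)
  if (nrow(points) < 2L) stop("need at least 2 points")
  x <- points[[1]]
  y <- points[[2]]
  if (all(x == 0)) stop("degenerate fit: all x are 0")
  sum(x * y) / sum(x * x)
}
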