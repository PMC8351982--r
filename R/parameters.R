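# Parameter registry: distribution construction from printed moments,
# ordered/truncated sampling, and time-scale conversion of probabilities.

PARAM_COLUMNS <- c(
  "id", "name", "mean", "se", "dist_family", "source_duration_years",
  "sens_low", "sens_high", "group", "order_group", "order_rank"
)

DIST_FAMILIES <- c(
  "beta", "gamma", "truncated_ordered_normal", "uniform", "deterministic"
)

#' Load the model parameter table
#'
#' Reads a parameter table in the package CSV schema (columns `id`, `name`,
#' `mean`, `se`, `dist_family`, `source_duration_years`, `sens_low`,
#' `sens_high`, `group`, `order_group`, `order_rank`; one row per model
#' variable). With `path = NULL` the bundled default table is returned: the
#' 25 variables of the UIA coiling model, i.e. transition probabilities
#' (procedural complications, recanalization, retreatment, de novo
#' aneurysms, rupture, aSAH outcomes), procedure and annual care costs in
#' 2018 USD, health-state utilities, and the adjunct efficacy/price rows.
#'
#' `source_duration_years` is the period over which a probability is
#' quoted (0 means per event/procedure); [per_cycle_probability()] converts
#' it to the model's cycle length. `sens_low`/`sens_high` are the one-way
#' sensitivity-analysis bounds. `order_group`/`order_rank` mark variables
#' whose joint draw must be ordered (values ascending in `order_rank`).
#'
#' @param path Path to a CSV file, or `NULL` for the bundled default.
#' @return A `data.frame` of class `cea_parameters`.
#' @export
#' @examples
#' specs <- load_parameter_table()
#' specs[specs$id == 4, c("name", "mean", "se")]
load_parameter_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "parameters.csv",
                        package = "coilcea", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("parameter table not found: ", path)
  specs <- read.csv(path, stringsAsFactors = FALSE)
  validate_parameter_table(specs)
}

validate_parameter_table <- function(specs) {
  missing_cols <- setdiff(PARAM_COLUMNS, names(specs))
  if (length(missing_cols)) {
    stop("parameter table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("id", "mean", "se", "source_duration_years",
                "sens_low", "sens_high", "order_rank")) {
    if (!is.numeric(specs[[col]]) && !all(is.na(specs[[col]]))) {
      bad <- which(!is.na(specs[[col]]) &
                     is.na(suppressWarnings(as.numeric(specs[[col]]))))
      if (length(bad)) {
        stop("parameter table schema error: non-numeric '", col,
             "' in row(s) ", paste(bad, collapse = ", "))
      }
      specs[[col]] <- suppressWarnings(as.numeric(specs[[col]]))
    }
  }
  if (anyNA(specs$id)) stop("parameter table schema error: missing id")
  if (anyDuplicated(specs$id)) {
    stop("parameter table schema error: duplicate id ",
         paste(unique(specs$id[duplicated(specs$id)]), collapse = ", "))
  }
  expected <- seq_len(25L)
  if (nrow(specs) != 25L || !setequal(specs$id, expected)) {
    stop("parameter table schema error: expected exactly 25 rows with ids ",
         "1-25, got ", nrow(specs), " rows (missing: ",
         paste(setdiff(expected, specs$id), collapse = ", "), ")")
  }
  bad_fam <- setdiff(unique(specs$dist_family), DIST_FAMILIES)
  if (length(bad_fam)) {
    stop("parameter table schema error: unknown dist_family ",
         paste(bad_fam, collapse = ", "))
  }
  specs <- specs[order(specs$id), , drop = FALSE]
  rownames(specs) <- NULL
  prob <- specs$group == "probability"
  if (any(prob & (specs$mean < 0 | specs$mean > 1))) {
    stop("probability mean outside [0, 1] in row id ",
         paste(specs$id[prob & (specs$mean < 0 | specs$mean > 1)],
               collapse = ", "))
  }
  if (any(specs$group == "cost" & specs$mean < 0)) {
    stop("negative cost mean in row id ",
         paste(specs$id[specs$group == "cost" & specs$mean < 0],
               collapse = ", "))
  }
  # sensitivity bounds must bracket the mean (the disutility row stores its
  # magnitude bounds 0 and -0.152 and is exempt)
  has_b <- !is.na(specs$sens_low) & !is.na(specs$sens_high) & specs$id != 22L
  bad_b <- has_b & (specs$sens_low > specs$mean | specs$mean > specs$sens_high)
  if (any(bad_b)) {
    stop("sensitivity bounds do not bracket the mean in row id ",
         paste(specs$id[bad_b], collapse = ", "))
  }
  for (g in unique(specs$order_group[!is.na(specs$order_group) &
                                       nzchar(specs$order_group)])) {
    rk <- specs$order_rank[specs$order_group %in% g]
    if (anyNA(rk) || anyDuplicated(rk)) {
      stop("order_rank values must be distinct and present in group '",
           g, "'")
    }
  }
  class(specs) <- c("cea_parameters", "data.frame")
  specs
}

#' Beta distribution from a printed mean and standard error
#'
#' Moment matching: `nu = mean (1 - mean) / se^2 - 1`, `alpha = mean nu`,
#' `beta = (1 - mean) nu`, so the Beta has exactly the given mean and
#' variance `se^2`.
#'
#' @param mean Mean in (0, 1).
#' @param se Standard error, `se^2 < mean (1 - mean)`.
#' @return Named vector `c(alpha, beta)`.
#' @export
beta_from_moments <- function(mean, se) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1) {
    stop("beta_from_moments: mean must lie in (0, 1)")
  }
  if (!is.finite(se) || se <= 0) stop("beta_from_moments: se must be > 0")
  if (se^2 >= mean * (1 - mean)) {
    stop("infeasible moments: se^2 >= mean (1 - mean)")
  }
  nu <- mean * (1 - mean) / se^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Gamma distribution from a printed mean and standard error
#'
#' Moment matching: `shape = mean^2 / se^2`, `scale = se^2 / mean`.
#'
#' @param mean Mean, > 0.
#' @param se Standard error, > 0.
#' @return Named vector `c(shape, scale)`.
#' @export
gamma_from_moments <- function(mean, se) {
  if (!is.finite(mean) || mean <= 0 || !is.finite(se) || se <= 0) {
    stop("gamma_from_moments: mean and se must be > 0")
  }
  c(shape = mean^2 / se^2, scale = se^2 / mean)
}

# mean of N(mu, sd) truncated to [lower, upper]; the one-sided case uses
# a log-scale Mills ratio so deep-tail locations stay finite
truncnorm_mean <- function(mu, sd, lower, upper) {
  a <- (lower - mu) / sd
  if (!is.finite(upper)) {
    mills <- exp(dnorm(a, log = TRUE) -
                   pnorm(a, lower.tail = FALSE, log.p = TRUE))
    return(mu + sd * mills)
  }
  b <- (upper - mu) / sd
  z <- pnorm(b) - pnorm(a)
  mu + sd * (dnorm(a) - dnorm(b)) / z
}

# location parameter such that the truncated-normal mean equals the target
# printed mean (keeps published moments honest even when the truncation
# bound is close, e.g. a cost with SE comparable to its mean)
truncnorm_location <- function(target_mean, sd, lower, upper) {
  if (sd == 0) return(target_mean)
  f <- function(mu) truncnorm_mean(mu, sd, lower, upper) - target_mean
  uniroot(f, lower = target_mean - 10 * sd, upper = target_mean + 10 * sd,
          tol = 1e-9 * max(1, abs(target_mean)))$root
}

# exact inverse-CDF sampler for a truncated normal
rtruncnorm <- function(n, mu, sd, lower, upper) {
  if (sd == 0) return(rep(mu, n))
  pa <- pnorm(lower, mu, sd)
  pb <- pnorm(upper, mu, sd)
  qnorm(runif(n, pa, pb), mu, sd)
}

natural_bounds <- function(group) {
  if (group == "utility") c(0, 1) else c(0, Inf)
}

# inverse CDF of a truncated normal at probability q
qtruncnorm <- function(q, mu, sd, lower, upper) {
  if (sd == 0) return(rep(mu, length(q)))
  pa <- pnorm(lower, mu, sd)
  pb <- pnorm(upper, mu, sd)
  qnorm(pa + q * (pb - pa), mu, sd)
}

#' Sample an ordered group of truncated normal variables
#'
#' Draws each member from a normal truncated to its natural bounds (costs
#' non-negative, utilities in \[0, 1\]), with the location parameter
#' adjusted so the truncated marginal mean equals the printed mean. The
#' group ordering (ascending in `order_rank`) is imposed either by
#' comonotonic sampling (`"quantile"`, the default used by the PSA: one
#' shared uniform mapped through each member's inverse CDF, which
#' preserves every printed marginal exactly and orders the draw whenever
#' the quantile curves do not cross) or by group-level rejection
#' (`"rejection"`: redraw independent draws until ordered, which
#' guarantees the ordering in every draw at the price of shifting the
#' conditional marginals of strongly overlapping groups).
#'
#' @param specs Rows of a [load_parameter_table()] table sharing one
#'   `order_group`.
#' @param n Number of joint draws.
#' @param method `"quantile"` (comonotonic) or `"rejection"`.
#' @param max_tries Rejection budget per call (rejection method).
#' @return Matrix `n x k`, columns named `v<id>`, in rank order.
#' @export
sample_ordered_truncated_normal_group <- function(specs, n,
                                                  method = c("quantile",
                                                             "rejection"),
                                                  max_tries = 10000L) {
  method <- match.arg(method)
  og <- unique(specs$order_group)
  if (length(og) != 1L || is.na(og) || !nzchar(og)) {
    stop("specs must share a single order_group")
  }
  specs <- specs[order(specs$order_rank), , drop = FALSE]
  k <- nrow(specs)
  lo <- numeric(k); hi <- numeric(k); mu <- numeric(k)
  for (j in seq_len(k)) {
    b <- natural_bounds(specs$group[j])
    lo[j] <- b[1]; hi[j] <- b[2]
    mu[j] <- truncnorm_location(specs$mean[j], specs$se[j], b[1], b[2])
  }
  if (method == "quantile") {
    q <- runif(n)
    x <- vapply(seq_len(k),
                function(j) qtruncnorm(q, mu[j], specs$se[j], lo[j], hi[j]),
                numeric(n))
    x <- matrix(x, nrow = n)
  } else {
    draw_rows <- function(m) {
      vapply(seq_len(k),
             function(j) rtruncnorm(m, mu[j], specs$se[j], lo[j], hi[j]),
             numeric(m))
    }
    x <- matrix(draw_rows(n), nrow = n)
    ordered_ok <- function(m) {
      ok <- rep(TRUE, nrow(m))
      for (j in seq_len(k - 1L)) ok <- ok & m[, j] <= m[, j + 1L]
      ok
    }
    tries <- 0L
    repeat {
      bad <- which(!ordered_ok(x))
      if (!length(bad)) break
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("sampling failure: ordering of group '", og,
             "' not reached within ", max_tries, " redraws")
      }
      x[bad, ] <- matrix(draw_rows(length(bad)), nrow = length(bad))
    }
  }
  colnames(x) <- paste0("v", specs$id)
  x
}

#' Adjunct (HTI) efficacy distribution
#'
#' Describes the distribution of the relative risk reduction (RRR) in
#' aneurysm recanalization conferred by the adjunct: `uniform01` (the base
#' case, expected RRR 50\%), `bounded_normal` (a normal truncated to
#' \[0, 1\], used in scenario and EVPPI analyses), or `fixed` (a point
#' value, used in the price-elasticity sweep).
#'
#' @param family One of `"uniform01"`, `"bounded_normal"`, `"fixed"`.
#' @param mu,sigma Mean and SD of the untruncated normal
#'   (`bounded_normal` only).
#' @param fixed_value Point RRR in \[0, 1\] (`fixed` only).
#' @return An object of class `hti_spec`.
#' @export
hti_efficacy <- function(family = c("uniform01", "bounded_normal", "fixed"),
                         mu = 0.5, sigma = 0.15, fixed_value = 0.5) {
  family <- match.arg(family)
  if (family == "bounded_normal") {
    if (!is.finite(mu) || !is.finite(sigma) || sigma <= 0) {
      stop("bounded_normal requires finite mu and sigma > 0")
    }
  }
  if (family == "fixed") {
    if (!is.finite(fixed_value) || fixed_value < 0 || fixed_value > 1) {
      stop("fixed_value must lie in [0, 1]")
    }
  }
  structure(list(family = family, mu = mu, sigma = sigma,
                 fixed_value = fixed_value),
            class = "hti_spec")
}

#' @export
print.hti_spec <- function(x, ...) {
  cat("HTI efficacy (RRR):",
      switch(x$family,
             uniform01 = "uniform on [0, 1]",
             bounded_normal = sprintf("normal(%.3g, %.3g) bounded to [0, 1]",
                                      x$mu, x$sigma),
             fixed = sprintf("fixed at %.3g", x$fixed_value)),
      "\n")
  invisible(x)
}

sample_rrr <- function(hti, n) {
  switch(hti$family,
         uniform01 = runif(n),
         fixed = rep(hti$fixed_value, n),
         bounded_normal = {
           x <- rnorm(n, hti$mu, hti$sigma)
           bad <- which(x < 0 | x > 1)
           while (length(bad)) {
             x[bad] <- rnorm(length(bad), hti$mu, hti$sigma)
             bad <- bad[x[bad] < 0 | x[bad] > 1]
           }
           x
         })
}

normalize_fixed <- function(fixed) {
  if (is.null(fixed) || !length(fixed)) return(NULL)
  nm <- names(fixed)
  if (is.null(nm) || any(!nzchar(nm))) stop("'fixed' must be a named list")
  nm <- ifelse(grepl("^[0-9]+$", nm), paste0("v", nm), nm)
  names(fixed) <- nm
  fixed
}

# one unvalidated pass of joint sampling; returns an n-row data.frame with
# columns v1..v23, v25 and rrr
sample_draws_once <- function(specs, hti, n) {
  out <- list()
  in_group <- !is.na(specs$order_group) & nzchar(specs$order_group)
  for (r in seq_len(nrow(specs))) {
    sp <- specs[r, ]
    if (in_group[r] || sp$id == 24L) next
    key <- paste0("v", sp$id)
    out[[key]] <- switch(
      sp$dist_family,
      beta = {
        # the disutility row is a negative decrement with Beta magnitude
        m <- abs(sp$mean)
        ab <- beta_from_moments(m, sp$se)
        x <- rbeta(n, ab[["alpha"]], ab[["beta"]])
        if (sp$mean < 0) -x else x
      },
      gamma = {
        gp <- gamma_from_moments(sp$mean, sp$se)
        rgamma(n, shape = gp[["shape"]], scale = gp[["scale"]])
      },
      truncated_ordered_normal = {
        b <- natural_bounds(sp$group)
        mu <- truncnorm_location(sp$mean, sp$se, b[1], b[2])
        rtruncnorm(n, mu, sp$se, b[1], b[2])
      },
      deterministic = rep(sp$mean, n),
      uniform = runif(n),
      stop("unsupported dist_family: ", sp$dist_family)
    )
  }
  for (g in unique(specs$order_group[in_group])) {
    grp <- sample_ordered_truncated_normal_group(
      specs[specs$order_group %in% g, , drop = FALSE], n)
    for (cn in colnames(grp)) out[[cn]] <- grp[, cn]
  }
  out$rrr <- sample_rrr(hti, n)
  as.data.frame(out)[, c(paste0("v", setdiff(specs$id, 24L)), "rrr")]
}

draws_feasible <- function(d) {
  (d$v1 + d$v2 + d$v3 < 1) & (d$v9 + d$v10 + d$v11 < 1)
}

#' Sample joint parameter realizations
#'
#' Draws `n` independent realizations of every model variable from its
#' distribution family (Beta/Gamma moment-matched to the printed mean and
#' SE, mean-preserving truncated normals with group-level ordering, point
#' values for deterministic rows) plus the adjunct RRR from `hti`. Rare
#' draws violating joint feasibility (procedural or aSAH outcome
#' probabilities summing past 1) are rejected and redrawn, preserving the
#' stated marginals; the redraw count is returned as attribute
#' `n_redrawn`.
#'
#' @param specs A [load_parameter_table()] table.
#' @param hti An [hti_efficacy()] spec.
#' @param n Number of joint draws.
#' @param fixed Optional named list of overrides, e.g.
#'   `list(v4 = 0.3158)` or `list(rrr = 0.5)`; values are recycled to
#'   length `n`. Used by the tornado and EVPPI analyses.
#' @return A `data.frame` with `n` rows and columns `v1..v23`, `v25`,
#'   `rrr`; attribute `durations` carries each variable's source period in
#'   years for cycle conversion.
#' @export
sample_draws <- function(specs, hti, n, fixed = NULL) {
  stopifnot(inherits(specs, "cea_parameters"), n >= 1)
  fixed <- normalize_fixed(fixed)
  apply_fixed <- function(d) {
    for (nm in names(fixed)) {
      if (!nm %in% names(d)) stop("unknown variable in 'fixed': ", nm)
      d[[nm]] <- rep_len(fixed[[nm]], nrow(d))
    }
    d
  }
  d <- apply_fixed(sample_draws_once(specs, hti, n))
  n_redrawn <- 0L
  tries <- 0L
  repeat {
    bad <- which(!draws_feasible(d))
    if (!length(bad)) break
    tries <- tries + 1L
    if (tries > 100L) {
      stop("infeasible draws persist after 100 redraw passes; ",
           "check parameter table (or 'fixed' overrides)")
    }
    n_redrawn <- n_redrawn + length(bad)
    d[bad, ] <- apply_fixed(sample_draws_once(specs, hti, length(bad)))
  }
  if (n_redrawn > 0.01 * n) {
    warning("more than 1% of parameter draws were infeasible and redrawn (",
            n_redrawn, " of ", n, ")")
  }
  durations <- setNames(specs$source_duration_years, paste0("v", specs$id))
  attr(d, "durations") <- durations
  attr(d, "n_redrawn") <- n_redrawn
  d
}

#' Sample a single parameter realization
#'
#' Convenience wrapper around [sample_draws()] for one joint draw,
#' returned as a `parameter_draw` object (named values plus the RRR).
#'
#' @inheritParams sample_draws
#' @param seed Optional integer seed.
#' @return An object of class `parameter_draw`.
#' @export
sample_draw <- function(specs, hti, seed = NULL, fixed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- sample_draws(specs, hti, 1L, fixed = fixed)
  structure(list(values = unlist(d[1, , drop = TRUE]),
                 rrr = d$rrr[1],
                 durations = attr(d, "durations")),
            class = "parameter_draw")
}

# accept either a parameter_draw or an n-row draws data.frame
as_draws <- function(draw) {
  if (inherits(draw, "parameter_draw")) {
    d <- as.data.frame(as.list(draw$values))
    attr(d, "durations") <- draw$durations
    return(d)
  }
  if (is.data.frame(draw)) return(draw)
  stop("expected a parameter_draw or a draws data.frame")
}

#' Convert a probability to the model cycle length
#'
#' Constant-hazard conversion `1 - (1 - p)^(cycle_years / duration)`. A
#' probability quoted per event or per procedure (`source_duration_years =
#' 0`) passes through unchanged; when the quoted period equals the cycle
#' length the input is returned exactly.
#'
#' @param p Probability (vectorized).
#' @param source_duration_years Period the probability is quoted over, in
#'   years; 0 means per event.
#' @param cycle_years Model cycle length in years.
#' @return Per-cycle probability.
#' @export
per_cycle_probability <- function(p, source_duration_years,
                                  cycle_years = 0.5) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  if (length(source_duration_years) == 1L) {
    source_duration_years <- rep_len(source_duration_years, length(p))
  }
  out <- p
  # identity when the quoted period already matches the cycle
  conv <- source_duration_years > 0 & source_duration_years != cycle_years
  if (any(p[conv] == 1)) {
    stop("degenerate probability: p = 1 cannot be rescaled to the cycle")
  }
  out[conv] <- 1 - (1 - p[conv])^(cycle_years / source_duration_years[conv])
  out
}
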