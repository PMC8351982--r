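# shared fixtures: everything is built in code at test time

default_specs <- local({
  specs <- NULL
  function() {
    if (is.null(specs)) specs <<- load_parameter_table()
    specs
  }
})

# a parameter_draw pinned at the printed Table means
means_draw <- function(specs = default_specs(), rrr = 0.5) {
  vals <- setNames(specs$mean, paste0("v", specs$id))
  vals <- vals[names(vals) != "v24"]
  structure(list(values = c(vals, rrr = rrr), rrr = rrr,
                 durations = setNames(specs$source_duration_years,
                                      paste0("v", specs$id))),
            class = "parameter_draw")
}

# degenerate draw: no model events, fixed utilities/costs
zero_event_draw <- function(u_mrs0 = 0.87) {
  vals <- c(v1 = 0, v2 = 0, v3 = 0, v4 = 0, v5 = 0, v6 = 0, v7 = 0,
            v8 = 0, v9 = 0, v10 = 0, v11 = 0,
            v12 = 30013, v13 = 47237, v14 = 65336,
            v15 = 11197, v16 = 12132, v17 = 42257, v18 = 93440,
            v19 = u_mrs0, v20 = 0.72, v21 = 0.41, v22 = 0, v23 = 0.41,
            v25 = 10000)
  structure(list(values = c(vals, rrr = 0), rrr = 0,
                 durations = c(v4 = 6, v5 = 6, v6 = 1, v7 = 1)),
            class = "parameter_draw")
}

# configuration with no discounting, no background mortality and a flat
# mRS 0 utility across age bands (closed-form accruals)
flat_cfg <- function(...) {
  model_config(discount_rate = 0, background_mortality = FALSE,
               utility_band_offsets = c(0, 0, 0, 0), ...)
}

# hand-built PSA sample sets for the analytic VOI checks
make_psa <- function(cost_std, qaly_std, cost_hti, qaly_hti, price = 0) {
  out <- data.frame(iteration = seq_along(cost_std), rrr = 0.5,
                    cost_std = cost_std, qaly_std = qaly_std,
                    cost_hti = cost_hti, qaly_hti = qaly_hti)
  attr(out, "price") <- price
  class(out) <- c("psa_samples", "data.frame")
  out
}
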