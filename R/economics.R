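#' Discount a value to present terms
#'
#' Flows occur at cycle start: year 0 is undiscounted.
#'
#' @param value Amount (USD or QALY).
#' @param year_index Years from the start (0, 1, 2, ...).
#' @param rate Annual discount rate (>= 0).
#' @return `value / (1 + rate)^year_index`.
#' @export
#' @examples
#' discount(100, 1, 0.03)
discount <- function(value, year_index, rate) {
  stopifnot(rate >= 0, all(year_index >= 0))
  value / (1 + rate)^year_index
}

#' Accrue discounted costs and QALYs from a trace
#'
#' Sums `count(t, s) * schedule(s)` over cycles and states with 3% (or any)
#' annual discounting, cycle 1 undiscounted. Death contributes nothing.
#'
#' @param trace An `ssb_trace`.
#' @param costs Named cost schedule over [health_states()]
#'   (see [cost_schedule()]).
#' @param utilities Named utility schedule (see [utility_schedule()]).
#' @param rate Annual discount rate.
#' @return List with `total_cost` (USD) and `total_qaly` (QALY), model scale.
#' @export
accrue <- function(trace, costs, utilities, rate = 0.03) {
  sc <- trace$state_counts
  if (!all(colnames(sc) %in% names(costs)) ||
      !all(colnames(sc) %in% names(utilities))) {
    stop("schedules do not cover all states in the trace")
  }
  if (trace$horizon == 0) return(list(total_cost = 0, total_qaly = 0))
  disc <- (1 + rate)^(-(seq_len(trace$horizon) - 1))
  list(
    total_cost = sum(disc * (sc %*% costs[colnames(sc)])),
    total_qaly = sum(disc * (sc %*% utilities[colnames(sc)]))
  )
}

#' Discounted tax revenue and administration cost streams
#'
#' Revenue and its administration cost accrue annually over the horizon and
#' are discounted at the same rate as all other flows.
#'
#' @param annual_revenue Annual tax revenue (USD/y).
#' @param admin_fraction Administration cost as a fraction of revenue.
#' @param horizon Number of years.
#' @param rate Annual discount rate.
#' @return List with `revenue_total` and `admin_total` (discounted USD).
#' @export
#' @examples
#' revenue_stream(862722888, 0.01, 20, 0.03)
revenue_stream <- function(annual_revenue, admin_fraction, horizon, rate) {
  stopifnot(admin_fraction >= 0, admin_fraction <= 1)
  if (horizon == 0) return(list(revenue_total = 0, admin_total = 0))
  annuity <- sum((1 + rate)^(-(seq_len(horizon) - 1)))
  list(revenue_total = annual_revenue * annuity,
       admin_total = annual_revenue * admin_fraction * annuity)
}

#' Incremental cost-effectiveness ratio
#'
#' @param cost_tax,cost_sq Total costs under the tax and status quo.
#' @param qaly_tax,qaly_sq Total QALYs under the tax and status quo.
#' @return An `ssb_icer`: list with `icer` (USD/QALY, `NaN` when the QALY
#'   increment is zero), `delta_cost`, `delta_qaly`, `dominant` (cost-saving
#'   and QALY-gaining) and `undefined` flags.
#' @export
#' @examples
#' icer(5000 + 10, 10, 0.05 + 1, 1)
icer <- function(cost_tax, cost_sq, qaly_tax, qaly_sq) {
  dc <- cost_tax - cost_sq
  dq <- qaly_tax - qaly_sq
  structure(list(
    icer = if (dq == 0) NaN else dc / dq,
    delta_cost = dc, delta_qaly = dq,
    dominant = dc < 0 && dq > 0,
    undefined = dq == 0
  ), class = "ssb_icer")
}

#' @export
print.ssb_icer <- function(x, ...) {
  if (x$undefined) {
    cat("ICER undefined (zero QALY increment)\n")
  } else {
    cat(sprintf("ICER: %s$%s per QALY%s\n", if (x$icer < 0) "-" else "",
                format(abs(round(x$icer)), big.mark = ","),
                if (x$dominant) " (dominant: cost-saving and QALY-gaining)" else ""))
  }
  invisible(x)
}

#' Rescale model-scale estimates to the target population
#'
#' @param x Count or USD amount at model scale.
#' @param factor Population rescale factor (default 1,462.36, i.e.
#'   29,247,121 Californian adults / 20,000 simulated).
#' @return `x * factor`.
#' @export
rescale <- function(x, factor = 1462.36) {
  stopifnot(factor > 0)
  x * factor
}

#' Two-perspective cost-effectiveness analysis of a pair of traces
#'
#' Accrues discounted costs and QALYs in both arms, adds the tax arm's
#' discounted revenue and administration-cost streams, and computes
#' incremental costs, ICER and net monetary benefit from the health-care
#' perspective (direct medical costs only) and the government perspective
#' (medical costs plus administration cost minus tax revenue).
#'
#' @param traces List with `status_quo` and `soda_tax` traces
#'   (from [simulate_arms()]).
#' @param params An `ssb_parameters` set.
#' @param config An `ssb_config`.
#' @param rescaled Rescale all totals to the target population?
#' @return An object of class `ssb_cea`.
#' @export
cea <- function(traces, params, config, rescaled = TRUE) {
  costs <- cost_schedule(params)
  utils_ <- utility_schedule(params)
  r <- config$discount_rate
  if (traces$soda_tax$n != config$n_individuals) {
    stop("config$n_individuals must match the simulated cohort size ",
         "(adjust rescale_factor so n * factor is the target population)")
  }
  sq <- accrue(traces$status_quo, costs, utils_, r)
  tx <- accrue(traces$soda_tax, costs, utils_, r)
  f <- if (rescaled) config$rescale_factor else 1

  # revenue and admin cost are population-level annual flows; hold their
  # model-scale share so that rescaling recovers the population totals
  rev <- revenue_stream(params$revenue$mean / config$rescale_factor,
                        0, config$horizon_years, r)$revenue_total
  # admin cost is its own parameter (1% of annual revenue at the point value)
  adm <- revenue_stream(params$admin$mean / config$rescale_factor,
                        0, config$horizon_years, r)$revenue_total

  dc_hc <- (tx$total_cost - sq$total_cost) * f
  dq <- (tx$total_qaly - sq$total_qaly) * f
  rev_f <- rev * f
  adm_f <- adm * f
  dc_gov <- dc_hc + adm_f - rev_f

  structure(list(
    rescaled = rescaled,
    arm_totals = data.frame(
      arm = c("status_quo", "soda_tax"),
      total_cost = c(sq$total_cost, tx$total_cost) * f,
      total_qaly = c(sq$total_qaly, tx$total_qaly) * f
    ),
    revenue_total = rev_f,
    admin_cost_total = adm_f,
    delta_qaly = dq,
    delta_cost_healthcare = dc_hc,
    delta_cost_government = dc_gov,
    icer_healthcare = icer(tx$total_cost * f, sq$total_cost * f,
                           tx$total_qaly * f, sq$total_qaly * f),
    icer_government = {
      ic <- icer(dc_gov, 0, dq, 0)
      ic
    },
    nmb_healthcare = config$wtp * dq - dc_hc,
    nmb_government = config$wtp * dq - dc_gov,
    wtp = config$wtp
  ), class = "ssb_cea")
}

#' @export
print.ssb_cea <- function(x, ...) {
  cat("Cost-effectiveness summary",
      if (x$rescaled) "(population scale)" else "(model scale)", "\n")
  at <- x$arm_totals
  for (i in seq_len(nrow(at))) {
    cat(sprintf("  %-10s cost $%.2f bn, QALYs %.4f bn\n", at$arm[i],
                at$total_cost[i] / 1e9, at$total_qaly[i] / 1e9))
  }
  cat(sprintf("  tax revenue (disc.) $%.2f bn; admin cost $%.3f bn\n",
              x$revenue_total / 1e9, x$admin_cost_total / 1e9))
  cat(sprintf("  delta QALY %.4g; delta cost HC $%.4g; delta cost gov $%.4g\n",
              x$delta_qaly, x$delta_cost_healthcare, x$delta_cost_government))
  cat(sprintf("  ICER (health care) %.0f; ICER (government) %.0f $/QALY\n",
              x$icer_healthcare$icer, x$icer_government$icer))
  invisible(x)
}

#' Export a CEA summary as CSV
#'
#' @param x An `ssb_cea`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cea_csv <- function(x, path) {
  rows <- data.frame(
    item = c("total_qaly_status_quo", "total_qaly_soda_tax",
             "total_cost_hc_status_quo", "total_cost_hc_soda_tax",
             "tax_revenue_total", "admin_cost_total",
             "delta_qaly", "delta_cost_healthcare", "delta_cost_government",
             "icer_healthcare", "icer_government",
             "nmb_healthcare", "nmb_government"),
    value = c(x$arm_totals$total_qaly[1], x$arm_totals$total_qaly[2],
              x$arm_totals$total_cost[1], x$arm_totals$total_cost[2],
              x$revenue_total, x$admin_cost_total,
              x$delta_qaly, x$delta_cost_healthcare, x$delta_cost_government,
              x$icer_healthcare$icer, x$icer_government$icer,
              x$nmb_healthcare, x$nmb_government),
    units = c("QALY", "QALY", "2022 USD", "2022 USD", "2022 USD", "2022 USD",
              "QALY", "2022 USD", "2022 USD", "2022 USD/QALY",
              "2022 USD/QALY", "2022 USD", "2022 USD")
  )
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
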