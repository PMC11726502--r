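#' Arm specification
#'
#' @param name `"status_quo"` or `"soda_tax"`.
#' @param weight_effect Annual weight change attributable to the tax (kg/y);
#'   must be 0 for the status-quo arm. The default tax effect is the
#'   published -0.56 kg/y.
#' @return An object of class `ssb_arm`.
#' @export
arm_spec <- function(name = c("status_quo", "soda_tax"), weight_effect = NULL) {
  name <- match.arg(name)
  if (is.null(weight_effect)) {
    weight_effect <- if (name == "status_quo") 0 else -0.56
  }
  if (name == "status_quo" && weight_effect != 0) {
    stop("status-quo arm must have zero weight effect")
  }
  structure(list(name = name, weight_effect = weight_effect), class = "ssb_arm")
}

#' One annual weight update
#'
#' Adds the individual's natural weight gain for the year and the arm's tax
#' weight effect; weight is floored at 30 kg to guard against pathological
#' draws in sensitivity analysis.
#'
#' @param weight Current weight (kg), vectorised.
#' @param gain Natural annual gain (kg/y), drawn uniformly from the
#'   population gain range.
#' @param weight_effect Arm weight effect (kg/y; 0 without the tax).
#' @return Updated weight (kg).
#' @export
#' @examples
#' weight_step(80, 0.68, -0.56)
weight_step <- function(weight, gain, weight_effect = 0) {
  pmax(30, weight + gain + weight_effect)
}

#' Convert daily sugar intake to daily calories
#'
#' One gram of sugar carries roughly 4 kcal, so the 3.08 g/day reduction in
#' added sugar observed after a 1-cent-per-ounce tax corresponds to 12.32
#' fewer kcal/day.
#'
#' @param grams_per_day Grams of sugar per day (may be negative for a bound).
#' @param kcal_per_gram kcal per gram of sugar (default 4).
#' @return kcal per day.
#' @export
#' @examples
#' sugar_to_calories(3.08)
sugar_to_calories <- function(grams_per_day, kcal_per_gram = 4) {
  kcal_per_gram * grams_per_day
}

#' Convert a sustained daily calorie change to an annual weight-change rate
#'
#' Static energy-balance rule: a pound of body weight corresponds to an
#' energy store of about 3,500 kcal, so a sustained deficit of `d` kcal/day
#' implies `d * 365 / 3500 / 2.20462` kg lost per year. This converter
#' documents the provenance of the tax weight effect; the simulation itself
#' takes the published -0.56 kg/y as its input.
#'
#' @param kcal_per_day Sustained calorie change (kcal/day).
#' @param days_per_year Days per year (365).
#' @param kcal_per_pound kcal per pound of body weight (3,500).
#' @param lb_per_kg Pounds per kilogram (2.20462).
#' @return Weight-change rate in kg/year.
#' @export
#' @examples
#' calories_to_weight_rate(12.32)
calories_to_weight_rate <- function(kcal_per_day, days_per_year = 365,
                                    kcal_per_pound = 3500,
                                    lb_per_kg = 2.20462) {
  kcal_per_day * days_per_year / kcal_per_pound / lb_per_kg
}

# one annual cycle, vectorised over individuals.
# state: integer codes into .STATES; gain/u: this cycle's random numbers.
# Order: weight update -> BMI reclassification (weight-governed states only)
# -> occupancy recorded -> one categorical transition draw -> tunnel
# promotion for stroke/MI stayers.
.advance_cycle <- function(state, weight, height, gain, u, cum_t,
                           weight_effect) {
  alive <- state != 10L
  weight[alive] <- weight_step(weight[alive], gain[alive], weight_effect)
  wg <- alive & state <= 3L
  state[wg] <- .classify_bmi_int(weight[wg], height[wg])
  occ <- state  # state occupied during this cycle (accrual basis)

  cum_rows <- cum_t[state, , drop = FALSE]
  k <- rowSums(u > cum_rows) + 1L
  moved <- k <= 10L
  dest <- state
  dest[moved] <- k[moved]
  # tunnel: an acute-event year not ended by another transition becomes the
  # chronic post-event state next cycle
  stayed <- !moved
  dest[stayed & state == 5L] <- 6L
  dest[stayed & state == 7L] <- 8L

  events <- c(
    diabetes = sum(dest == 4L & occ != 4L),
    stroke   = sum(dest == 5L & occ != 5L),
    mi       = sum(dest == 7L & occ != 7L),
    esrd     = sum(dest == 9L & occ != 9L),
    death    = sum(dest == 10L & occ != 10L)
  )
  list(state = dest, occ = occ, weight = weight, events = events)
}

#' Simulate one arm of the microsimulation
#'
#' Advances the cohort through `config$horizon_years` annual cycles. Each
#' cycle applies, in order: a per-person uniform natural weight gain plus the
#' arm's tax weight effect; BMI reclassification for individuals in
#' weight-governed states; at most one sampled transition from the current
#' state's row of the transition matrix (residual mass = stay); and tunnel
#' promotion of stroke/MI stayers into poststroke/post-MI. Death is
#' absorbing. All random numbers (gains and transition uniforms) are drawn
#' up front from `seed`, so two arms run with the same seed share common
#' random numbers and differ only through `weight_effect`.
#'
#' @param cohort An `ssb_cohort` from [generate_cohort()].
#' @param tmat 10 x 10 transition matrix from [transition_matrix()].
#' @param config An `ssb_config`.
#' @param seed Integer seed for the arm's random streams.
#' @param weight_effect Arm weight effect (kg/y).
#' @param natural_gain_range Length-2 vector, uniform bounds of annual
#'   natural weight gain (kg/y).
#' @param arm Arm label stored in the trace.
#' @return An object of class `ssb_trace`: per-cycle occupancy counts
#'   (`state_counts`, horizon x 10), per-cycle incident events (`events`),
#'   ever-in-category counts for overweight/obesity, and the final state
#'   vector.
#' @export
simulate_arm <- function(cohort, tmat, config, seed,
                         weight_effect = 0,
                         natural_gain_range = c(0.45, 0.91),
                         arm = if (weight_effect == 0) "status_quo" else "soda_tax") {
  stopifnot(inherits(cohort, "ssb_cohort"))
  n <- nrow(cohort)
  H <- config$horizon_years
  state <- match(cohort$state, .STATES)
  if (anyNA(state)) stop("cohort contains unknown states")
  weight <- cohort$weight
  height <- cohort$height
  cum_t <- t(apply(tmat, 1, cumsum))

  state_counts <- matrix(0L, nrow = H, ncol = 10,
                         dimnames = list(NULL, .STATES))
  ev_names <- c("diabetes", "stroke", "mi", "esrd", "death")
  events <- matrix(0L, nrow = H, ncol = 5, dimnames = list(NULL, ev_names))
  ever_ow <- state == 2L
  ever_ob <- state == 3L

  if (H > 0) {
    set.seed(as.integer(seed))
    gain <- matrix(stats::runif(n * H, natural_gain_range[1],
                                natural_gain_range[2]), n, H)
    u <- matrix(stats::runif(n * H), n, H)
    for (t in seq_len(H)) {
      step <- .advance_cycle(state, weight, height, gain[, t], u[, t],
                             cum_t, weight_effect)
      state <- step$state
      weight <- step$weight
      state_counts[t, ] <- tabulate(step$occ, 10L)
      events[t, ] <- step$events
      ever_ow <- ever_ow | step$occ == 2L
      ever_ob <- ever_ob | step$occ == 3L
    }
  }
  structure(list(arm = arm, n = n, horizon = H,
                 weight_effect = weight_effect,
                 state_counts = state_counts, events = events,
                 ever = c(overweight = sum(ever_ow), obesity = sum(ever_ob)),
                 final_state = .STATES[state]),
            class = "ssb_trace")
}

#' @export
print.ssb_trace <- function(x, ...) {
  cat(sprintf("Microsimulation trace: arm=%s, n=%d, %d cycles\n",
              x$arm, x$n, x$horizon))
  cat("  cumulative incident events:\n")
  tot <- colSums(x$events)
  for (nm in names(tot)) cat(sprintf("    %-9s %d\n", nm, tot[nm]))
  cat(sprintf("  ever overweight %d, ever obese %d\n",
              x$ever["overweight"], x$ever["obesity"]))
  invisible(x)
}

#' Simulate both arms with common random numbers
#'
#' Runs the status-quo and soda-tax arms from the same seed so that all
#' stochastic inputs (natural weight gains and transition uniforms) are
#' shared and the arms differ only through the tax weight effect.
#'
#' @param cohort An `ssb_cohort`.
#' @param params An `ssb_parameters` set.
#' @param config An `ssb_config`.
#' @param seed Integer seed shared by both arms.
#' @param weight_effect Tax-arm weight effect; defaults to the parameter
#'   set's point value.
#' @return List with `status_quo` and `soda_tax` traces.
#' @export
simulate_arms <- function(cohort, params, config, seed,
                          weight_effect = params$weight_effect$mean) {
  tmat <- transition_matrix(params$transitions)
  gr <- params$natural_gain_range
  list(
    status_quo = simulate_arm(cohort, tmat, config, seed, 0, gr, "status_quo"),
    soda_tax = simulate_arm(cohort, tmat, config, seed, weight_effect, gr,
                            "soda_tax")
  )
}

#' Export a trace as long-format CSV
#'
#' Writes `cycle,state,count` occupancy rows followed by
#' `cycle,event,count` incident-event rows (the `kind` column distinguishes
#' them).
#'
#' @param trace An `ssb_trace`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  occ <- data.frame(kind = "occupancy",
                    cycle = rep(seq_len(trace$horizon), times = 10),
                    name = rep(.STATES, each = trace$horizon),
                    count = as.vector(trace$state_counts))
  ev <- data.frame(kind = "event",
                   cycle = rep(seq_len(trace$horizon), times = ncol(trace$events)),
                   name = rep(colnames(trace$events), each = trace$horizon),
                   count = as.vector(trace$events))
  utils::write.csv(rbind(occ, ev), path, row.names = FALSE)
  invisible(path)
}
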