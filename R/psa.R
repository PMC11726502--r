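#' Draw one parameter set for probabilistic sensitivity analysis
#'
#' Replaces every non-fixed parameter by one draw from its moment-matched
#' distribution (gamma for costs and revenue, beta for probabilities and
#' utilities, normal for the tax weight effect). After drawing, each origin
#' state's outgoing transition probabilities are renormalised proportionally
#' if their sum exceeds 1, so the stay probability stays non-negative. Uses
#' the current RNG state; seed with [set.seed()] for reproducibility.
#'
#' @param base The base `ssb_parameters` set.
#' @return A new `ssb_parameters` set with drawn point values.
#' @export
draw_parameter_set <- function(base) {
  drawn <- base
  draw_df <- function(df) {
    df$mean <- vapply(seq_len(nrow(df)), function(i) {
      dist_draw(fit_distribution(as.list(df[i, ])), 1)
    }, numeric(1))
    df
  }
  drawn$transitions <- draw_df(base$transitions)
  # renormalise any origin whose drawn outgoing mass exceeds 1
  for (org in unique(drawn$transitions$origin)) {
    idx <- drawn$transitions$origin == org
    s <- sum(drawn$transitions$mean[idx])
    if (s > 1) drawn$transitions$mean[idx] <- drawn$transitions$mean[idx] / s
  }
  drawn$costs <- draw_df(base$costs)
  drawn$utilities <- draw_df(base$utilities)
  drawn$weight_effect$mean <-
    dist_draw(fit_distribution(as.list(base$weight_effect)), 1)
  drawn$revenue$mean <- dist_draw(fit_distribution(as.list(base$revenue)), 1)
  drawn$admin$mean <- dist_draw(fit_distribution(as.list(base$admin)), 1)
  drawn
}

#' Run the probabilistic sensitivity analysis
#'
#' For each iteration: draw a parameter set, simulate both arms with common
#' random numbers on the same baseline cohort, accrue discounted costs and
#' QALYs, and record the population-scale increments from both perspectives.
#' The baseline cohort is regenerated from the same seed every iteration, so
#' only parameter uncertainty (not population sampling) is propagated.
#'
#' The default desk-scale profile (200 iterations of 2,000 individuals)
#' keeps runtime modest; the published analysis corresponds to
#' `n_iterations = 1000, n_individuals = 20000`.
#'
#' @param params Base `ssb_parameters`.
#' @param config An `ssb_config`; `rescale_factor * n_individuals` defines
#'   the target population, held fixed when `n_individuals` is scaled down.
#' @param spec An `ssb_popspec` (calibrated); its `n` is overridden.
#' @param n_iterations Number of PSA iterations.
#' @param n_individuals Cohort size per iteration.
#' @param seed Master seed; all iteration streams derive from it.
#' @return An object of class `ssb_psa`: `iterations` data.frame
#'   (`iteration`, `delta_cost_hc`, `delta_cost_gov`, `delta_qaly`,
#'   `weight_effect`), plus `summaries` (mean and 2.5/97.5 percentiles).
#' @export
run_psa <- function(params, config, spec,
                    n_iterations = 200, n_individuals = 2000, seed = 1L) {
  stopifnot(n_iterations >= 1, n_individuals >= 1)
  population <- config$rescale_factor * config$n_individuals
  cfg <- config
  cfg$n_individuals <- as.integer(n_individuals)
  cfg$rescale_factor <- population / n_individuals
  sp <- spec
  sp$n <- as.integer(n_individuals)

  cohort_seed <- (as.integer(seed) + 777L) %% 2147483647L
  cohort <- generate_cohort(sp, seed = cohort_seed)

  it <- data.frame(iteration = seq_len(n_iterations),
                   delta_cost_hc = NA_real_, delta_cost_gov = NA_real_,
                   delta_qaly = NA_real_, weight_effect = NA_real_)
  for (i in seq_len(n_iterations)) {
    draw_seed <- (as.integer(seed) + 104729L * i) %% 2147483647L
    sim_seed <- (as.integer(seed) + 15485863L + 104729L * i) %% 2147483647L
    set.seed(draw_seed)
    p_i <- draw_parameter_set(params)
    traces <- simulate_arms(cohort, p_i, cfg, seed = sim_seed)
    res <- cea(traces, p_i, cfg, rescaled = TRUE)
    it$delta_cost_hc[i] <- res$delta_cost_healthcare
    it$delta_cost_gov[i] <- res$delta_cost_government
    it$delta_qaly[i] <- res$delta_qaly
    it$weight_effect[i] <- p_i$weight_effect$mean
  }

  q <- function(x) c(mean = mean(x), lo = unname(stats::quantile(x, 0.025)),
                     hi = unname(stats::quantile(x, 0.975)))
  icer_hc <- ifelse(it$delta_qaly == 0, NaN, it$delta_cost_hc / it$delta_qaly)
  structure(list(
    iterations = it,
    n_iterations = n_iterations,
    n_individuals = n_individuals,
    wtp = config$wtp,
    summaries = list(delta_cost_hc = q(it$delta_cost_hc),
                     delta_cost_gov = q(it$delta_cost_gov),
                     delta_qaly = q(it$delta_qaly),
                     icer_hc = q(icer_hc))
  ), class = "ssb_psa")
}

#' @export
print.ssb_psa <- function(x, ...) {
  cat(sprintf("PSA: %d iterations x %d individuals\n",
              x$n_iterations, x$n_individuals))
  s <- x$summaries
  cat(sprintf("  delta QALY        %.3g (95%% CI %.3g, %.3g)\n",
              s$delta_qaly[1], s$delta_qaly[2], s$delta_qaly[3]))
  cat(sprintf("  delta cost (HC)   %.4g (95%% CI %.4g, %.4g)\n",
              s$delta_cost_hc[1], s$delta_cost_hc[2], s$delta_cost_hc[3]))
  cat(sprintf("  delta cost (gov)  %.4g (95%% CI %.4g, %.4g)\n",
              s$delta_cost_gov[1], s$delta_cost_gov[2], s$delta_cost_gov[3]))
  cat(sprintf("  P(cost-effective at $%s/QALY, HC) = %.2f\n",
              format(x$wtp, big.mark = ","),
              ceac(x, x$wtp, "healthcare")$probability))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA iterations with
#' positive net monetary benefit, `wtp * delta_qaly - delta_cost > 0`.
#' At `wtp = 0` this is the probability the tax is cost-saving.
#'
#' @param psa An `ssb_psa` from [run_psa()].
#' @param wtp_grid Willingness-to-pay values (USD/QALY).
#' @param perspective `"healthcare"` or `"government"`.
#' @return Data.frame `wtp, probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 2e5, by = 1e4),
                 perspective = c("healthcare", "government")) {
  perspective <- match.arg(perspective)
  it <- psa$iterations
  if (nrow(it) == 0) stop("PSA result has no iterations")
  dc <- if (perspective == "healthcare") it$delta_cost_hc else it$delta_cost_gov
  prob <- vapply(wtp_grid, function(l) mean(l * it$delta_qaly - dc > 0),
                 numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Export PSA draws and CEAC as CSV
#'
#' @param psa An `ssb_psa`.
#' @param path File path.
#' @param wtp_grid Willingness-to-pay grid for the CEAC file.
#' @param perspective Perspective for the CEAC file.
#' @return `path`, invisibly.
#' @export
write_psa_csv <- function(psa, path) {
  utils::write.csv(psa$iterations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psa_csv
#' @export
write_ceac_csv <- function(psa, path, wtp_grid = seq(0, 2e5, by = 1e4),
                           perspective = "healthcare") {
  utils::write.csv(ceac(psa, wtp_grid, perspective), path, row.names = FALSE)
  invisible(path)
}
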