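#' Health states of the state-transition model
#'
#' The model distinguishes three weight-governed states (normal, overweight,
#' obesity), five disease states (diabetes, stroke, myocardial infarction,
#' end-stage renal disease, with one-cycle tunnel states `stroke`/`mi` feeding
#' chronic `poststroke`/`postmi`), and absorbing death.
#'
#' @return Character vector of the ten state names, in model order.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("normal", "overweight", "obesity", "diabetes", "stroke",
    "poststroke", "mi", "postmi", "esrd", "death")
}

# integer codes used throughout the engine
.STATES <- c("normal", "overweight", "obesity", "diabetes", "stroke",
             "poststroke", "mi", "postmi", "esrd", "death")
.S <- as.list(stats::setNames(seq_along(.STATES), .STATES))

#' Plus/minus 25 percent uncertainty bounds
#'
#' Parameters published without an interval carry a conventional uncertainty
#' band of 25% either side of the point value.
#'
#' @param mean Numeric vector of point values.
#' @return A list with components `low` (0.75 mean) and `high` (1.25 mean).
#' @export
#' @examples
#' pm25_bounds(8627229)
pm25_bounds <- function(mean) {
  stopifnot(is.numeric(mean), all(is.finite(mean)))
  list(low = 0.75 * mean, high = 1.25 * mean)
}

#' Convert a multi-year risk to an annual probability
#'
#' Uses the constant-rate convention: if the cumulative risk over `years`
#' years is `risk`, the implied annual probability is
#' `1 - (1 - risk)^(1/years)`.
#'
#' @param risk Cumulative risk over the period, in `[0, 1)`.
#' @param years Length of the period in years (>= 1).
#' @return Annual probability in `[0, risk]`.
#' @export
#' @examples
#' multi_year_risk_to_annual(0.2, 10)
multi_year_risk_to_annual <- function(risk, years) {
  stopifnot(is.numeric(risk), is.numeric(years), years >= 1)
  if (any(risk < 0 | risk > 1)) stop("risk must lie in [0, 1]")
  if (any(risk == 1 & years > 1)) {
    stop("risk of 1 over more than one year has no finite annual rate")
  }
  1 - (1 - risk)^(1 / years)
}

#' Convert a ratio measure to a probability
#'
#' Translates a relative effect on a reference probability into the implied
#' probability in the exposed group, using the standard conversion for each
#' ratio type: risk ratios scale the probability directly (capped at 1);
#' hazard ratios and incidence-rate ratios act on the log-survival scale,
#' `1 - (1 - p)^ratio`; odds ratios act on the odds scale.
#'
#' @param p_ref Reference (unexposed) probability in `[0, 1)`.
#' @param ratio Positive ratio measure.
#' @param kind One of `"rr"`, `"hr"`, `"irr"`, `"or"`.
#' @return Probability in `[0, 1]`; equals `p_ref` when `ratio = 1`.
#' @export
#' @examples
#' ratio_to_probability(0.1, 2, "or")
#' ratio_to_probability(0.1, 2, "hr")
ratio_to_probability <- function(p_ref, ratio, kind = c("rr", "hr", "irr", "or")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(p_ref), is.numeric(ratio))
  if (any(p_ref < 0 | p_ref >= 1)) stop("p_ref must lie in [0, 1)")
  if (any(ratio <= 0)) stop("ratio must be positive")
  switch(kind,
    rr  = pmin(1, ratio * p_ref),
    hr  = 1 - (1 - p_ref)^ratio,
    irr = 1 - (1 - p_ref)^ratio,
    or  = ratio * p_ref / (1 - p_ref + ratio * p_ref)
  )
}

#' Fit a sampling distribution to a point value and interval
#'
#' Moment-matches the distribution family mandated for each parameter class
#' (gamma for costs, beta for probabilities and utilities, log-normal for
#' ratio measures, normal for sign-indefinite effects) to the point value and
#' its uncertainty interval. The interval half-width is read as 1.96 standard
#' errors, i.e. `sd = (high - low) / 3.92`, for printed 95% intervals and
#' plus/minus-25% bands alike.
#'
#' Degenerate inputs (zero-width intervals, `uncertainty = "fixed"`) yield a
#' point mass. A gamma or log-normal fit to a nonpositive mean, or a beta fit
#' to a mean on the boundary of `[0, 1]`, is infeasible and falls back to a
#' point mass (with a warning for the nonpositive-mean case). A beta sd
#' exceeding the feasible bound `sqrt(m(1-m))` is clipped.
#'
#' @param pv A parameter value: list with `mean`, `low`, `high`,
#'   `uncertainty` (`"ci95"`, `"pm25"` or `"fixed"`), `family`
#'   (`"gamma"`, `"beta"`, `"lognormal"`, `"normal"` or `"fixed"`).
#' @return An object of class `ssb_dist`: list with `family`, `mean`, `sd`
#'   and the family's natural parameters.
#' @export
#' @examples
#' fit_distribution(list(mean = 21218, low = 15913, high = 26522,
#'                       uncertainty = "pm25", family = "gamma"))
fit_distribution <- function(pv) {
  m <- pv$mean
  fam <- if (is.null(pv$family)) "fixed" else pv$family
  unc <- if (is.null(pv$uncertainty)) "fixed" else pv$uncertainty
  s <- if (unc == "fixed" || is.null(pv$low) || is.null(pv$high)) 0
       else (pv$high - pv$low) / 3.92
  out <- list(family = "fixed", mean = m, sd = 0)
  if (s <= 0 || fam == "fixed") {
    class(out) <- "ssb_dist"
    return(out)
  }
  if (fam %in% c("gamma", "lognormal") && m <= 0) {
    warning(sprintf("%s fit requires a positive mean; using a point mass at %g",
                    fam, m))
    class(out) <- "ssb_dist"
    return(out)
  }
  if (fam == "beta" && (m <= 0 || m >= 1)) {
    # boundary mean (e.g. a utility of exactly 1): beta is infeasible
    class(out) <- "ssb_dist"
    return(out)
  }
  out <- switch(fam,
    gamma = list(family = "gamma", mean = m, sd = s,
                 shape = m^2 / s^2, scale = s^2 / m),
    beta = {
      s2max <- m * (1 - m)
      s2 <- min(s^2, 0.99 * s2max)
      nu <- m * (1 - m) / s2 - 1
      list(family = "beta", mean = m, sd = sqrt(s2),
           alpha = m * nu, beta = (1 - m) * nu)
    },
    lognormal = {
      sigma2 <- log(1 + s^2 / m^2)
      list(family = "lognormal", mean = m, sd = s,
           meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
    },
    normal = list(family = "normal", mean = m, sd = s),
    stop("unknown distribution family: ", fam)
  )
  class(out) <- "ssb_dist"
  out
}

#' Analytic mean of a fitted distribution
#' @param d An `ssb_dist` object.
#' @return The distribution's mean.
#' @export
dist_mean <- function(d) {
  switch(d$family,
    fixed = d$mean,
    gamma = d$shape * d$scale,
    beta = d$alpha / (d$alpha + d$beta),
    lognormal = exp(d$meanlog + d$sdlog^2 / 2),
    normal = d$mean
  )
}

#' Draw from a fitted distribution
#'
#' Uses the current RNG state, so draws are reproducible under
#' [set.seed()].
#'
#' @param d An `ssb_dist` object from [fit_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
dist_draw <- function(d, n = 1) {
  switch(d$family,
    fixed = rep(d$mean, n),
    gamma = stats::rgamma(n, shape = d$shape, scale = d$scale),
    beta = stats::rbeta(n, d$alpha, d$beta),
    lognormal = stats::rlnorm(n, d$meanlog, d$sdlog),
    normal = stats::rnorm(n, d$mean, d$sd)
  )
}

# ---- parameter-set ingestion -------------------------------------------

.req_transitions <- data.frame(
  origin = c(rep("normal", 5), rep("overweight", 5), rep("obesity", 5),
             rep("diabetes", 4), rep("stroke", 2), rep("mi", 2),
             rep("esrd", 3), rep("poststroke", 2), rep("postmi", 2)),
  destination = c("diabetes", "stroke", "mi", "esrd", "death",
                  "diabetes", "stroke", "mi", "esrd", "death",
                  "diabetes", "stroke", "mi", "esrd", "death",
                  "stroke", "mi", "esrd", "death",
                  "mi", "death",
                  "stroke", "death",
                  "stroke", "mi", "death",
                  "mi", "death",
                  "stroke", "death"),
  stringsAsFactors = FALSE
)
.req_cost_states <- c("normal", "overweight", "obesity", "diabetes", "stroke",
                      "poststroke", "mi", "postmi", "esrd")
.req_utility_states <- c("normal", "overweight", "obesity", "diabetes",
                         "stroke", "mi", "esrd", "death")

.pv_row <- function(x, name, kind = c("probability", "utility", "cost", "other")) {
  kind <- match.arg(kind)
  if (is.null(x$mean)) stop("parameter '", name, "' has no mean value")
  unc <- if (is.null(x$uncertainty)) "fixed" else x$uncertainty
  if (!unc %in% c("ci95", "pm25", "fixed")) {
    stop("parameter '", name, "': unknown uncertainty kind '", unc, "'")
  }
  low <- x$low; high <- x$high
  if (unc == "pm25" && (is.null(low) || is.null(high))) {
    b <- pm25_bounds(x$mean); low <- b$low; high <- b$high
  }
  if (unc == "fixed") { low <- x$mean; high <- x$mean }
  if (is.null(low) || is.null(high)) {
    stop("parameter '", name, "' has uncertainty '", unc,
         "' but no low/high bounds")
  }
  if (isTRUE(low == high) && unc != "fixed") unc <- "fixed"
  if (low > x$mean || x$mean > high) {
    stop("parameter '", name, "': bounds do not bracket the mean")
  }
  if (kind %in% c("probability", "utility") && (x$mean < 0 || x$mean > 1)) {
    stop("parameter '", name, "': value ", x$mean, " outside [0, 1]")
  }
  if (kind == "cost" && x$mean < 0) {
    stop("parameter '", name, "': negative cost")
  }
  fam <- if (is.null(x$family)) "fixed" else x$family
  data.frame(mean = x$mean, low = low, high = high,
             uncertainty = unc, family = fam, stringsAsFactors = FALSE)
}

#' Load model parameters and run configuration
#'
#' Reads the structured YAML input file shipped with the package (or a
#' user-supplied one of the same shape) and returns the validated parameter
#' set together with the run configuration. The default file encodes the
#' published model inputs: 30 annual transition probabilities, per-state
#' annual costs and EQ-5D utilities, the tax-revenue and administration-cost
#' parameters, and the weight-change parameters.
#'
#' @param path Path to a YAML input file; defaults to the packaged inputs.
#' @return A list with components `params` (class `ssb_parameters`) and
#'   `config` (class `ssb_config`).
#' @export
#' @examples
#' inp <- load_parameters()
#' nrow(inp$params$transitions)
load_parameters <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "soda_tax_inputs.yaml", package = "ssbcea")
  }
  raw <- yaml::read_yaml(path)
  for (sec in c("config", "weight", "revenue", "costs", "utilities", "transitions")) {
    if (is.null(raw[[sec]])) stop("input file is missing section '", sec, "'")
  }

  tr <- do.call(rbind, lapply(raw$transitions, function(e) {
    name <- paste0(e$origin, "->", e$destination)
    if (is.null(e$origin) || is.null(e$destination)) {
      stop("transition entry without origin/destination")
    }
    if (!e$origin %in% .STATES || !e$destination %in% .STATES) {
      stop("transition '", name, "' uses an unknown state")
    }
    cbind(data.frame(origin = e$origin, destination = e$destination,
                     stringsAsFactors = FALSE),
          .pv_row(e, name, "probability"))
  }))
  key <- function(d) paste0(d$origin, "->", d$destination)
  missing_tr <- setdiff(key(.req_transitions), key(tr))
  if (length(missing_tr)) {
    stop("missing transition parameter(s): ", paste(missing_tr, collapse = ", "))
  }

  costs <- do.call(rbind, lapply(.req_cost_states, function(s) {
    e <- raw$costs[[s]]
    if (is.null(e)) stop("missing cost parameter: ", s)
    cbind(data.frame(state = s, stringsAsFactors = FALSE),
          .pv_row(e, paste0("cost:", s), "cost"))
  }))
  utilities <- do.call(rbind, lapply(.req_utility_states, function(s) {
    e <- raw$utilities[[s]]
    if (is.null(e)) stop("missing utility parameter: ", s)
    cbind(data.frame(state = s, stringsAsFactors = FALSE),
          .pv_row(e, paste0("utility:", s), "utility"))
  }))

  w <- raw$weight
  if (is.null(w$natural_gain_kg_per_year)) stop("missing natural weight-gain range")
  gain <- c(w$natural_gain_kg_per_year$low, w$natural_gain_kg_per_year$high)
  if (length(gain) != 2 || gain[1] > gain[2]) {
    stop("natural weight-gain range must be a valid [low, high] interval")
  }
  if (is.null(w$tax_weight_effect_kg_per_year)) stop("missing tax weight effect")
  weff <- .pv_row(w$tax_weight_effect_kg_per_year, "tax_weight_effect", "other")

  rev <- .pv_row(raw$revenue$annual_tax_revenue_usd, "annual_tax_revenue", "cost")
  adm <- .pv_row(raw$revenue$admin_cost_usd_per_year, "admin_cost", "cost")

  params <- structure(list(
    transitions = tr,
    costs = costs,
    utilities = utilities,
    natural_gain_range = gain,
    weight_effect = weff,
    revenue = rev,
    admin = adm
  ), class = "ssb_parameters")

  # defaults not present in the file fall back to model_config()'s own
  cfg <- do.call(model_config, raw$config)

  rs <- row_sums(params)
  bad <- names(rs)[rs > 1]
  if (length(bad)) {
    stop("outgoing transition probabilities exceed 1 for state(s): ",
         paste(bad, collapse = ", "))
  }
  list(params = params, config = cfg)
}

#' Run configuration for the microsimulation
#'
#' Collects all scalar run settings: cohort size, horizon, discounting,
#' population rescale factor, willingness-to-pay threshold and the physical
#' constants of the calorie-to-weight chain.
#'
#' @param n_individuals Simulated cohort size (the published analysis uses
#'   20,000).
#' @param horizon_years Number of annual cycles (20).
#' @param discount_rate Annual discount rate for costs and QALYs (0.03).
#' @param rescale_factor Multiplier from model counts to the California adult
#'   population: 29,247,121 / 20,000 = 1,462.36.
#' @param wtp Willingness-to-pay threshold in USD per QALY (100,000).
#' @param calories_per_gram_sugar kcal per gram of sugar (4).
#' @param kcal_per_pound Energy deficit per pound of weight loss (3,500).
#' @param lb_per_kg Pounds per kilogram (2.20462).
#' @param days_per_year Days per year (365).
#' @param admin_cost_fraction Government administration cost as a fraction of
#'   annual tax revenue (0.01).
#' @param seed Default random seed.
#' @return An object of class `ssb_config` (a validated list).
#' @export
model_config <- function(n_individuals = 20000,
                         horizon_years = 20,
                         discount_rate = 0.03,
                         rescale_factor = 1462.36,
                         wtp = 1e5,
                         calories_per_gram_sugar = 4,
                         kcal_per_pound = 3500,
                         lb_per_kg = 2.20462,
                         days_per_year = 365,
                         admin_cost_fraction = 0.01,
                         seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              horizon_years = as.integer(horizon_years),
              cycle_length = 1,
              discount_rate = discount_rate,
              rescale_factor = rescale_factor,
              wtp = wtp,
              calories_per_gram_sugar = calories_per_gram_sugar,
              kcal_per_pound = kcal_per_pound,
              lb_per_kg = lb_per_kg,
              days_per_year = days_per_year,
              admin_cost_fraction = admin_cost_fraction,
              seed = as.integer(seed))
  stopifnot(cfg$n_individuals >= 1, cfg$horizon_years >= 0,
            cfg$discount_rate >= 0, cfg$rescale_factor > 0,
            cfg$admin_cost_fraction >= 0, cfg$admin_cost_fraction <= 1)
  class(cfg) <- "ssb_config"
  cfg
}

#' @export
print.ssb_parameters <- function(x, ...) {
  cat("Soda-tax model parameter set\n")
  cat(sprintf("  %d transition probabilities, %d state costs, %d utilities\n",
              nrow(x$transitions), nrow(x$costs), nrow(x$utilities)))
  cat(sprintf("  tax weight effect %.2f kg/y; natural gain [%.2f, %.2f] kg/y\n",
              x$weight_effect$mean, x$natural_gain_range[1],
              x$natural_gain_range[2]))
  cat(sprintf("  annual revenue $%s; admin cost $%s\n",
              format(x$revenue$mean, big.mark = ","),
              format(x$admin$mean, big.mark = ",")))
  invisible(x)
}

#' Per-origin sums of outgoing transition probabilities
#'
#' @param params An `ssb_parameters` object.
#' @return Named numeric vector over origin states; the residual `1 - sum`
#'   is the stay probability.
#' @export
row_sums <- function(params) {
  tapply(params$transitions$mean, params$transitions$origin, sum)
}

#' Transition table with stay probabilities resolved
#'
#' @param params An `ssb_parameters` object.
#' @return A data.frame `origin, destination, probability, low, high,
#'   uncertainty_kind` including the residual stay ("remain") rows.
#' @export
transition_table <- function(params) {
  tr <- params$transitions
  out <- data.frame(origin = tr$origin, destination = tr$destination,
                    probability = tr$mean, low = tr$low, high = tr$high,
                    uncertainty_kind = tr$uncertainty,
                    stringsAsFactors = FALSE)
  rs <- row_sums(params)
  stay <- data.frame(origin = names(rs), destination = "remain",
                     probability = as.numeric(1 - rs), low = NA_real_,
                     high = NA_real_, uncertainty_kind = "derived",
                     stringsAsFactors = FALSE)
  rbind(out, stay)
}

#' Dense annual transition matrix
#'
#' @param transitions A data.frame with columns `origin`, `destination` and a
#'   probability column (`mean` or `probability`).
#' @return A 10 x 10 matrix over [health_states()], off-diagonal entries the
#'   listed transition probabilities; diagonal left at zero (the engine
#'   treats residual mass as staying). Death has no outgoing mass.
#' @export
transition_matrix <- function(transitions) {
  p <- if ("probability" %in% names(transitions)) transitions$probability
       else transitions$mean
  keep <- transitions$destination %in% .STATES
  m <- matrix(0, 10, 10, dimnames = list(.STATES, .STATES))
  m[cbind(match(transitions$origin[keep], .STATES),
          match(transitions$destination[keep], .STATES))] <- p[keep]
  if (any(rowSums(m) > 1 + 1e-12)) stop("transition row sums exceed 1")
  m
}

#' Write / read a transition table as CSV
#'
#' @param params An `ssb_parameters` object (for writing).
#' @param path File path.
#' @return `write_transition_csv` returns `path` invisibly;
#'   `read_transition_csv` returns the table as a data.frame.
#' @export
write_transition_csv <- function(params, path) {
  utils::write.csv(transition_table(params), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transition_csv
#' @export
read_transition_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Per-state annual cost and utility schedules
#'
#' Expands the parameter set to named vectors over all ten states. The
#' chronic poststroke/post-MI states carry the stroke/MI utility; death costs
#' nothing and has utility zero.
#'
#' @param params An `ssb_parameters` object.
#' @return Named numeric vector over [health_states()].
#' @export
cost_schedule <- function(params) {
  v <- stats::setNames(rep(0, 10), .STATES)
  v[params$costs$state] <- params$costs$mean
  v["death"] <- 0
  v
}

#' @rdname cost_schedule
#' @export
utility_schedule <- function(params) {
  u <- params$utilities
  val <- stats::setNames(u$mean, u$state)
  v <- stats::setNames(rep(0, 10), .STATES)
  v[names(val)] <- val
  v["poststroke"] <- val[["stroke"]]
  v["postmi"] <- val[["mi"]]
  v["death"] <- 0
  v
}
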