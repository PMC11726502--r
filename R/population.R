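#' Classify BMI into weight categories
#'
#' BMI is weight / height^2 (kg/m^2). Categories: normal (< 25), overweight
#' (25 <= BMI < 30), obesity (BMI >= 30); both lower bounds are inclusive.
#'
#' @param weight Weight in kg.
#' @param height Height in m (> 0).
#' @return Character vector: `"normal"`, `"overweight"` or `"obesity"`.
#' @export
#' @examples
#' classify_bmi(70, 1.70)
#' classify_bmi(86.7, 1.70)
classify_bmi <- function(weight, height) {
  if (any(height <= 0)) stop("height must be positive")
  bmi <- weight / height^2
  ifelse(bmi >= 30, "obesity", ifelse(bmi >= 25, "overweight", "normal"))
}

.classify_bmi_int <- function(weight, height) {
  bmi <- weight / height^2
  1L + (bmi >= 25) + (bmi >= 30)
}

#' Population specification for the synthetic cohort
#'
#' Weight has a log-normal marginal and height a normal marginal, coupled by
#' a Gaussian copula. The defaults are a placeholder; use
#' [calibrate_population()] to solve the parameters against the survey
#' targets (mean weight 77.67 kg, SD 19.96 kg, obesity prevalence 28.2%).
#'
#' @param n Cohort size.
#' @param mean_log_weight,sd_log_weight Log-scale weight parameters (log-kg).
#' @param mean_height,sd_height Height moments (m).
#' @param corr Weight-height copula correlation, in (-1, 1).
#' @param targets Named list of calibration targets (`mean_weight`,
#'   `sd_weight`, `obesity_prev`); carried for validation reporting.
#' @return An object of class `ssb_popspec`.
#' @export
population_spec <- function(n = 20000,
                            mean_log_weight = log(77.67),
                            sd_log_weight = 0.25,
                            mean_height = 1.68,
                            sd_height = 0.10,
                            corr = 0.4,
                            targets = list(mean_weight = 77.67,
                                           sd_weight = 19.96,
                                           obesity_prev = 0.282)) {
  stopifnot(n >= 1, sd_log_weight > 0, sd_height > 0, abs(corr) < 1)
  structure(list(n = as.integer(n), mean_log_weight = mean_log_weight,
                 sd_log_weight = sd_log_weight, mean_height = mean_height,
                 sd_height = sd_height, corr = corr, targets = targets),
            class = "ssb_popspec")
}

#' @export
print.ssb_popspec <- function(x, ...) {
  cat(sprintf(
    "Synthetic population spec: n=%d, logW ~ N(%.4f, %.4f), H ~ N(%.3f, %.3f), corr=%.3f\n",
    x$n, x$mean_log_weight, x$sd_log_weight, x$mean_height, x$sd_height, x$corr))
  invisible(x)
}

# shared draw machinery: standard-normal pair with the copula correlation
.draw_wh <- function(spec, n, z1, z2) {
  rho <- spec$corr
  w <- exp(spec$mean_log_weight + spec$sd_log_weight * z1)
  h <- spec$mean_height + spec$sd_height * (rho * z1 + sqrt(1 - rho^2) * z2)
  h <- pmin(pmax(h, 1.2), 2.2)
  list(weight = w, height = h)
}

#' Generate a synthetic baseline cohort
#'
#' Draws `spec$n` adults with log-normal weight and normal height coupled by
#' a Gaussian copula, and assigns each a baseline weight category from BMI.
#' All individuals start free of diabetes, cardiovascular disease and ESRD;
#' disease states are entered only through simulated transitions.
#'
#' @param spec An `ssb_popspec`, typically from [calibrate_population()].
#' @param seed Integer seed; the same spec and seed reproduce the cohort.
#' @return A data.frame (class `ssb_cohort`) with columns `id`, `weight`
#'   (kg), `height` (m), `state`.
#' @export
#' @examples
#' coh <- generate_cohort(population_spec(n = 100), seed = 1)
#' table(coh$state)
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "ssb_popspec"))
  set.seed(as.integer(seed))
  n <- spec$n
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  wh <- .draw_wh(spec, n, z1, z2)
  out <- data.frame(id = seq_len(n), weight = wh$weight, height = wh$height,
                    state = classify_bmi(wh$weight, wh$height),
                    stringsAsFactors = FALSE)
  class(out) <- c("ssb_cohort", "data.frame")
  out
}

#' Calibrate the population spec to survey targets
#'
#' The log-normal weight parameters are solved analytically so the implied
#' weight mean and SD equal the targets exactly:
#' `sd_log = sqrt(log(1 + (sd/mean)^2))`, `mean_log = log(mean) - sd_log^2/2`.
#' The copula correlation is then adjusted by a one-dimensional root search
#' (with a fixed internal set of standard-normal draws, so the objective is
#' deterministic and monotone) until the simulated obesity prevalence at
#' `n_check` draws matches the target within `tol`.
#'
#' @param targets List with `mean_weight` (kg), `sd_weight` (kg),
#'   `obesity_prev` (proportion in (0, 1)).
#' @param mean_height,sd_height Fixed height moments (m).
#' @param n Cohort size stored in the returned spec.
#' @param n_check Number of draws used in the calibration check.
#' @param tol Tolerance on obesity prevalence (absolute, default 0.005).
#' @return A calibrated `ssb_popspec`.
#' @export
#' @examples
#' spec <- calibrate_population()
#' spec$corr
calibrate_population <- function(targets = list(mean_weight = 77.67,
                                                sd_weight = 19.96,
                                                obesity_prev = 0.282),
                                 mean_height = 1.68, sd_height = 0.10,
                                 n = 20000, n_check = 1e5, tol = 0.005) {
  if (is.null(targets$obesity_prev) ||
      targets$obesity_prev <= 0 || targets$obesity_prev >= 1) {
    stop("obesity prevalence target must lie strictly inside (0, 1)")
  }
  cv <- targets$sd_weight / targets$mean_weight
  sd_log <- sqrt(log(1 + cv^2))
  mean_log <- log(targets$mean_weight) - sd_log^2 / 2

  # fixed normal draws -> prevalence is a smooth deterministic function of rho
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(20150101)
  z1 <- stats::rnorm(n_check)
  z2 <- stats::rnorm(n_check)

  prev_at <- function(rho) {
    sp <- population_spec(n = n, mean_log_weight = mean_log,
                          sd_log_weight = sd_log, mean_height = mean_height,
                          sd_height = sd_height, corr = rho, targets = targets)
    wh <- .draw_wh(sp, n_check, z1, z2)
    mean(wh$weight / wh$height^2 >= 30)
  }
  f <- function(rho) prev_at(rho) - targets$obesity_prev
  lo <- -0.95; hi <- 0.95
  if (f(lo) * f(hi) > 0) {
    stop(sprintf(
      "calibration cannot bracket the obesity target %.3f: prevalence ranges [%.4f, %.4f] over corr in [%.2f, %.2f]",
      targets$obesity_prev, prev_at(hi), prev_at(lo), lo, hi))
  }
  # prevalence decreases in rho here (higher corr shrinks BMI dispersion)
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-4)
  spec <- population_spec(n = n, mean_log_weight = mean_log,
                          sd_log_weight = sd_log, mean_height = mean_height,
                          sd_height = sd_height, corr = root$root,
                          targets = targets)
  achieved <- prev_at(root$root)
  if (abs(achieved - targets$obesity_prev) > tol) {
    stop(sprintf("calibration converged to prevalence %.4f, outside +/-%.3f of target %.3f",
                 achieved, tol, targets$obesity_prev))
  }
  spec
}

# save/restore global RNG state so calibration does not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write / read a cohort as CSV
#'
#' @param cohort An `ssb_cohort` data.frame.
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the cohort.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- data.frame(id = cohort$id, weight_kg = cohort$weight,
                    height_m = cohort$height, state = cohort$state)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(id = d$id, weight = d$weight_kg, height = d$height_m,
                    state = d$state, stringsAsFactors = FALSE)
  class(out) <- c("ssb_cohort", "data.frame")
  out
}
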