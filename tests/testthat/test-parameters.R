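test_that("plus/minus 25% bounds reproduce the printed intervals and are linear", {
  b <- pm25_bounds(8627229)
  expect_equal(round(b$low), 6470422)
  expect_equal(round(b$high), 10784036)
  b2 <- pm25_bounds(0.0090)
  expect_equal(b2$low, 0.00675)
  expect_equal(b2$high, 0.01125)
  expect_equal(pm25_bounds(0), list(low = 0, high = 0))
  # exact linearity in the point value
  for (c_ in c(0.5, 2, 137.5)) {
    expect_equal(pm25_bounds(c_ * 3.7)$low, c_ * pm25_bounds(3.7)$low)
    expect_equal(pm25_bounds(c_ * 3.7)$high, c_ * pm25_bounds(3.7)$high)
  }
})

test_that("multi-year risks convert to annual probabilities under the constant-rate rule", {
  expect_equal(multi_year_risk_to_annual(0, 7), 0)
  expect_equal(multi_year_risk_to_annual(0.2, 1), 0.2)
  p1 <- multi_year_risk_to_annual(0.2, 10)
  expect_equal(p1, 0.02206723, tolerance = 1e-6)
  # oracle: ten independent annual trials at p1 must recover the 10-y risk
  expect_equal(1 - (1 - p1)^10, 0.2, tolerance = 1e-12)
  expect_true(p1 <= 0.2)
  expect_error(multi_year_risk_to_annual(1, 10), "no finite annual rate")
})

test_that("ratio measures convert to probabilities consistently with their defining scales", {
  # null ratio is the identity for every kind
  for (k in c("rr", "hr", "irr", "or")) {
    expect_equal(ratio_to_probability(0.1, 1, k), 0.1)
  }
  # odds-ratio oracle: solve the 2x2 odds definition directly
  p_or <- ratio_to_probability(0.1, 2, "or")
  odds <- function(p) p / (1 - p)
  oracle <- uniroot(function(p) odds(p) / odds(0.1) - 2, c(1e-9, 1 - 1e-9),
                    tol = 1e-15)$root
  expect_equal(p_or, oracle, tolerance = 1e-12)
  expect_equal(p_or, 2 / 11, tolerance = 1e-12)
  # hazard-ratio oracle: survival curve raised to the hazard ratio
  expect_equal(ratio_to_probability(0.1, 2, "hr"), 1 - 0.9^2, tolerance = 1e-12)
  expect_equal(ratio_to_probability(0.1, 2, "irr"), 1 - 0.9^2, tolerance = 1e-12)
  expect_equal(ratio_to_probability(0.3, 2, "rr"), 0.6)
  expect_equal(ratio_to_probability(0.6, 2, "rr"), 1)  # capped
})

test_that("ratio conversions are monotone in the ratio and agree for rare outcomes", {
  ratios <- c(0.25, 0.5, 1, 1.5, 2, 4)
  for (k in c("rr", "hr", "or")) {
    p <- ratio_to_probability(0.05, ratios, k)
    expect_true(all(diff(p) > 0), info = k)
  }
  # rare-disease limit: all conversions within 5% relative of each other
  for (p_ref in c(0.001, 0.01)) {
    vals <- vapply(c("rr", "hr", "or"), function(k)
      ratio_to_probability(p_ref, 1.8, k), numeric(1))
    expect_lt(diff(range(vals)) / mean(vals), 0.05)
  }
})

test_that("distribution fits match the stated moments analytically", {
  g <- fit_distribution(list(mean = 21218, low = 15913, high = 26522,
                             uncertainty = "pm25", family = "gamma"))
  expect_equal(g$family, "gamma")
  expect_equal(g$sd, (26522 - 15913) / 3.92, tolerance = 1e-12)
  expect_equal(g$sd, 2706.4, tolerance = 1e-4)
  expect_equal(dist_mean(g), 21218, tolerance = 1e-9)

  b <- fit_distribution(list(mean = 0.785, low = 0.681, high = 0.889,
                             uncertainty = "ci95", family = "beta"))
  expect_equal(b$family, "beta")
  expect_equal(dist_mean(b), 0.785, tolerance = 1e-9)
  expect_equal(sqrt(b$alpha * b$beta / ((b$alpha + b$beta)^2 *
                                        (b$alpha + b$beta + 1))),
               (0.889 - 0.681) / 3.92, tolerance = 1e-9)

  ln <- fit_distribution(list(mean = 1.5, low = 1.0, high = 2.0,
                              uncertainty = "ci95", family = "lognormal"))
  expect_equal(dist_mean(ln), 1.5, tolerance = 1e-9)
  s <- 1 / 3.92
  expect_equal(sqrt((exp(ln$sdlog^2) - 1) * exp(2 * ln$meanlog + ln$sdlog^2)),
               s, tolerance = 1e-9)

  # degenerate interval -> point mass
  d <- fit_distribution(list(mean = 0.0087, low = 0.0087, high = 0.0087,
                             uncertainty = "ci95", family = "beta"))
  expect_equal(d$family, "fixed")
  expect_equal(dist_draw(d, 3), rep(0.0087, 3))
  # boundary beta mean (utility of 1) is infeasible -> point mass
  u1 <- fit_distribution(list(mean = 1, low = 0.75, high = 1,
                              uncertainty = "pm25", family = "beta"))
  expect_equal(u1$family, "fixed")
  expect_warning(
    fit_distribution(list(mean = 0, low = -1, high = 1,
                          uncertainty = "ci95", family = "gamma")),
    "positive mean")
})

test_that("Monte-Carlo sampling recovers the fitted means within 3 standard errors", {
  set.seed(42)
  cases <- list(
    list(mean = 21218, low = 15913, high = 26522, uncertainty = "pm25",
         family = "gamma"),
    list(mean = 0.785, low = 0.681, high = 0.889, uncertainty = "ci95",
         family = "beta"),
    list(mean = 1.5, low = 1.0, high = 2.0, uncertainty = "ci95",
         family = "lognormal"),
    list(mean = -0.56, low = -1.93, high = 0.77, uncertainty = "ci95",
         family = "normal")
  )
  n <- 1e5
  for (pv in cases) {
    d <- fit_distribution(pv)
    x <- dist_draw(d, n)
    expect_lt(abs(mean(x) - pv$mean), 3 * d$sd / sqrt(n))
  }
})

test_that("the shipped inputs load with the full published parameter complement", {
  inp <- default_inputs()
  expect_s3_class(inp$params, "ssb_parameters")
  expect_equal(nrow(inp$params$transitions), 30)
  expect_equal(nrow(inp$params$costs), 9)
  expect_equal(nrow(inp$params$utilities), 8)
  expect_equal(inp$params$natural_gain_range, c(0.45, 0.91))
  expect_equal(inp$params$weight_effect$mean, -0.56)
  expect_equal(inp$params$revenue$mean, 862722888)
  expect_equal(inp$config$horizon_years, 20)
  expect_equal(inp$config$discount_rate, 0.03)
  # every origin leaves positive stay probability
  expect_true(all(row_sums(inp$params) < 1))
  # degenerate overweight->death interval is treated as fixed
  tr <- inp$params$transitions
  owd <- tr[tr$origin == "overweight" & tr$destination == "death", ]
  expect_equal(owd$uncertainty, "fixed")
})

test_that("invalid or incomplete inputs are rejected with named errors", {
  bad_prob <- modified_inputs_file(function(raw) {
    raw$transitions[[1]]$mean <- 1.5
    raw$transitions[[1]]$low <- 1.4
    raw$transitions[[1]]$high <- 1.6
    raw
  })
  expect_error(load_parameters(bad_prob), "outside \\[0, 1\\]")

  missing_tr <- modified_inputs_file(function(raw) {
    keep <- !vapply(raw$transitions, function(e)
      e$origin == "obesity" && e$destination == "diabetes", logical(1))
    raw$transitions <- raw$transitions[keep]
    raw
  })
  expect_error(load_parameters(missing_tr), "obesity->diabetes")

  missing_cost <- modified_inputs_file(function(raw) {
    raw$costs$diabetes <- NULL
    raw
  })
  expect_error(load_parameters(missing_cost), "missing cost parameter: diabetes")
})

test_that("transition tables round-trip through CSV with residual stay rows", {
  inp <- default_inputs()
  tab <- transition_table(inp$params)
  expect_equal(nrow(tab), 30 + 9)  # 9 origins get a stay row
  stay <- tab[tab$destination == "remain", ]
  expect_true(all(stay$probability > 0))
  rs <- tapply(tab$probability, tab$origin, sum)
  expect_equal(as.vector(rs), rep(1, 9), tolerance = 1e-12)

  path <- tempfile(fileext = ".csv")
  write_transition_csv(inp$params, path)
  back <- read_transition_csv(path)
  expect_equal(back$probability, tab$probability)
  expect_equal(back$origin, tab$origin)

  m <- transition_matrix(inp$params$transitions)
  expect_equal(dim(m), c(10, 10))
  expect_equal(sum(m["death", ]), 0)  # absorbing
  expect_equal(m["normal", "diabetes"], 0.0069)
})
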