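# shared fixtures, memoised so expensive objects are built once per run
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

default_inputs <- function() cached("inputs", load_parameters())

calibrated_spec <- function(n = 20000) {
  cached(paste0("spec", n), calibrate_population(n = n))
}

# a cohort built directly, bypassing the generator
make_cohort <- function(weight, height, state = classify_bmi(weight, height)) {
  out <- data.frame(id = seq_along(weight), weight = weight, height = height,
                    state = state, stringsAsFactors = FALSE)
  class(out) <- c("ssb_cohort", "data.frame")
  out
}

# transitions data.frame with every probability zero except those given as
# "origin->destination" = p
sparse_transitions <- function(...) {
  entries <- list(...)
  if (length(entries) == 0) {
    return(data.frame(origin = character(), destination = character(),
                      mean = numeric(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(names(entries), "->", fixed = TRUE)
  data.frame(origin = vapply(parts, `[`, "", 1),
             destination = vapply(parts, `[`, "", 2),
             mean = unlist(entries), stringsAsFactors = FALSE)
}

# a minimal trace for accrual tests: state occupancy given as a named list
# of per-cycle counts
make_trace <- function(horizon, counts) {
  sc <- matrix(0L, nrow = horizon, ncol = 10,
               dimnames = list(NULL, health_states()))
  for (s in names(counts)) sc[, s] <- counts[[s]]
  structure(list(arm = "test", n = sum(unlist(counts)), horizon = horizon,
                 weight_effect = 0, state_counts = sc,
                 events = matrix(0L, horizon, 5,
                                 dimnames = list(NULL, c("diabetes", "stroke",
                                                         "mi", "esrd", "death"))),
                 ever = c(overweight = 0L, obesity = 0L),
                 final_state = character()),
            class = "ssb_trace")
}

# write a modified copy of the default YAML inputs to a temp file
modified_inputs_file <- function(mutate) {
  raw <- yaml::read_yaml(system.file("extdata", "soda_tax_inputs.yaml",
                                     package = "ssbcea"))
  raw <- mutate(raw)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, path)
  path
}

# parameter set with every uncertainty collapsed to the point value
all_fixed_params <- function(params = default_inputs()$params) {
  fix_df <- function(df) { df$uncertainty <- "fixed"; df$family <- "fixed"; df }
  params$transitions <- fix_df(params$transitions)
  params$costs <- fix_df(params$costs)
  params$utilities <- fix_df(params$utilities)
  params$weight_effect$uncertainty <- "fixed"
  params$weight_effect$family <- "fixed"
  params$revenue$uncertainty <- "fixed"; params$revenue$family <- "fixed"
  params$admin$uncertainty <- "fixed"; params$admin$family <- "fixed"
  params
}
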