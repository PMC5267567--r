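# internal helpers shared across modules

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
# All user-facing randomness flows through this, so results are reproducible
# from a single integer and functions never clobber the session RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Exact string matching between dataset and tree after underscore/space
# normalization and case folding; fuzzy matching is deliberately out of scope.
normalize_taxon_name <- function(x) {
  tolower(gsub("[ _]+", "_", trimws(x)))
}

#' @noRd
metric_columns <- function(metric) {
  metric <- match.arg(metric, c("mass", "scl"))
  if (metric == "mass") c(male = "male_mass_g", female = "female_mass_g")
  else c(male = "male_scl_cm", female = "female_scl_cm")
}

# rows with a complete, positive male/female pair for the metric
has_complete_pair <- function(ds, metric) {
  cols <- metric_columns(metric)
  m <- ds[[cols[["male"]]]]
  f <- ds[[cols[["female"]]]]
  !is.na(m) & !is.na(f) & m > 0 & f > 0
}

ssd_message <- function(verbose, ...) {
  if (isTRUE(verbose)) message(...)
}
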