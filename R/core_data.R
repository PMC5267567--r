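#' Column schema of a population body-size table
#'
#' A dataset row is one population of one species, carrying sex-paired mean
#' body sizes in two metrics: body mass in grams and straight carapace length
#' (SCL) in centimetres. Provenance flags record whether the reported size is
#' a mean, the midpoint of a reported range, or a maximum, and whether the
#' population is captive. Missing sizes are encoded as empty cells or `"NA"`.
#'
#' @format Character vector of the eleven canonical column names:
#'   `species`, `family`, `suborder`, `population_id`, `male_mass_g`,
#'   `female_mass_g`, `male_scl_cm`, `female_scl_cm`, `basis`
#'   (one of `"mean"`, `"midpoint"`, `"maximum"`), `captive` (logical),
#'   `source_id`.
#' @export
dataset_columns <- c(
  "species", "family", "suborder", "population_id",
  "male_mass_g", "female_mass_g", "male_scl_cm", "female_scl_cm",
  "basis", "captive", "source_id"
)

#' Read a population body-size dataset from CSV
#'
#' Parses a CSV with one row per population and validates it against the
#' schema in [dataset_columns]. Rows lacking a complete male/female pair for
#' both metrics carry no usable signal for any analysis and are dropped, with
#' the count reported. Sizes must be strictly positive where present.
#'
#' @param file Path to a CSV file, or a connection, with a header row.
#' @param schema Optional named character vector mapping canonical field
#'   names (names) to the file's column names (values), for files whose
#'   headers differ from [dataset_columns].
#' @param verbose Report dropped-row counts via [message()]. Default `TRUE`.
#' @return A `data.frame` with the canonical columns, one row per retained
#'   population.
#' @examples
#' path <- system.file("extdata", "synthetic_turtles.csv",
#'                     package = "ssdallometry")
#' ds <- read_dataset(path, verbose = FALSE)
#' head(ds)
#' @export
read_dataset <- function(file, schema = NULL, verbose = TRUE) {
  ds <- tryCatch(
    utils::read.csv(file, stringsAsFactors = FALSE,
                    na.strings = c("", "NA"), strip.white = TRUE),
    error = function(e) stop("malformed CSV: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (!is.null(schema)) {
    missing_src <- setdiff(unname(schema), names(ds))
    if (length(missing_src))
      stop("schema refers to absent columns: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    names(ds)[match(unname(schema), names(ds))] <- names(schema)
  }
  missing_cols <- setdiff(dataset_columns, names(ds))
  if (length(missing_cols))
    stop("dataset lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  ds <- ds[dataset_columns]

  size_cols <- c("male_mass_g", "female_mass_g", "male_scl_cm", "female_scl_cm")
  for (cl in size_cols) {
    v <- ds[[cl]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(v))
      if (any(is.na(v) & !is.na(ds[[cl]])))
        stop("non-numeric size value in column ", cl, call. = FALSE)
      ds[[cl]] <- v
    }
    bad <- which(!is.na(v) & (!is.finite(v) | v <= 0))
    if (length(bad))
      stop("nonpositive or non-finite size in column ", cl,
           " for record(s): ",
           paste(ds$species[bad], ds$population_id[bad],
                 sep = "/", collapse = ", "),
           call. = FALSE)
  }
  ds$captive <- as.logical(ds$captive)

  usable <- has_complete_pair(ds, "mass") | has_complete_pair(ds, "scl")
  n_drop <- sum(!usable)
  if (n_drop > 0)
    ssd_message(verbose, "Dropped ", n_drop,
                " record(s) with no complete sex pair for either metric")
  ds <- ds[usable, , drop = FALSE]
  rownames(ds) <- NULL
  ds
}

#' Write a population dataset to CSV
#'
#' Inverse of [read_dataset()]: writes the canonical columns so that a
#' read/write round trip is lossless for all fields.
#'
#' @param ds Dataset `data.frame` with the columns of [dataset_columns].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_dataset <- function(ds, file) {
  stopifnot(all(dataset_columns %in% names(ds)))
  utils::write.csv(ds[dataset_columns], file, row.names = FALSE, na = "")
  invisible(file)
}

#' Midpoint of a reported size range
#'
#' Sources that report only a range of adult sizes contribute the range
#' midpoint, on the raw (untransformed) scale, as the population's average
#' size.
#'
#' @param low,high Range endpoints; `0 < low <= high`.
#' @return `(low + high) / 2`.
#' @examples
#' midpoint_from_range(100, 300)  # 200
#' @export
midpoint_from_range <- function(low, high) {
  if (any(!is.finite(low)) || any(!is.finite(high)) || any(low <= 0))
    stop("range endpoints must be positive and finite", call. = FALSE)
  if (any(low > high))
    stop("range low exceeds high", call. = FALSE)
  (low + high) / 2
}

#' Select one population per species at random
#'
#' Species represented by several populations contribute exactly one,
#' drawn uniformly among the populations with a complete male/female pair
#' for the chosen metric. Species with no complete pair for the metric are
#' excluded. The draw is deterministic for a fixed seed.
#'
#' @param ds Dataset `data.frame` (see [dataset_columns]).
#' @param metric `"mass"` or `"scl"`.
#' @param seed Integer seed driving the selection.
#' @param verbose Report the number of excluded species. Default `TRUE`.
#' @return A `data.frame` with one row per retained species, sorted by
#'   species name, with attributes `metric` and `seed` recorded for
#'   provenance.
#' @export
select_one_population_per_species <- function(ds, metric = c("mass", "scl"),
                                              seed, verbose = TRUE) {
  metric <- match.arg(metric)
  if (nrow(ds) == 0) stop("empty dataset", call. = FALSE)
  eligible <- ds[has_complete_pair(ds, metric), , drop = FALSE]
  excluded <- setdiff(unique(ds$species), unique(eligible$species))
  if (length(excluded))
    ssd_message(verbose, "Excluded ", length(excluded),
                " species with no complete ", metric, " pair")
  species <- sort(unique(eligible$species))
  picked <- with_seed(seed, {
    vapply(species, function(sp) {
      idx <- which(eligible$species == sp)
      if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
    }, integer(1))
  })
  out <- eligible[picked, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "metric") <- metric
  attr(out, "seed") <- seed
  out
}

#' Log-transform body sizes
#'
#' All allometric analyses operate on logarithms of size. Base 10 is the
#' package default: SMA slopes, r-squared, confidence intervals and the
#' slope-equals-one test are invariant to the common log base, and base-10
#' intercepts match conventional allometry plots.
#'
#' @param values Positive numeric sizes.
#' @param base Logarithm base; default 10.
#' @return Elementwise `log(values, base)`.
#' @export
log_transform <- function(values, base = 10) {
  if (any(!is.finite(values) | values <= 0))
    stop("log_transform requires strictly positive finite values",
         call. = FALSE)
  log(values, base = base)
}
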