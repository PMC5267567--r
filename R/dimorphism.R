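#' Lovich-Gibbons sexual size dimorphism index
#'
#' The index is `(larger sex / smaller sex) - 1`, signed positive when
#' females are the larger sex and negative when males are. It is symmetric
#' around zero and reads as a proportional size difference (0.684 means the
#' larger sex is 68.4% bigger). By default the ratio is taken on raw,
#' untransformed sizes, which is the scale on which the index is a percent
#' difference; a log-scale variant is exposed for comparison but changes the
#' index's magnitude substantially and is not used by the summaries.
#'
#' @param male_size,female_size Positive sizes, same units; vectorized.
#' @param scale `"raw"` (default) or `"log"` (index of the base-10 logs).
#' @return Signed numeric index, zero when the sexes are equal.
#' @examples
#' dimorphism_index(9500, 16000)   # 0.684: females two-thirds heavier
#' dimorphism_index(45.4, 52.3)    # 0.152
#' dimorphism_index(200, 100)      # -1: males twice as heavy
#' @export
dimorphism_index <- function(male_size, female_size, scale = c("raw", "log")) {
  scale <- match.arg(scale)
  check_sizes(male_size, female_size)
  m <- male_size
  f <- female_size
  if (scale == "log") {
    m <- log10(m)
    f <- log10(f)
    if (any(m <= 0) || any(f <= 0))
      stop("log-scale index requires sizes > 1 in their unit", call. = FALSE)
  }
  ratio <- pmax(m, f) / pmin(m, f)
  sign <- ifelse(f >= m, 1, -1)
  sign * (ratio - 1)
}

check_sizes <- function(male_size, female_size) {
  if (any(!is.finite(male_size) | male_size <= 0) ||
      any(!is.finite(female_size) | female_size <= 0))
    stop("sizes must be strictly positive and finite", call. = FALSE)
}

#' Classify the direction of sexual size dimorphism
#'
#' A species whose sexes differ by less than `negligible_threshold`
#' (proportionally, on raw sizes) is classed as negligibly dimorphic;
#' otherwise the larger sex labels the direction. A difference exactly at
#' the threshold counts as dimorphic (strict `<`).
#'
#' @inheritParams dimorphism_index
#' @param negligible_threshold Proportional difference below which SSD is
#'   negligible; default 0.02 (2%).
#' @return Factor with levels `female_larger`, `male_larger`, `negligible`.
#' @export
classify_direction <- function(male_size, female_size,
                               negligible_threshold = 0.02) {
  stopifnot(negligible_threshold > 0, negligible_threshold < 1)
  idx <- dimorphism_index(male_size, female_size)
  out <- ifelse(abs(idx) < negligible_threshold, "negligible",
                ifelse(idx > 0, "female_larger", "male_larger"))
  factor(out, levels = c("female_larger", "male_larger", "negligible"))
}

#' Family-level summary of sizes and dimorphism
#'
#' For each family: species count, arithmetic mean male and female size, and
#' the arithmetic mean of the per-species signed dimorphism indices — the
#' mean of the ratios rather than the ratio of the means, so that the
#' largest species do not dominate the family's dimorphism summary.
#'
#' @param ds One-record-per-species dataset (after
#'   [select_one_population_per_species()]).
#' @param metric `"mass"` or `"scl"`.
#' @return `data.frame` with columns `family`, `n_species`,
#'   `mean_male_size`, `mean_female_size`, `mean_index`, sorted by family.
#' @export
summarize_by_family <- function(ds, metric = c("mass", "scl")) {
  metric <- match.arg(metric)
  cols <- metric_columns(metric)
  ds <- ds[has_complete_pair(ds, metric), , drop = FALSE]
  if (anyDuplicated(ds$species))
    stop("summarize_by_family expects one record per species", call. = FALSE)
  idx <- dimorphism_index(ds[[cols[["male"]]]], ds[[cols[["female"]]]])
  fams <- sort(unique(ds$family))
  out <- do.call(rbind, lapply(fams, function(fam) {
    i <- ds$family == fam
    data.frame(
      family = fam,
      n_species = sum(i),
      mean_male_size = mean(ds[[cols[["male"]]]][i]),
      mean_female_size = mean(ds[[cols[["female"]]]][i]),
      mean_index = mean(idx[i])
    )
  }))
  rownames(out) <- NULL
  out
}

#' Census of dimorphism direction across species
#'
#' Counts and percentages of species in which females are larger, males are
#' larger, or the difference is negligible. Percentages are reported to one
#' decimal place, as count / n * 100.
#'
#' @inheritParams summarize_by_family
#' @param negligible_threshold Proportional difference below which SSD is
#'   negligible; default 0.02.
#' @return `data.frame` with columns `direction`, `count`, `percent`; counts
#'   sum to the number of species censused.
#' @export
direction_census <- function(ds, metric = c("mass", "scl"),
                             negligible_threshold = 0.02) {
  metric <- match.arg(metric)
  cols <- metric_columns(metric)
  ds <- ds[has_complete_pair(ds, metric), , drop = FALSE]
  if (anyDuplicated(ds$species))
    stop("direction_census expects one record per species", call. = FALSE)
  dir <- classify_direction(ds[[cols[["male"]]]], ds[[cols[["female"]]]],
                            negligible_threshold)
  counts <- table(dir)
  data.frame(
    direction = names(counts),
    count = as.integer(counts),
    percent = round(as.integer(counts) / nrow(ds) * 100, 1)
  )
}
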