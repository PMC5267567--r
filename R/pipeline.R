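#' Configuration of a Rensch's-rule analysis run
#'
#' @param metric Body-size metric: `"mass"` or `"scl"`.
#' @param level Clade stratification for the per-clade rows: `"order"`
#'   (whole dataset only), `"suborder"`, or `"family"`.
#' @param min_clade_size Minimum species count for a clade to get its own
#'   row (default 7); smaller clades still contribute to the whole-dataset
#'   and suborder analyses.
#' @param alpha Level of the slope CIs and tests; default 0.05.
#' @param phylogenetic Whether the run uses independent contrasts.
#' @param seed Integer seed driving population selection and polytomy
#'   resolution.
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(metric = c("mass", "scl"),
                            level = c("family", "suborder", "order"),
                            min_clade_size = 7, alpha = 0.05,
                            phylogenetic = FALSE, seed = 1) {
  metric <- match.arg(metric)
  level <- match.arg(level)
  stopifnot(min_clade_size >= 3, alpha > 0, alpha < 1)
  structure(list(metric = metric, level = level,
                 min_clade_size = as.integer(min_clade_size),
                 alpha = alpha, phylogenetic = isTRUE(phylogenetic),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

# clades analysed at the configured level; the whole dataset always gets
# the first row ("All"). min_clade_size governs family rows (the
# seven-or-more-species rule); suborders are top-level strata and need
# only the SMA minimum of 3 species.
clade_groups <- function(ds, config) {
  groups <- list(All = seq_len(nrow(ds)))
  if (config$level != "order") {
    col <- if (config$level == "suborder") "suborder" else "family"
    threshold <- if (col == "family") config$min_clade_size else 3L
    for (cl in sort(unique(ds[[col]]))) {
      idx <- which(ds[[col]] == cl)
      if (length(idx) >= threshold) groups[[cl]] <- idx
    }
  }
  groups
}

#' Clade-stratified SMA analysis of Rensch's rule (traditional)
#'
#' For the whole dataset and each clade at the configured level with at
#' least `min_clade_size` species, fits the SMA of log10 male size (y) on
#' log10 female size (x) and attaches the CI-based verdict. Clades below
#' the size threshold are skipped and listed in the `skipped` attribute.
#'
#' @param ds One-record-per-species dataset projected to `config$metric`
#'   (see [select_one_population_per_species()]).
#' @param config An [analysis_config()].
#' @return `data.frame` with one row per analysed clade: `clade`, `n`,
#'   `intercept`, `slope`, `ci_low`, `ci_high`, `r_squared`, `p_slope_eq_1`,
#'   `verdict`. Attribute `skipped` names clades below the threshold.
#' @export
run_traditional <- function(ds, config) {
  stopifnot(inherits(config, "analysis_config"))
  cols <- metric_columns(config$metric)
  ds <- ds[has_complete_pair(ds, config$metric), , drop = FALSE]
  if (anyDuplicated(ds$species))
    stop("expected one record per species; run ",
         "select_one_population_per_species() first", call. = FALSE)
  groups <- clade_groups(ds, config)
  rows <- lapply(names(groups), function(cl) {
    i <- groups[[cl]]
    x <- log_transform(ds[[cols[["female"]]]][i])
    y <- log_transform(ds[[cols[["male"]]]][i])
    fit <- sma_fit(x, y, alpha = config$alpha)
    data.frame(clade = cl, n = fit$n, intercept = fit$intercept,
               slope = fit$slope, ci_low = fit$ci_low,
               ci_high = fit$ci_high, r_squared = fit$r_squared,
               p_slope_eq_1 = fit$p_slope_eq_1,
               verdict = classify_allometry(fit))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  col <- if (config$level == "suborder") "suborder" else "family"
  if (config$level != "order")
    attr(out, "skipped") <- setdiff(sort(unique(ds[[col]])), out$clade)
  out
}

#' Clade-stratified SMA analysis on phylogenetic independent contrasts
#'
#' For each clade analysed by [run_traditional()]: prunes the tree to the
#' clade's species, resolves polytomies into seeded random dichotomies,
#' computes independent contrasts of female and of male log10 size on the
#' same resolved tree (so the contrast pairs are comparable), and fits the
#' through-origin SMA of male on female contrasts. Species absent from the
#' tree are dropped with a note; clades with fewer than 3 matched species
#' are skipped.
#'
#' @inheritParams run_traditional
#' @param tree A rooted `phylo` object with branch lengths covering (at
#'   least part of) the dataset's species.
#' @return `data.frame` with one row per analysed clade: `clade`, `n`
#'   (matched species), `slope`, `ci_low`, `ci_high`, `r_squared`,
#'   `p_slope_eq_1`, `verdict`. Attributes `skipped` (clades without enough
#'   matched species) and `unmatched` (species absent from the tree).
#' @export
run_phylogenetic <- function(ds, tree, config) {
  stopifnot(inherits(config, "analysis_config"))
  cols <- metric_columns(config$metric)
  ds <- ds[has_complete_pair(ds, config$metric), , drop = FALSE]
  if (anyDuplicated(ds$species))
    stop("expected one record per species", call. = FALSE)
  groups <- clade_groups(ds, config)
  skipped <- character(0)
  unmatched <- character(0)
  rows <- list()
  for (cl in names(groups)) {
    i <- groups[[cl]]
    sub <- ds[i, , drop = FALSE]
    pr <- tryCatch(prune_to_taxa(tree, sub$species), error = function(e) NULL)
    if (is.null(pr)) {
      skipped <- c(skipped, cl)
      next
    }
    unmatched <- union(unmatched, pr$in_data_only)
    clade_tree <- resolve_polytomies(pr$tree, seed = config$seed)
    key <- match(normalize_taxon_name(clade_tree$tip.label),
                 normalize_taxon_name(sub$species))
    fvals <- stats::setNames(log_transform(sub[[cols[["female"]]]][key]),
                             clade_tree$tip.label)
    mvals <- stats::setNames(log_transform(sub[[cols[["male"]]]][key]),
                             clade_tree$tip.label)
    fc <- pic_contrasts(clade_tree, fvals)$contrasts
    mc <- pic_contrasts(clade_tree, mvals)$contrasts
    fit <- sma_fit_through_origin(fc, mc, alpha = config$alpha)
    rows[[cl]] <- data.frame(
      clade = cl, n = length(clade_tree$tip.label), slope = fit$slope,
      ci_low = fit$ci_low, ci_high = fit$ci_high,
      r_squared = fit$r_squared, p_slope_eq_1 = fit$p_slope_eq_1,
      verdict = classify_allometry(fit))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "unmatched") <- unmatched
  out
}

#' Sex-specific mass-length regressions with Chow and slope tests
#'
#' On all populations with complete mass and SCL for both sexes, regresses
#' log10 SCL on log10 mass for males, for females, and for both sexes
#' pooled (each population contributes one male and one female record to
#' the pooled fit), then compares the sexes with a Chow test on the pooled
#' versus separate fits and a two-group slope-equality t-test.
#'
#' @param ds Population-level dataset (all populations; multiple per
#'   species allowed).
#' @return List with `male`, `female`, `pooled` (`ols_fit` objects),
#'   `chow` ([chow_test()] result), `slope_equality`
#'   ([slope_equality_test()] result), and `n_populations`.
#' @export
run_mass_length <- function(ds) {
  ok <- has_complete_pair(ds, "mass") & has_complete_pair(ds, "scl")
  sub <- ds[ok, , drop = FALSE]
  if (nrow(sub) < 3)
    stop("insufficient data: fewer than 3 populations with complete ",
         "mass and SCL for both sexes", call. = FALSE)
  xm <- log_transform(sub$male_mass_g)
  ym <- log_transform(sub$male_scl_cm)
  xf <- log_transform(sub$female_mass_g)
  yf <- log_transform(sub$female_scl_cm)
  list(
    male = ols_fit(xm, ym),
    female = ols_fit(xf, yf),
    pooled = ols_fit(c(xm, xf), c(ym, yf)),
    chow = chow_test(xm, ym, xf, yf),
    slope_equality = slope_equality_test(xm, ym, xf, yf),
    n_populations = nrow(sub)
  )
}

#' Reproduce the full study from a dataset and a tree
#'
#' Runs the complete pipeline for both metrics: per-species population
#' selection, family summaries and direction censuses, traditional SMA at
#' order/suborder/family levels, phylogenetic-contrast SMA on the pruned
#' and resolved tree, Blomberg's K with permutation p for each sex, and the
#' population-level mass-length comparison. All randomness (population
#' selection, polytomy resolution, permutations) derives from `seed`.
#'
#' @param dataset_path CSV dataset path (see [dataset_columns]).
#' @param tree_path Newick tree path.
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, all tables are written as
#'   CSV plus a `run_log.txt` recording the seed and record counts.
#' @param metrics Metrics to analyse; default both.
#' @param min_clade_size Minimum species per family row; default 7.
#' @param alpha Test level; default 0.05.
#' @param n_permutations Permutations for the K test; default 999.
#' @param verbose Emit progress messages. Default `TRUE`.
#' @return Nested list, one element per metric with `summary`, `census`,
#'   `traditional`, `phylogenetic`, `blomberg_k`, plus `mass_length` and
#'   `config`.
#' @export
reproduce_study <- function(dataset_path, tree_path, seed = 1,
                            out_dir = NULL, metrics = c("mass", "scl"),
                            min_clade_size = 7, alpha = 0.05,
                            n_permutations = 999, verbose = TRUE) {
  ds_all <- read_dataset(dataset_path, verbose = verbose)
  tree <- read_newick(tree_path)
  report <- list(config = list(seed = seed, alpha = alpha,
                               min_clade_size = min_clade_size,
                               dataset = dataset_path, tree = tree_path,
                               n_records = nrow(ds_all)))
  for (metric in metrics) {
    ssd_message(verbose, "== metric: ", metric, " ==")
    ds1 <- select_one_population_per_species(ds_all, metric, seed = seed,
                                             verbose = verbose)
    cfg_t <- analysis_config(metric, "family", min_clade_size, alpha,
                             phylogenetic = FALSE, seed = seed)
    cfg_s <- analysis_config(metric, "suborder", min_clade_size, alpha,
                             phylogenetic = FALSE, seed = seed)
    trad <- rbind(run_traditional(ds1, cfg_s),
                  run_traditional(ds1, cfg_t)[-1, , drop = FALSE])
    phylo <- rbind(run_phylogenetic(ds1, tree, cfg_s),
                   run_phylogenetic(ds1, tree, cfg_t)[-1, , drop = FALSE])

    pr <- prune_to_taxa(tree, ds1$species)
    ktree <- resolve_polytomies(pr$tree, seed = seed)
    key <- match(normalize_taxon_name(ktree$tip.label),
                 normalize_taxon_name(ds1$species))
    cols <- metric_columns(metric)
    kres <- lapply(c(male = "male", female = "female"), function(sx) {
      vals <- stats::setNames(log_transform(ds1[[cols[[sx]]]][key]),
                              ktree$tip.label)
      k_significance(ktree, vals, n_permutations = n_permutations,
                     seed = seed)
    })
    report[[metric]] <- list(
      summary = summarize_by_family(ds1, metric),
      census = direction_census(ds1, metric),
      traditional = trad,
      phylogenetic = phylo,
      blomberg_k = data.frame(
        sex = names(kres),
        k = vapply(kres, `[[`, numeric(1), "k"),
        p_value = vapply(kres, `[[`, numeric(1), "p_value"),
        n_permutations = n_permutations, row.names = NULL)
    )
  }
  report$mass_length <- tryCatch(run_mass_length(ds_all),
                                 error = function(e) NULL)
  if (!is.null(out_dir)) write_report(report, out_dir, metrics)
  invisible(report)
}

write_report <- function(report, out_dir, metrics) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (metric in metrics) {
    for (tb in c("summary", "census", "traditional", "phylogenetic",
                 "blomberg_k")) {
      utils::write.csv(report[[metric]][[tb]],
                       file.path(out_dir, paste0(tb, "_", metric, ".csv")),
                       row.names = FALSE)
    }
  }
  if (!is.null(report$mass_length)) {
    ml <- report$mass_length
    utils::write.csv(data.frame(
      group = c("male", "female", "pooled"),
      n = c(ml$male$n, ml$female$n, ml$pooled$n),
      slope = c(ml$male$slope, ml$female$slope, ml$pooled$slope),
      intercept = c(ml$male$intercept, ml$female$intercept,
                    ml$pooled$intercept),
      r_squared = c(ml$male$r_squared, ml$female$r_squared,
                    ml$pooled$r_squared)),
      file.path(out_dir, "mass_length.csv"), row.names = FALSE)
  }
  cfg <- report$config
  writeLines(c(
    paste0("seed: ", cfg$seed),
    paste0("alpha: ", cfg$alpha),
    paste0("min_clade_size: ", cfg$min_clade_size),
    paste0("dataset: ", cfg$dataset),
    paste0("tree: ", cfg$tree),
    paste0("n_records: ", cfg$n_records)
  ), file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
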