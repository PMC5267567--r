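#' Read a rooted phylogeny from a Newick file or string
#'
#' Thin wrapper over [ape::read.tree()] adding the validation the
#' comparative analyses need: unique tip labels and branch lengths on every
#' edge. Trees without branch lengths are rejected unless a default length
#' is supplied, in which case it is assigned to every edge with a warning.
#'
#' @param file Path to a Newick file, or `NULL` when `text` is given.
#' @param text Newick string, alternative to `file`.
#' @param default_length Optional branch length to assign when the tree has
#'   none.
#' @return A rooted `phylo` object with branch lengths.
#' @export
read_newick <- function(file = NULL, text = NULL, default_length = NULL) {
  tree <- tryCatch(
    if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: no tree found", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length)) {
    if (is.null(default_length))
      stop("tree has no branch lengths (supply default_length to assign one)",
           call. = FALSE)
    warning("tree has no branch lengths; assigning default ", default_length)
    tree$edge.length <- rep(default_length, nrow(tree$edge))
  }
  if (any(tree$edge.length < 0))
    stop("negative branch length in tree", call. = FALSE)
  tree
}

#' Write a phylogeny to Newick
#' @param tree A `phylo` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_newick <- function(tree, file) {
  ape::write.tree(tree, file = file)
  invisible(file)
}

#' Resolve polytomies into random dichotomies
#'
#' Multifurcations are broken into a uniformly random sequence of
#' bifurcations (via [ape::multi2di()]), inserting zero-length internal
#' edges so that every tip-to-root path length — and hence the expected
#' Brownian variance of every tip — is unchanged. Deterministic for a fixed
#' seed; an already binary tree is returned untouched.
#'
#' @param tree A rooted `phylo` object.
#' @param seed Integer seed for the random resolution.
#' @return A strictly binary `phylo` object.
#' @export
resolve_polytomies <- function(tree, seed) {
  # a basal trichotomy passes is.binary() (unrooted sense); require rooted
  if (ape::is.binary(tree) && ape::is.rooted(tree)) return(tree)
  with_seed(seed, ape::multi2di(tree, random = TRUE))
}

#' Prune a tree to a set of taxa, reporting mismatches
#'
#' Restricts the tree to the tips whose labels match `names` (exact match
#' after underscore/space normalization and case folding). Degree-2 nodes
#' left by the pruning are suppressed with branch lengths summed, so all
#' pairwise path lengths among survivors are preserved.
#'
#' @param tree A `phylo` object.
#' @param names Character vector of taxon names to keep.
#' @return List with elements `tree` (the pruned `phylo`),
#'   `in_data_only` (names absent from the tree) and `in_tree_only` (tips
#'   not requested). At least 3 matches are required.
#' @export
prune_to_taxa <- function(tree, names) {
  if (length(names) == 0) stop("no taxon names supplied", call. = FALSE)
  tip_norm <- normalize_taxon_name(tree$tip.label)
  want_norm <- normalize_taxon_name(names)
  keep <- tree$tip.label[tip_norm %in% want_norm]
  if (length(keep) < 3)
    stop("insufficient overlap: only ", length(keep),
         " of ", length(names), " taxa matched the tree", call. = FALSE)
  list(
    tree = ape::keep.tip(tree, keep),
    in_data_only = names[!(want_norm %in% tip_norm)],
    in_tree_only = tree$tip.label[!(tip_norm %in% want_norm)]
  )
}

#' Felsenstein phylogenetic independent contrasts
#'
#' Computes the n-1 standardized independent contrasts of a trait on a
#' rooted binary tree by post-order pruning. At an internal node with child
#' values `x_i, x_j` on working branch lengths `v_i, v_j`, the contrast is
#' `(x_i - x_j) / sqrt(v_i + v_j)`; the node's working value is the
#' precision-weighted mean `(x_i/v_i + x_j/v_j) / (1/v_i + 1/v_j)` and its
#' parent edge is extended by `v_i v_j / (v_i + v_j)`. Contrast signs depend
#' on an arbitrary child ordering, so downstream statistics must be
#' invariant to sign flips — which is why contrast regressions go through
#' the origin.
#'
#' @param tree A rooted, strictly binary `phylo` object with branch
#'   lengths; zero-length edges are allowed provided no contrast is
#'   standardized by a total of zero.
#' @param tip_values Named numeric vector covering every tip label.
#' @return An object of class `contrast_set`: list with `contrasts`
#'   (numeric, length n-1, named by internal node number) and
#'   `node_variances` (the standardizing sums `v_i + v_j`).
#' @examples
#' tr <- read_newick(text = "((A:1,B:1):1,C:2);")
#' pic_contrasts(tr, c(A = 1, B = 3, C = 6))
#' @export
pic_contrasts <- function(tree, tip_values) {
  if (!ape::is.binary(tree))
    stop("tree must be strictly binary (resolve polytomies first)",
         call. = FALSE)
  miss <- setdiff(tree$tip.label, names(tip_values))
  if (length(miss))
    stop("missing tip value(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  nnode <- tr$Nnode
  x <- numeric(ntip + nnode)
  x[seq_len(ntip)] <- as.numeric(tip_values[tr$tip.label])
  ext <- numeric(ntip + nnode)       # pruning extension of each node's edge
  contrasts <- numeric(nnode)
  variances <- numeric(nnode)

  parent <- tr$edge[, 1]
  child <- tr$edge[, 2]
  elen <- tr$edge.length
  for (i in seq(1, length(parent), by = 2)) {
    k <- parent[i]
    stopifnot(parent[i + 1] == k)    # postorder pairs children of one node
    c1 <- child[i]; c2 <- child[i + 1]
    v1 <- elen[i] + ext[c1]
    v2 <- elen[i + 1] + ext[c2]
    vt <- v1 + v2
    if (vt == 0)
      stop("degenerate standardization: both child branches of node ", k,
           " have zero working length", call. = FALSE)
    j <- k - ntip
    contrasts[j] <- (x[c1] - x[c2]) / sqrt(vt)
    variances[j] <- vt
    x[k] <- if (v1 == 0) x[c1]
            else if (v2 == 0) x[c2]
            else (x[c1] / v1 + x[c2] / v2) / (1 / v1 + 1 / v2)
    ext[k] <- v1 * v2 / vt
  }
  names(contrasts) <- names(variances) <- as.character(ntip + seq_len(nnode))
  structure(list(contrasts = contrasts, node_variances = variances),
            class = "contrast_set")
}

#' Blomberg's K statistic of phylogenetic signal
#'
#' K compares the observed ratio of among-species trait variance to the
#' variance remaining after accounting for the tree, against the same ratio
#' expected under Brownian motion. With `V` the matrix of shared path
#' lengths between tips, phylogenetic GLS mean
#' `a = (1' V^-1 x) / (1' V^-1 1)`, `MSE0 = sum((x - a)^2) / (n - 1)` and
#' `MSE = (x - a)' V^-1 (x - a) / (n - 1)`:
#' `K = (MSE0 / MSE) / ((tr(V) - n / (1' V^-1 1)) / (n - 1))`.
#' K = 1 matches the Brownian expectation on the given tree; K < 1 means
#' relatives resemble each other less than Brownian motion predicts. The
#' matrix form requires no ultrametricity. K is invariant to shifting and
#' positively rescaling the trait.
#'
#' @param tree A rooted `phylo` object with branch lengths (need not be
#'   binary or ultrametric).
#' @param tip_values Named numeric vector covering every tip.
#' @return The K value (nonnegative scalar).
#' @export
blomberg_k <- function(tree, tip_values) {
  miss <- setdiff(tree$tip.label, names(tip_values))
  if (length(miss))
    stop("missing tip value(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- as.numeric(tip_values[tree$tip.label])
  n <- length(x)
  V <- ape::vcv(tree)
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular phylogenetic covariance matrix ",
         "(zero-distance duplicate tips?)", call. = FALSE))
  one_Vi_one <- sum(Vi)
  ahat <- sum(Vi %*% x) / one_Vi_one
  d <- x - ahat
  mse0 <- sum(d^2) / (n - 1)
  mse <- as.numeric(t(d) %*% Vi %*% d) / (n - 1)
  expected <- (sum(diag(V)) - n / one_Vi_one) / (n - 1)
  (mse0 / mse) / expected
}

#' Permutation test of phylogenetic signal
#'
#' Assesses whether a trait carries more phylogenetic signal than expected
#' if tip values were interchangeable: the test statistic is the variance of
#' the standardized independent contrasts (lower variance = more signal),
#' and the null is generated by permuting the trait values across tips. The
#' p-value uses the add-one convention
#' `p = (1 + #{permuted variance <= observed}) / (n_permutations + 1)`, so
#' it is never zero.
#'
#' @param tree A rooted, binary `phylo` object with branch lengths.
#' @param tip_values Named numeric vector covering every tip.
#' @param n_permutations Number of permutations; default 999.
#' @param seed Integer seed for the permutations.
#' @return An object of class `k_result`: list with `k` (Blomberg's K),
#'   `p_value`, `n_permutations`, `seed`, and `observed_variance`.
#' @export
k_significance <- function(tree, tip_values, n_permutations = 999, seed) {
  k <- blomberg_k(tree, tip_values)
  obs <- stats::var(pic_contrasts(tree, tip_values)$contrasts)
  vals <- as.numeric(tip_values[tree$tip.label])
  perm_vars <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      perm <- stats::setNames(sample(vals), tree$tip.label)
      stats::var(pic_contrasts(tree, perm)$contrasts)
    }, numeric(1))
  })
  p <- (1 + sum(perm_vars <= obs)) / (n_permutations + 1)
  structure(list(k = k, p_value = p, n_permutations = n_permutations,
                 seed = seed, observed_variance = obs),
            class = "k_result")
}

#' @export
print.k_result <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.4g, permutation P = %.4g (%d permutations)\n",
              x$k, x$p_value, x$n_permutations))
  invisible(x)
}
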