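#' Per-protein one-way ANOVA F-ratio screen
#'
#' For each protein, the F ratio is the model mean square divided by the
#' error mean square of a one-way between-group ANOVA over the run profiles
#' (`df = (g - 1, N - g)`), and the p-value is the upper tail of the F
#' distribution. A protein is retained when `F >= f_min` and `p <= p_max`
#' (defaults 2 and 0.05). This univariate retention rule is the variable
#' screen often run ahead of discriminant analysis in proteomics software.
#'
#' Degenerate proteins: zero between- and within-group variance gives
#' `F = 0, p = 1` (uninformative); zero within-group variance with
#' between-group signal gives `F = Inf, p = 0` (retained).
#'
#' @param m run-level [count_matrix] (normally normalized).
#' @param design run design; ignored when `groups` is given.
#' @param groups grouping factor aligned with the matrix columns; defaults to
#'   the condition label of each run.
#' @param f_min,p_max retention thresholds.
#' @param adjust `"none"` (default, raw p-values) or `"BH"` for
#'   Benjamini-Hochberg adjustment before thresholding.
#' @return `data.frame` with `protein, f_ratio, p_value, retained`.
#' @export
f_screen <- function(m, design = NULL, groups = NULL,
                     f_min = 2, p_max = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(groups)) {
    if (is.null(design)) stop("provide a design or explicit groups")
    validate_design(design)
    design <- design[match(colnames(m), design$run_id), ]
    groups <- condition_id(design)
  }
  if (length(groups) != ncol(m))
    stop("groups must match the matrix columns")
  g <- factor(groups)
  k <- nlevels(g)
  n <- ncol(m)
  if (k < 2) stop("need at least two groups")
  if (n <= k) stop("need more observations than groups")
  X <- unclass(m)
  ng <- as.vector(table(g))
  ind <- stats::model.matrix(~ g - 1)
  gm <- sweep(X %*% ind, 2, ng, "/")          # group means
  grand <- rowMeans(X)
  ssb <- rowSums(sweep(sweep(gm, 1, grand, "-")^2, 2, ng, "*"))
  sst <- rowSums((X - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  eps <- 1e-12 * pmax(sst, 1)
  f <- msb / msw
  p <- pf(f, k - 1, n - k, lower.tail = FALSE)
  zero_w <- ssw <= eps
  zero_b <- ssb <= eps
  f[zero_w & zero_b] <- 0;   p[zero_w & zero_b] <- 1
  f[zero_w & !zero_b] <- Inf; p[zero_w & !zero_b] <- 0
  if (adjust == "BH") p <- p.adjust(p, "BH")
  data.frame(protein = rownames(m), f_ratio = unname(f), p_value = unname(p),
             retained = unname(f >= f_min & p <= p_max),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ward / Euclidean hierarchical clustering of column profiles
#'
#' Agglomerative clustering of the run (or condition) profiles using
#' Euclidean distance and Ward's minimum-variance criterion. Columns are
#' ordered lexicographically before clustering so ties break
#' deterministically.
#'
#' @param m [count_matrix], usually restricted to screened proteins.
#' @return an `hclust` object (`method = "ward.D2"`, heights equal
#'   `sqrt(2 x increase in within-cluster sum of squares)`).
#' @export
cluster_profiles <- function(m) {
  if (ncol(m) < 2) stop("need at least two columns to cluster")
  if (anyNA(m)) stop("NaN/NA in matrix")
  X <- unclass(m)[, order(colnames(m)), drop = FALSE]
  hclust(dist(t(X)), method = "ward.D2")
}

#' Export a dendrogram as Newick with merge heights as branch lengths
#'
#' @param hc an `hclust` from [cluster_profiles()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' PCA of condition-level aPSM profiles
#'
#' Conditions are the observations, proteins the (row-centred) variables.
#' Components are orthonormal and ordered by decreasing explained variance.
#'
#' @param m condition-level [count_matrix] (>= 2 columns).
#' @return list with `scores` (conditions x components), `loadings`
#'   (proteins x components), `explained` (variance fractions, summing to 1
#'   over the returned components) and the fitted `prcomp` object.
#' @export
pca_profiles <- function(m) {
  if (ncol(m) < 2) stop("need at least two conditions")
  pr <- prcomp(t(unclass(m)), center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  list(scores = pr$x, loadings = pr$rotation,
       explained = ev / sum(ev), prcomp = pr)
}

#' Union of screen-retained proteins and DEPs with provenance
#'
#' Combines the F-screen selection with the DEP calls into one candidate
#' list, recording for each protein which selection(s) produced it.
#'
#' @param screen_set character vector of screen-retained proteins.
#' @param dep_set character vector of DEPs.
#' @return `data.frame` with `protein, from_screen, from_dep`, one row per
#'   protein in the union (sorted).
#' @export
combine_selections <- function(screen_set, dep_set) {
  all <- sort(unique(c(screen_set, dep_set)))
  data.frame(protein = all,
             from_screen = all %in% screen_set,
             from_dep = all %in% dep_set,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Discriminant-axis projection (optional diagnostic)
#'
#' Projects run profiles of the retained proteins onto canonical discriminant
#' axes via [MASS::lda]; provided for visual checking only — variable
#' retention itself is the F screen of [f_screen()].
#'
#' @param m run-level matrix restricted to retained proteins.
#' @param groups grouping factor over columns.
#' @return matrix of discriminant scores (runs x axes).
#' @export
discriminant_projection <- function(m, groups) {
  if (!requireNamespace("MASS", quietly = TRUE))
    stop("MASS is required for discriminant_projection")
  fit <- MASS::lda(t(unclass(m)), grouping = factor(groups))
  stats::predict(fit)$x
}
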