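#' Total-count normalization of a run-level matrix
#'
#' Scales every run column so that its total equals the mean of the raw
#' column totals; within-column proportions are untouched. This aligns the 72
#' protein lists onto a common sampling depth before averaging and
#' comparison, and is idempotent.
#'
#' @param m a run-level [count_matrix].
#' @return the normalized [count_matrix] with attribute `scale_factors`.
#' @export
normalize_runs <- function(m) {
  if (column_kind(m) != "run")
    stop("normalize_runs expects a run-level matrix")
  totals <- colSums(m)
  zero <- colnames(m)[totals == 0]
  if (length(zero) > 0)
    stop("all-zero run column(s): ", paste(zero, collapse = ", "))
  f <- mean(totals) / totals
  out <- sweep(unclass(m), 2, f, "*")
  out <- count_matrix(out, kind = "run", species = attr(m, "species"))
  attr(out, "scale_factors") <- f
  out
}

#' Average runs into condition-level aPSM profiles
#'
#' The average PSM (aPSM) of a protein in a condition is the arithmetic mean
#' of its (normalized) counts over all runs of that condition; proteins
#' absent from a run contribute 0. By default the mean is taken over all runs
#' of the condition in one step; `nested = TRUE` first averages technical
#' replicates within each biological replicate, then averages bioreps (equal
#' for balanced designs).
#'
#' @param m run-level [count_matrix] (normally normalized first).
#' @param design run design covering all columns of `m`.
#' @param by grouping: `"condition"` (the 12 factorial cells) or the name of
#'   a design column (e.g. `"bpa"` for pooled arm profiles).
#' @param nested use tech-then-bio nested averaging.
#' @return a [count_matrix] with `column_kind = "condition"`.
#' @export
average_condition <- function(m, design, by = "condition", nested = FALSE) {
  validate_design(design)
  if (!all(colnames(m) %in% design$run_id))
    stop("matrix columns missing from design")
  design <- design[match(colnames(m), design$run_id), ]
  grp <- if (identical(by, "condition")) condition_id(design)
         else if (by %in% names(design)) as.character(design[[by]])
         else stop("unknown grouping: ", by)
  levels <- unique(grp)
  if (nested) {
    bio <- paste(grp, design$biorep, sep = "|")
    mb <- group_means(m, bio)
    grp2 <- sub("\\|[^|]*$", "", colnames(mb))
    out <- group_means(mb, grp2)[, levels, drop = FALSE]
  } else {
    out <- group_means(m, grp)[, levels, drop = FALSE]
  }
  count_matrix(out, kind = "condition", species = attr(m, "species"))
}

group_means <- function(m, grp) {
  if (any(table(grp) == 0)) stop("condition with zero runs")
  g <- factor(grp, levels = unique(grp))
  ind <- outer(g, levels(g), "==") * 1
  sums <- unclass(m) %*% ind
  colnames(sums) <- levels(g)
  sweep(sums, 2, table(g)[levels(g)], "/")
}

#' Technical / biological repeatability by pairwise linear regression
#'
#' For technical pairs (the two instrument runs of one biological replicate)
#' or biological pairs (bioreps within a condition, technical replicates
#' averaged first), computes the coefficient of determination R-squared of
#' one profile against the other over the union of proteins (zeros filled).
#' R-squared is the squared Pearson correlation of the two count vectors, so
#' it is symmetric in the pair.
#'
#' @param m run-level [count_matrix].
#' @param design run design.
#' @param pair_kind `"technical"` or `"biological"`.
#' @return list of class `repeatability_summary`: `pair_kind`, named
#'   `r2_values`, `mean_r2`, `sd_r2`.
#' @export
repeatability_r2 <- function(m, design, pair_kind = c("technical", "biological")) {
  pair_kind <- match.arg(pair_kind)
  validate_design(design)
  design <- design[match(colnames(m), design$run_id), ]
  cond <- condition_id(design)
  r2 <- c()
  if (pair_kind == "technical") {
    key <- paste(cond, design$biorep, sep = "|b")
    for (k in unique(key)) {
      cols <- which(key == k)
      if (length(cols) < 2) next
      pairs <- utils::combn(cols, 2)
      for (j in seq_len(ncol(pairs))) {
        r2 <- c(r2, stats::setNames(
          cor(m[, pairs[1, j]], m[, pairs[2, j]])^2,
          paste(colnames(m)[pairs[, j]], collapse = " vs ")))
      }
    }
  } else {
    bio <- paste(cond, design$biorep, sep = "|b")
    mb <- group_means(m, bio)
    bcond <- sub("\\|b[^|]*$", "", colnames(mb))
    for (k in unique(bcond)) {
      cols <- which(bcond == k)
      if (length(cols) < 2) next
      pairs <- utils::combn(cols, 2)
      for (j in seq_len(ncol(pairs))) {
        r2 <- c(r2, stats::setNames(
          cor(mb[, pairs[1, j]], mb[, pairs[2, j]])^2,
          paste(colnames(mb)[pairs[, j]], collapse = " vs ")))
      }
    }
  }
  if (length(r2) == 0)
    stop("no ", pair_kind, " replicate pairs in the design")
  structure(list(pair_kind = pair_kind, r2_values = r2,
                 mean_r2 = mean(r2), sd_r2 = stats::sd(r2)),
            class = "repeatability_summary")
}

#' Presence-frequency filter over conditions
#'
#' Keeps proteins detected (aPSM > 0) in at least `min_conditions` of the
#' condition columns — the usual guard against one-off identifications.
#'
#' @param apsm condition-level [count_matrix].
#' @param min_conditions minimum number of conditions with evidence.
#' @return character vector of retained protein ids.
#' @export
frequency_filter <- function(apsm, min_conditions = 2L) {
  if (column_kind(apsm) != "condition")
    stop("frequency_filter expects a condition-level aPSM matrix")
  rownames(apsm)[rowSums(unclass(apsm) > 0) >= min_conditions]
}

#' Percentage of a query set found in a reference set
#'
#' Used to score identified proteins/genes against a user-supplied reference
#' list of known vesicle proteins.
#'
#' @param query character vector (non-empty).
#' @param reference character vector.
#' @return percentage in `[0, 100]`.
#' @export
overlap_percent <- function(query, reference) {
  query <- unique(query)
  if (length(query) == 0) stop("empty query set")
  100 * length(intersect(query, reference)) / length(query)
}
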