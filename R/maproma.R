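#' MAProMa differential indexes DAve and DCI
#'
#' For a protein with average spectral counts `X` and `Y` in two compared
#' samples, the Differential Average is `DAve = (X - Y)/(X + Y)/0.5 =
#' 2(X - Y)/(X + Y)`, a fold-change-like index bounded in `[-2, 2]`, and the
#' Differential Confidence Index is `DCI = (X + Y)(X - Y)/2`, an
#' abundance-weighted difference that guards calls on low-count proteins.
#' Both are 0 when `X = Y = 0` (absence in both samples is no evidence).
#'
#' @param x,y non-negative aPSM values (vectorized).
#' @return numeric vector.
#' @examples
#' dave(3, 1) # 1
#' dci(4, 0)  # 8
#' @export
dave <- function(x, y) {
  check_nonneg(x, y)
  s <- x + y
  out <- numeric(length(s))
  nz <- s > 0
  out[nz] <- 2 * (x[nz] - y[nz]) / s[nz]
  out
}

#' @rdname dave
#' @export
dci <- function(x, y) {
  check_nonneg(x, y)
  (x + y) * (x - y) / 2
}

check_nonneg <- function(x, y) {
  if (any(x < 0) || any(y < 0)) stop("aPSM values must be non-negative")
  if (length(x) != length(y)) stop("x and y must have equal length")
  invisible(TRUE)
}

#' Specification of one pairwise condition comparison
#'
#' @param name comparison label.
#' @param x_condition,y_condition condition column ids; positive DAve means
#'   up in `x_condition`.
#' @param dave_threshold,dci_threshold joint DEP-calling thresholds on
#'   `|DAve|` and `|DCI|` (defaults 0.2 and 2).
#' @return list of class `comparison_spec`.
#' @export
comparison_spec <- function(name, x_condition, y_condition,
                            dave_threshold = 0.2, dci_threshold = 2.0) {
  stopifnot(dave_threshold > 0, dci_threshold > 0,
            !identical(x_condition, y_condition))
  structure(list(name = name, x_condition = x_condition,
                 y_condition = y_condition,
                 dave_threshold = dave_threshold,
                 dci_threshold = dci_threshold),
            class = "comparison_spec")
}

#' Call differentially expressed proteins for one comparison
#'
#' One row per protein present (aPSM > 0) in either compared condition; a
#' protein is a DEP iff `|DAve| >= dave_threshold` and `|DCI| >=
#' dci_threshold` jointly. Direction follows the sign of DAve.
#'
#' @param apsm condition-level [count_matrix].
#' @param spec a [comparison_spec()].
#' @return `data.frame` with columns `protein, x_apsm, y_apsm, dave, dci,
#'   is_dep, direction` plus attribute `comparison` (the spec name).
#' @export
compare_conditions <- function(apsm, spec) {
  stopifnot(inherits(spec, "comparison_spec"))
  missing <- setdiff(c(spec$x_condition, spec$y_condition), colnames(apsm))
  if (length(missing) > 0)
    stop("condition column(s) not in matrix: ", paste(missing, collapse = ", "))
  x <- unclass(apsm)[, spec$x_condition]
  y <- unclass(apsm)[, spec$y_condition]
  present <- x > 0 | y > 0
  x <- x[present]; y <- y[present]
  dv <- dave(x, y)
  dc <- dci(x, y)
  out <- data.frame(
    protein = rownames(apsm)[present],
    x_apsm = x, y_apsm = y, dave = dv, dci = dc,
    is_dep = abs(dv) >= spec$dave_threshold & abs(dc) >= spec$dci_threshold,
    direction = ifelse(dv > 0, "up_in_X", ifelse(dv < 0, "up_in_Y", "none")),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "comparison") <- spec$name
  out
}

#' Proteins with a common differential trend across comparisons
#'
#' Mines a family of pairwise comparisons for proteins that are DEPs with the
#' same direction in at least `min_support` of them; the default demands all
#' of them ("always up/down").
#'
#' @param comparisons list of DEP-call tables from [compare_conditions()].
#' @param min_support minimum number of supporting comparisons.
#' @return list with character vectors `up_in_X` and `up_in_Y`.
#' @export
common_trend <- function(comparisons, min_support = length(comparisons)) {
  if (length(comparisons) < 2) stop("need at least two comparisons")
  stopifnot(min_support >= 1, min_support <= length(comparisons))
  support <- function(dir) {
    votes <- unlist(lapply(comparisons, function(cc)
      cc$protein[cc$is_dep & cc$direction == dir]))
    names(which(table(votes) >= min_support))
  }
  list(up_in_X = sort(support("up_in_X")), up_in_Y = sort(support("up_in_Y")))
}

#' The standard comparison families of the two-arm dose/time design
#'
#' Enumerates (i) the six BPA+ vs BPA- comparisons at matched dose and
#' harvest time (X = BPA+), and (ii) within the BPA+ arm, the four dose
#' contrasts 11.3 Gy vs 0 Gy and 11.3 Gy vs 1.9 Gy at each harvest time
#' (X = higher dose). For non-default designs, every matched pair found is
#' emitted and unmatched cells are reported in a warning.
#'
#' @param design run design.
#' @param dave_threshold,dci_threshold thresholds copied into each spec.
#' @return list of [comparison_spec()] objects (10 for the default design).
#' @export
comparison_family <- function(design, dave_threshold = 0.2, dci_threshold = 2.0) {
  validate_design(design)
  cells <- unique(data.frame(bpa = design$bpa, dose_gy = design$dose_gy,
                             harvest_h = design$harvest_h,
                             cond = condition_id(design),
                             stringsAsFactors = FALSE))
  specs <- list()
  unmatched <- character(0)
  # family 1: BPA+ vs BPA- at matched (dose, harvest)
  plus <- cells[cells$bpa == "plus", ]
  for (i in seq_len(nrow(plus))) {
    m <- cells$bpa == "minus" & cells$dose_gy == plus$dose_gy[i] &
      cells$harvest_h == plus$harvest_h[i]
    if (!any(m)) { unmatched <- c(unmatched, plus$cond[i]); next }
    nm <- sprintf("BPA+_vs_BPA-_%sGy_%sh", plus$dose_gy[i], plus$harvest_h[i])
    specs[[nm]] <- comparison_spec(nm, plus$cond[i], cells$cond[m][1],
                                   dave_threshold, dci_threshold)
  }
  # family 2: within BPA+, high dose vs lower doses at each harvest time
  doses <- sort(unique(plus$dose_gy))
  if (length(doses) >= 2) {
    hi <- max(doses)
    for (h in sort(unique(plus$harvest_h))) {
      xi <- plus$cond[plus$dose_gy == hi & plus$harvest_h == h]
      if (length(xi) == 0) next
      for (lo in setdiff(doses, hi)) {
        yi <- plus$cond[plus$dose_gy == lo & plus$harvest_h == h]
        if (length(yi) == 0) { unmatched <- c(unmatched, sprintf("BPA+ %sGy %sh", lo, h)); next }
        nm <- sprintf("%sGy_vs_%sGy_BPA+_%sh", hi, lo, h)
        specs[[nm]] <- comparison_spec(nm, xi[1], yi[1],
                                       dave_threshold, dci_threshold)
      }
    }
  }
  if (length(unmatched) > 0)
    warning("unmatched design cells: ", paste(unmatched, collapse = ", "))
  if (length(specs) == 0) stop("no comparable condition pairs in design")
  specs
}
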