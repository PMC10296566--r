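#' Full-factorial run design of a two-arm boron/neutron-dose EV experiment
#'
#' Builds the run-to-condition mapping of the study layout this package
#' targets: two treatment arms (with/without the boron carrier BPA), three
#' neutron irradiation doses (0, 1.9 and 11.3 Gy, delivered over 0, 10 and
#' 60 min), two EV harvest times (6 and 24 h post irradiation), each measured
#' in biological replicates that are run in technical duplicate on the
#' instrument. The default gives 12 conditions x 3 bioreps x 2 tech runs =
#' 72 runs.
#'
#' @param bioreps number of biological replicates per condition.
#' @param techreps number of technical (instrument) replicates per biorep.
#' @return A `data.frame` with columns `run_id`, `bpa` (`"minus"`/`"plus"`),
#'   `dose_gy`, `irradiation_min`, `harvest_h`, `biorep`, `techrep`.
#' @examples
#' d <- bnct_design()
#' nrow(d)                      # 72
#' length(unique(condition_id(d)))  # 12
#' @export
bnct_design <- function(bioreps = 3, techreps = 2) {
  stopifnot(bioreps >= 1, techreps >= 1)
  doses <- data.frame(dose_gy = c(0, 1.9, 11.3), irradiation_min = c(0, 10, 60))
  g <- expand.grid(
    techrep = seq_len(techreps), biorep = seq_len(bioreps),
    harvest_h = c(6, 24), dose_i = seq_len(nrow(doses)),
    bpa = c("minus", "plus"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  d <- data.frame(
    bpa = g$bpa,
    dose_gy = doses$dose_gy[g$dose_i],
    irradiation_min = doses$irradiation_min[g$dose_i],
    harvest_h = g$harvest_h,
    biorep = g$biorep,
    techrep = g$techrep,
    stringsAsFactors = FALSE
  )
  d$run_id <- sprintf(
    "%s_d%s_h%d_b%d_t%d",
    ifelse(d$bpa == "plus", "BPApos", "BPAneg"),
    d$dose_gy, d$harvest_h, d$biorep, d$techrep
  )
  validate_design(d)
  d[, c("run_id", "bpa", "dose_gy", "irradiation_min", "harvest_h",
        "biorep", "techrep")]
}

#' Condition label of each design row
#'
#' One condition is one cell of the (BPA arm, dose, harvest time) factorial;
#' replicate runs of a cell share its label.
#'
#' @param design a design `data.frame` as from [bnct_design()].
#' @return character vector, one label per row, e.g. `"BPA+_11.3Gy_24h"`.
#' @export
condition_id <- function(design) {
  validate_design(design)
  sprintf("BPA%s_%sGy_%sh",
          ifelse(design$bpa == "plus", "+", "-"),
          design$dose_gy, design$harvest_h)
}

#' Validate a run design table
#'
#' @param design candidate design `data.frame`.
#' @return the design, invisibly; errors describe the first violation found.
#' @export
validate_design <- function(design) {
  req <- c("run_id", "bpa", "dose_gy", "irradiation_min", "harvest_h",
           "biorep", "techrep")
  miss <- setdiff(req, names(design))
  if (length(miss) > 0)
    stop("design is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(design) == 0) stop("design has no runs")
  if (anyDuplicated(design$run_id))
    stop("duplicate run ids in design: ",
         paste(unique(design$run_id[duplicated(design$run_id)]), collapse = ", "))
  if (!all(design$bpa %in% c("minus", "plus")))
    stop("design$bpa must be 'minus' or 'plus'")
  if (any(design$dose_gy < 0) || any(design$irradiation_min < 0))
    stop("dose_gy and irradiation_min must be non-negative")
  if (any(design$harvest_h <= 0)) stop("harvest_h must be positive")
  invisible(design)
}

#' Read / write a design table as TSV
#'
#' @param path file path.
#' @return `read_design()` returns a validated design `data.frame`.
#' @export
read_design <- function(path) {
  d <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  validate_design(d)
  d
}

#' @rdname read_design
#' @param design design table to write.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  data.table::fwrite(design, path, sep = "\t")
  invisible(path)
}
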