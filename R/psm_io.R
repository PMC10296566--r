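#' @section PSM tables:
#' A PSM table is one row per identified spectrum, tab separated, with header
#' `run_id protein_accession species gene_symbol peptide met_oxidized
#' tyr_nitrosylated`. `species` is one of `human`, `bovine`, `other` (or
#' empty when it is to be assigned from FASTA files). Peptides are uppercase
#' amino-acid strings of at least six residues; a modification flag may only
#' be set when the peptide contains the residue.
#' @name psm-tables
NULL

PSM_COLUMNS <- c("run_id", "protein_accession", "species", "gene_symbol",
                 "peptide", "met_oxidized", "tyr_nitrosylated")
SPECIES_LEVELS <- c("human", "bovine", "other")

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Validate PSM records
#'
#' Checks the column contract, peptide length (minimum six residues, mirroring
#' the identification filter applied upstream of this pipeline) and the
#' consistency of modification flags with peptide composition. Adds the
#' derived columns `has_met` / `has_tyr` when absent.
#'
#' @param records a `data.frame`/`data.table` of PSM rows.
#' @param allow_empty_species if `TRUE`, empty species tokens pass (they must
#'   then be assigned via [map_species_from_fasta()]).
#' @return a validated `data.table` with derived residue-content columns.
#' @export
validate_psm_records <- function(records, allow_empty_species = FALSE) {
  rec <- data.table::as.data.table(records)
  miss <- setdiff(PSM_COLUMNS, names(rec))
  if (length(miss) > 0)
    stop("PSM table missing column(s): ", paste(miss, collapse = ", "))
  rec[, met_oxidized := as_flag(met_oxidized)]
  rec[, tyr_nitrosylated := as_flag(tyr_nitrosylated)]
  rec[, peptide := toupper(as.character(peptide))]
  bad_pep <- which(nchar(rec$peptide) < 6L)
  if (length(bad_pep) > 0)
    stop("peptide shorter than 6 residues at line(s): ",
         paste(head(bad_pep, 5), collapse = ", "))
  if (!grepl_all_aa(rec$peptide))
    stop("peptide contains non amino-acid characters")
  rec[, has_met := grepl("M", peptide, fixed = TRUE)]
  rec[, has_tyr := grepl("Y", peptide, fixed = TRUE)]
  bad_m <- which(rec$met_oxidized & !rec$has_met)
  if (length(bad_m) > 0)
    stop("met_oxidized set but peptide lacks M at line(s): ",
         paste(head(bad_m, 5), collapse = ", "))
  bad_y <- which(rec$tyr_nitrosylated & !rec$has_tyr)
  if (length(bad_y) > 0)
    stop("tyr_nitrosylated set but peptide lacks Y at line(s): ",
         paste(head(bad_y, 5), collapse = ", "))
  ok_species <- rec$species %in% SPECIES_LEVELS |
    (allow_empty_species & (is.na(rec$species) | rec$species == ""))
  if (!all(ok_species)) {
    off <- unique(rec$protein_accession[!ok_species])
    stop("unknown species token for accession(s): ",
         paste(head(off, 5), collapse = ", "))
  }
  rec[]
}

grepl_all_aa <- function(x) !any(grepl("[^ACDEFGHIKLMNPQRSTVWY]", x))

#' Read / write a PSM table (one row per spectrum)
#'
#' @param path TSV file path.
#' @param allow_empty_species passed to [validate_psm_records()].
#' @return `read_psm_table()` returns a validated `data.table` of records.
#' @export
read_psm_table <- function(path, allow_empty_species = FALSE) {
  rec <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = 1:5))
  validate_psm_records(rec, allow_empty_species = allow_empty_species)
}

#' @rdname read_psm_table
#' @param records PSM records to write; derived columns are dropped.
#' @export
write_psm_table <- function(records, path) {
  rec <- validate_psm_records(records, allow_empty_species = TRUE)
  data.table::fwrite(rec[, PSM_COLUMNS, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' Keep records of one species, dropping contaminant identifications
#'
#' EV preparations from serum-conditioned media are dominated by bovine serum
#' proteins (chiefly albumin); quantification proceeds on the human
#' identifications only. The number of removed rows is reported as a message
#' and attached as attribute `n_removed`.
#'
#' @param records validated PSM records.
#' @param keep species to keep (default `"human"`).
#' @return the kept records, with attribute `n_removed`.
#' @export
filter_species <- function(records, keep = "human") {
  keep <- match.arg(keep, SPECIES_LEVELS)
  rec <- validate_psm_records(records)
  out <- rec[species == keep]
  n_removed <- nrow(rec) - nrow(out)
  message(sprintf("filter_species: kept %d %s PSMs, removed %d",
                  nrow(out), keep, n_removed))
  if (nrow(out) == 0)
    warning("no records left after species filtering")
  data.table::setattr(out, "n_removed", n_removed)
  out
}

#' Assign species from a pair (or more) of FASTA databases
#'
#' Every accession must occur in exactly one of the supplied FASTA files;
#' shared accessions are an upstream protein-grouping problem this pipeline
#' refuses to guess about.
#'
#' @param records PSM records (species column may be empty).
#' @param fasta_paths named character vector, names are species labels
#'   (`human`, `bovine`, ...), values FASTA paths. The accession is the first
#'   whitespace-delimited token of each header.
#' @return records with `species` filled in.
#' @export
map_species_from_fasta <- function(records, fasta_paths) {
  if (is.null(names(fasta_paths)) || any(names(fasta_paths) == ""))
    stop("fasta_paths must be named by species label")
  rec <- validate_psm_records(records, allow_empty_species = TRUE)
  maps <- lapply(names(fasta_paths), function(sp) {
    seqs <- Biostrings::readAAStringSet(fasta_paths[[sp]])
    acc <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
    data.table::data.table(protein_accession = acc, species_new = sp)
  })
  map <- data.table::rbindlist(maps)
  dup <- map$protein_accession[duplicated(map$protein_accession)]
  hit <- map[match(rec$protein_accession, map$protein_accession)]
  ambiguous <- unique(rec$protein_accession[rec$protein_accession %in% dup])
  absent <- unique(rec$protein_accession[is.na(hit$species_new)])
  if (length(ambiguous) > 0)
    stop("accession(s) in more than one FASTA: ",
         paste(head(ambiguous, 5), collapse = ", "))
  if (length(absent) > 0)
    stop("accession(s) in no FASTA: ", paste(head(absent, 5), collapse = ", "))
  rec[, species := hit$species_new]
  validate_psm_records(rec)
}

#' Aggregate PSM records into a protein x run count matrix
#'
#' @param records validated PSM records.
#' @param design the run design; every run in `records` must be listed, and
#'   design runs without records yield all-zero columns.
#' @return a [count_matrix] with `column_kind = "run"`, columns in design
#'   order, rows sorted by accession; protein species kept in attribute
#'   `species`.
#' @export
aggregate_counts <- function(records, design) {
  validate_design(design)
  rec <- validate_psm_records(records)
  stray <- setdiff(unique(rec$run_id), design$run_id)
  if (length(stray) > 0)
    stop("run(s) in records but not in design: ",
         paste(head(stray, 5), collapse = ", "))
  tab <- rec[, .N, by = .(protein_accession, run_id)]
  prots <- sort(unique(rec$protein_accession))
  m <- matrix(0, nrow = length(prots), ncol = nrow(design),
              dimnames = list(prots, design$run_id))
  m[cbind(match(tab$protein_accession, prots), match(tab$run_id, design$run_id))] <- tab$N
  sp <- rec[, species[1L], by = protein_accession]
  species <- stats::setNames(sp$V1, sp$protein_accession)[prots]
  count_matrix(m, kind = "run", species = species)
}

#' Protein x column count matrix
#'
#' A plain numeric matrix (proteins in rows) carrying a `column_kind`
#' attribute that records whether columns are individual runs or averaged
#' conditions, and optionally a per-protein `species` annotation.
#'
#' @param m numeric matrix with row and column names.
#' @param kind `"run"` or `"condition"`.
#' @param species optional named character vector of per-protein species.
#' @return the matrix with class `count_matrix`.
#' @export
count_matrix <- function(m, kind = c("run", "condition"), species = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(m), is.numeric(m))
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("count matrix needs protein row names and column names")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("duplicate protein or column ids")
  if (any(m < 0)) stop("counts must be non-negative")
  attr(m, "column_kind") <- kind
  attr(m, "species") <- species
  class(m) <- c("count_matrix", class(m))
  m
}

#' @rdname count_matrix
#' @param x a `count_matrix`.
#' @export
column_kind <- function(x) attr(x, "column_kind") %||% "run"

#' Read / write a count matrix as TSV (first column = protein id)
#'
#' @param path TSV file path.
#' @param kind column kind recorded on the matrix read back.
#' @return `read_count_matrix()` returns a [count_matrix].
#' @export
read_count_matrix <- function(path, kind = c("run", "condition")) {
  kind <- match.arg(kind)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt[[1]]
  count_matrix(m, kind = kind)
}

#' @rdname read_count_matrix
#' @param m matrix to write.
#' @export
write_count_matrix <- function(m, path) {
  dt <- data.table::data.table(protein = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(unclass(m)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
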