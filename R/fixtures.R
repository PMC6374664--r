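#' Packaged study tables
#'
#' The package ships three plain-text tables from the motivating field
#' study of the upper Black River (MI) predator community, for use as
#' mid-pipeline inputs and reproduction checks:
#' \describe{
#'   \item{`mock_homogenate_table()`}{mean biomass and sequence
#'     percentages for the 11 (merged) families of the mock tissue
#'     homogenate, with the published RCF column (`rcf_printed`).}
#'   \item{`drift_biomass_table()`}{nightly estimated catch biomass (g)
#'     per drift-net family over 5 drift and 2 postdrift nights, with
#'     individual dry masses and family-to-ESU groupings.}
#'   \item{`overlap_pairs_table()`}{Schoener overlap for all 78 predator
#'     species pairs in each period (three-letter species codes).}
#' }
#'
#' @return a data.frame (see details per function).
#' @name study_tables
NULL

#' @rdname study_tables
#' @export
mock_homogenate_table <- function() {
  utils::read.delim(system.file("extdata", "mock_homogenate.tsv",
                                package = "driftdiet"),
                    stringsAsFactors = FALSE)
}

#' @rdname study_tables
#' @export
drift_biomass_table <- function() {
  read_drift_survey(system.file("extdata", "drift_survey_biomass.tsv",
                                package = "driftdiet"), mode = "grams")
}

#' @rdname study_tables
#' @export
overlap_pairs_table <- function() {
  utils::read.delim(system.file("extdata", "schoener_overlap_pairs.tsv",
                                package = "driftdiet"),
                    stringsAsFactors = FALSE)
}

#' Read a reference database from FASTA + taxonomy TSV
#'
#' @param fasta path to the reference FASTA (record ids = `ref_id`).
#' @param taxonomy_tsv TSV with columns `ref_id`, `esu`,
#'   `is_bilaterian`, `self_of_species` (empty/NA for non-predator
#'   ESUs), and optionally `family`.
#' @return a `reference_db` usable by [assign_esu()].
#' @export
read_reference_db <- function(fasta, taxonomy_tsv) {
  seqs <- read_fasta(fasta)
  tax <- utils::read.delim(taxonomy_tsv, stringsAsFactors = FALSE)
  need <- c("ref_id", "esu", "is_bilaterian")
  miss <- setdiff(need, names(tax))
  if (length(miss) > 0) {
    stop("taxonomy is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"self_of_species" %in% names(tax)) tax$self_of_species <- NA_character_
  tax$self_of_species[tax$self_of_species == ""] <- NA_character_
  if (!all(names(seqs) %in% tax$ref_id)) {
    stop("FASTA records missing from taxonomy: ",
         paste(setdiff(names(seqs), tax$ref_id), collapse = ", "),
         call. = FALSE)
  }
  tax <- tax[match(names(seqs), tax$ref_id), ]
  esus <- unique(tax[, c("esu", "is_bilaterian", "self_of_species"),
                     drop = FALSE])
  esus$family <- if ("family" %in% names(tax)) {
    tax$family[match(esus$esu, tax$esu)]
  } else esus$esu
  structure(list(sequences = seqs,
                 refs = tax[, c("ref_id", "esu")],
                 esus = esus[, c("esu", "family", "is_bilaterian",
                                 "self_of_species")]),
            class = "reference_db")
}
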