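## Packaged reference tables: the ITS type definitions, the mixed-template
## calibration summary, and the 46-specimen survey panel.  All ship as TSV
## under inst/extdata and are read on demand.

.extdata <- function(name) {
  path <- system.file("extdata", name, package = "itshybrid")
  if (path == "") stop("packaged file not found: ", name, call. = FALSE)
  path
}

#' ITS type definitions
#'
#' The 13 ITS types: 4 homozygous pure lines (P0, PM0, T0, S0, with GenBank
#' accessions) and 9 heterozygous cultivar types.  Columns `b122`..`b500`
#' give the allele (possibly an IUPAC code) at each variable position;
#' `m122`..`m500` give the major (taller-peak) base at heterozygous sites
#' where the definition specifies an orientation, else `NA`.
#'
#' @return `data.frame`, one row per type.
#' @examples
#' its_type_defs()[, c("label", "species", "b122", "b226")]
#' @export
its_type_defs <- function() {
  utils::read.delim(.extdata("its_types.tsv"), stringsAsFactors = FALSE,
                    quote = "", colClasses = "character")
}

#' Pure-line (homozygous) type definitions
#'
#' @return Subset of [its_type_defs()] with only homozygous genotypes.
#' @export
pure_line_defs <- function() {
  defs <- its_type_defs()
  amb <- setdiff(names(.IUPAC_SETS), c("A", "C", "G", "T"))
  hom <- !apply(defs[, c("b122", "b135", "b226", "b500")], 1L,
                function(x) any(x %in% amb))
  defs[hom, , drop = FALSE]
}

#' Published calibration series summary
#'
#' Per-fraction mean +/- SD of the S-value at the heterozygous site and the
#' N-value of nearby noise (5 sequencing replicates per mixture), with the
#' variance-analysis significance flag at p < 0.01.  These moments are what
#' the simulator defaults are fit to.
#'
#' @return `data.frame`, one row per mixing fraction (percent scale).
#' @export
calibration_reference <- function() {
  utils::read.delim(.extdata("calibration_series.tsv"),
                    stringsAsFactors = FALSE, quote = "")
}

#' The 46-specimen survey panel
#'
#' Voucher, species, assigned ITS type, per-site hybrid-ratio mean +/- SD
#' (percent, 3 sequencing replicates), locality, altitude and collection
#' date for the 46 cultivated Codonopsis specimens.  The `its_type` column
#' is canonical (its per-type counts match the type-definition table);
#' `its_type_metadata` preserves the alternative assignment printed with the
#' collection metadata, which disagrees for vouchers CP34, CP37, CP38 and
#' CPM42-CPM45.
#'
#' @return `data.frame` of class `specimen_panel`, 46 rows.
#' @examples
#' panel <- build_specimen_panel()
#' nrow(panel)  # 46
#' @export
build_specimen_panel <- function() {
  panel <- utils::read.delim(
    .extdata("specimen_panel.tsv"), stringsAsFactors = FALSE, quote = "",
    colClasses = c(voucher = "character", species = "character",
                   its_type = "character", its_type_metadata = "character",
                   ratio122_mean = "numeric", ratio122_sd = "numeric",
                   ratio226_mean = "numeric", ratio226_sd = "numeric",
                   locality = "character", locality_no = "integer",
                   altitude_m = "numeric", date_collected = "character"))
  class(panel) <- c("specimen_panel", "data.frame")
  panel
}

#' Vouchers whose two packaged type assignments disagree
#'
#' @param panel A panel from [build_specimen_panel()].
#' @return Character vector of voucher ids.
#' @export
panel_type_discrepancies <- function(panel = build_specimen_panel()) {
  panel$voucher[panel$its_type != panel$its_type_metadata]
}

#' Packaged baseline reference sequence
#'
#' Reads the synthetic P0 reference FASTA shipped with the package (a fixed
#' realization of [make_reference()]).
#'
#' @return Sequence as a single uppercase string.
#' @export
packaged_reference <- function() {
  fa <- seqinr::read.fasta(.extdata("reference_p0_synthetic.fasta"),
                           as.string = TRUE, forceDNAtolower = FALSE)
  toupper(as.character(fa[[1]]))
}
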