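## IUPAC nucleotide code arithmetic shared by the simulator, typing and
## phylogeny code.  Only the ambiguity algebra lives here; sequence I/O goes
## through seqinr.

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Expand an IUPAC nucleotide code to its base set
#'
#' @param code Single IUPAC character (case-insensitive).
#' @return Character vector of plain bases, e.g. `c("C", "T")` for `"Y"`.
#' @examples
#' iupac_bases("Y")
#' @export
iupac_bases <- function(code) {
  code <- toupper(code)
  stopifnot(length(code) == 1L)
  set <- .IUPAC_SETS[[code]]
  if (is.null(set)) {
    stop("not an IUPAC nucleotide code: '", code, "'", call. = FALSE)
  }
  set
}

#' Collapse a set of plain bases to the IUPAC code
#'
#' @param bases Character vector of plain bases (subset of A, C, G, T).
#' @return Single IUPAC character.
#' @examples
#' iupac_code(c("C", "T"))  # "Y"
#' @export
iupac_code <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  if (!all(bases %in% c("A", "C", "G", "T")) || length(bases) == 0L) {
    stop("bases must be a non-empty subset of A, C, G, T", call. = FALSE)
  }
  key <- paste(bases, collapse = "")
  hit <- vapply(.IUPAC_SETS, function(s) paste(sort(s), collapse = "") == key,
                logical(1))
  names(.IUPAC_SETS)[hit][1L]
}

#' Reverse complement of a nucleotide sequence
#'
#' IUPAC ambiguity codes are complemented (Y <-> R, K <-> M, ...).
#'
#' @param seq Sequence as a single character string.
#' @return Reverse-complemented string.
#' @examples
#' reverse_complement("ACYT")  # "ARGT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  v <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(v), names(.IUPAC_COMPLEMENT))
  if (length(bad)) {
    stop("non-IUPAC characters in sequence: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  paste(rev(unname(.IUPAC_COMPLEMENT[v])), collapse = "")
}

## complement of a single base/code
.complement1 <- function(base) unname(.IUPAC_COMPLEMENT[toupper(base)])

## split a sequence string into a character vector
.seq_chars <- function(seq) strsplit(toupper(seq), "")[[1]]

## run code with a temporary RNG state; NULL seed leaves the RNG alone
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

## derive a child seed from a root seed; stays within 32-bit integer range
.derive_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) %% 1e6) * 2011 + i * 97) %% 2147483647L
}

## inverse-CDF truncated normal draws
.rtnorm <- function(n, mean, sd, lower = 0, upper = 1) {
  if (sd <= 0) return(pmin(upper, pmax(lower, rep(mean, n))))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}
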