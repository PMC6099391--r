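#' Assemble forward and reverse reads into a consensus contig
#'
#' Reverse-complements the reverse read, finds the best exact overlap with
#' the forward read (no gaps: the simulator never emits indels), and merges
#' the overlap position by position.  A plain base against its IUPAC
#' superset (C vs Y) resolves to the IUPAC code; disjoint bases (C vs T) are
#' recorded as conflicts and resolved to the union code with a warning.
#'
#' @param fwd_seq Forward read (string, IUPAC alphabet).
#' @param rev_seq Reverse read as sequenced (i.e. reverse-complement
#'   orientation relative to the forward read).
#' @param min_overlap Minimum acceptable overlap in nt (default 50).
#' @return List of class `its_contig`: `sequence`, `conflicts` (data frame
#'   of position, forward base, reverse-implied base), `offset`.
#' @examples
#' ref <- make_reference(seed = 1)
#' ctg <- assemble_contig(ref, reverse_complement(ref))
#' identical(ctg$sequence, as.character(ref))
#' @export
assemble_contig <- function(fwd_seq, rev_seq, min_overlap = 50L) {
  f <- .seq_chars(fwd_seq)
  r <- .seq_chars(reverse_complement(rev_seq))
  nf <- length(f)
  nr <- length(r)

  sets_f <- .IUPAC_SETS[f]
  sets_r <- .IUPAC_SETS[r]
  if (any(vapply(sets_f, is.null, logical(1))) ||
      any(vapply(sets_r, is.null, logical(1)))) {
    stop("non-IUPAC characters in input reads", call. = FALSE)
  }

  ## offset o: r[i] aligns with f[i + o]
  best <- NULL
  for (o in seq(-(nr - min_overlap), nf - min_overlap)) {
    i_r <- max(1L, 1L - o):min(nr, nf - o)
    len <- length(i_r)
    if (len < min_overlap) next
    i_f <- i_r + o
    compat <- mapply(function(a, b) length(intersect(a, b)) > 0L,
                     sets_f[i_f], sets_r[i_r])
    score <- mean(compat)
    cand <- list(offset = o, score = score, len = len,
                 i_f = i_f, i_r = i_r)
    if (is.null(best) || score > best$score ||
        (score == best$score && len > best$len)) {
      best <- cand
    }
  }
  if (is.null(best) || best$score < 0.5) {
    stop("no overlap of at least ", min_overlap,
         " nt between the two reads", call. = FALSE)
  }

  total_start <- min(1L, 1L + best$offset)
  total_end <- max(nf, nr + best$offset)
  cons <- rep(NA_character_, total_end - total_start + 1L)
  shift <- 1L - total_start
  cons[seq_len(nf) + shift] <- f
  cons[seq_len(nr) + best$offset + shift] <- r

  conflicts <- data.frame(pos = integer(0), fwd_base = character(0),
                          rev_base = character(0))
  for (k in seq_along(best$i_f)) {
    pf <- best$i_f[k]
    a <- sets_f[[pf]]
    b <- sets_r[[best$i_r[k]]]
    u <- iupac_code(union(a, b))
    if (length(intersect(a, b)) == 0L) {
      conflicts <- rbind(conflicts,
                         data.frame(pos = pf, fwd_base = f[pf],
                                    rev_base = r[best$i_r[k]]))
    }
    cons[pf + shift] <- u
  }
  if (nrow(conflicts)) {
    warning("strand conflict at position",
            if (nrow(conflicts) > 1L) "s " else " ",
            paste(conflicts$pos, collapse = ", "),
            "; resolved to the IUPAC union code", call. = FALSE)
  }
  structure(list(sequence = paste(cons, collapse = ""),
                 conflicts = conflicts, offset = best$offset),
            class = "its_contig")
}

#' Motif-based ITS1 / 5.8S / ITS2 boundary extraction
#'
#' The ITS region runs from the start of `start_motif` through the end of
#' `end_motif`; the 5.8S gene runs from the start of `s58_start_motif`
#' through the end of `s58_end_motif` (all inclusive); ITS1 and ITS2 are the
#' flanks within ITS.  Every motif must occur exactly once and in order.
#' Coordinates are 1-based relative to the first base of `start_motif`, so
#' the variable positions (122, 135, 226, 500) are directly addressable.
#'
#' @param seq Sequence string or an `its_contig`.
#' @param start_motif,end_motif,s58_start_motif,s58_end_motif Boundary
#'   motifs; defaults match [reference_layout()].
#' @return List of class `its_regions`: `its` (trimmed ITS string), `its1`,
#'   `s58`, `its2` (region strings), and `table` (region, start, end,
#'   length, gc_percent).
#' @examples
#' reg <- extract_regions(packaged_reference())
#' reg$table$length  # 257 163 235
#' @export
extract_regions <- function(seq, start_motif = "TCGAA",
                            end_motif = "TCCGACC",
                            s58_start_motif = "AAACGACTCT",
                            s58_end_motif = "CGTCACGC") {
  if (inherits(seq, "its_contig")) seq <- seq$sequence
  seq <- toupper(as.character(seq))

  find_once <- function(motif) {
    hits <- gregexpr(motif, seq, fixed = TRUE)[[1]]
    if (hits[1L] == -1L) stop("motif not found: '", motif, "'",
                              call. = FALSE)
    if (length(hits) > 1L) stop("motif occurs more than once: '", motif,
                                "'", call. = FALSE)
    as.integer(hits[1L])
  }

  its_start <- find_once(start_motif)
  its_end <- find_once(end_motif) + nchar(end_motif) - 1L
  s58_start <- find_once(s58_start_motif)
  s58_end <- find_once(s58_end_motif) + nchar(s58_end_motif) - 1L
  if (!(its_start < s58_start && s58_start < s58_end && s58_end < its_end)) {
    stop("boundary motifs out of order", call. = FALSE)
  }

  its <- substring(seq, its_start, its_end)
  s58_s <- s58_start - its_start + 1L   # relative to ITS start
  s58_e <- s58_end - its_start + 1L
  L <- nchar(its)
  if (s58_s <= 1L || s58_e >= L) {
    stop("5.8S boundaries leave an empty ITS1 or ITS2 flank", call. = FALSE)
  }
  its1 <- substring(its, 1L, s58_s - 1L)
  s58 <- substring(its, s58_s, s58_e)
  its2 <- substring(its, s58_e + 1L, L)
  tab <- data.frame(
    region = c("ITS1", "5.8S", "ITS2", "ITS"),
    start = c(1L, s58_s, s58_e + 1L, 1L),
    end = c(s58_s - 1L, s58_e, L, L),
    length = c(nchar(its1), nchar(s58), nchar(its2), L),
    gc_percent = c(gc_content(its1), gc_content(s58), gc_content(its2),
                   gc_content(its)))
  structure(list(its = its, its1 = its1, s58 = s58, its2 = its2,
                 table = tab),
            class = "its_regions")
}

#' G+C content of a sequence
#'
#' `100 * (#G + #C) / length`, rounded to 2 decimals.  IUPAC ambiguity
#' codes count as neither G nor C: this is the unique simple convention
#' that reproduces every packaged type GC value from the 397/655 baseline
#' (e.g. a type with three non-GC edits gives 394/655 = 60.15).
#'
#' @param seq Sequence string over the IUPAC alphabet.
#' @return Percent, numeric.
#' @examples
#' gc_content("GGCC")  # 100
#' gc_content("GYCA")  # 50: the Y is not counted
#' @export
gc_content <- function(seq) {
  seq <- toupper(as.character(seq))
  if (nchar(seq) == 0L) stop("empty sequence", call. = FALSE)
  v <- .seq_chars(seq)
  round(100 * sum(v %in% c("G", "C")) / length(v), 2L)
}
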