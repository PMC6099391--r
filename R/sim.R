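#' Simulation parameters for synthetic chromatograms
#'
#' Bundles the generator model for replicate secondary-peak (S) and noise (N)
#' statistics.  The expected S at minor-template fraction `f` is
#' `slope_a * f + intercept_b`: the observed secondary peak grows linearly
#' with the mixed-template fraction but is slightly attenuated, which is what
#' the calibration series of sequenced PCR mixtures shows.  The expected
#' N-value is `noise_mean_frac / (1 + noise_mean_frac)` (a noise channel at
#' `noise_mean_frac * amplitude` against a main peak at `amplitude`).
#'
#' @param amplitude Main-peak intensity, arbitrary units (default 1000).
#' @param slope_a Attenuation slope of mean S on fraction (default 0.905).
#' @param intercept_b Baseline S at fraction 0 (default 0.025).
#' @param s_rep_sd Replicate SD of S (default 0.015).
#' @param noise_mean_frac Mean noise intensity as a fraction of `amplitude`
#'   (default 0.11, giving mean N close to 0.099).
#' @param noise_rep_sd Replicate SD of N (default 0.011).
#' @param seed Optional integer root seed threaded through the generators.
#' @return An object of class `sim_params`.
#' @examples
#' p <- sim_params()
#' p$slope_a * 0.5 + p$intercept_b  # expected S for an equimolar mix
#' @export
sim_params <- function(amplitude = 1000, slope_a = 0.905, intercept_b = 0.025,
                       s_rep_sd = 0.015, noise_mean_frac = 0.11,
                       noise_rep_sd = 0.011, seed = NULL) {
  if (!(slope_a > 0 && slope_a <= 1)) {
    stop("slope_a must be in (0, 1]", call. = FALSE)
  }
  if (!(intercept_b >= 0 && intercept_b < 0.1)) {
    stop("intercept_b must be in [0, 0.1)", call. = FALSE)
  }
  if (s_rep_sd < 0 || noise_rep_sd < 0 || noise_mean_frac < 0) {
    stop("SDs and noise_mean_frac must be non-negative", call. = FALSE)
  }
  if (amplitude <= 0) stop("amplitude must be positive", call. = FALSE)
  structure(list(amplitude = amplitude, slope_a = slope_a,
                 intercept_b = intercept_b, s_rep_sd = s_rep_sd,
                 noise_mean_frac = noise_mean_frac,
                 noise_rep_sd = noise_rep_sd,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_params")
}

#' Layout constraints for the synthetic ITS reference
#'
#' Describes the 655-nt ITS1-5.8S-ITS2 reference: region lengths, the four
#' boundary motifs, the total G+C count, and the homozygous baseline alleles
#' at the four variable positions (122, 135, 226, 500).
#'
#' @param its1_len,s58_len,its2_len Region lengths in nt (257, 163, 235).
#' @param start_motif,end_motif ITS boundary motifs (`TCGAA`, `TCCGACC`).
#' @param s58_start_motif,s58_end_motif 5.8S boundary motifs.
#' @param gc_count Total G+C bases in the rendered reference (397, i.e.
#'   60.61\% of 655).
#' @param p0_alleles Named character vector of baseline alleles at the
#'   variable positions.
#' @return An object of class `reference_layout`.
#' @export
reference_layout <- function(its1_len = 257L, s58_len = 163L, its2_len = 235L,
                             start_motif = "TCGAA", end_motif = "TCCGACC",
                             s58_start_motif = "AAACGACTCT",
                             s58_end_motif = "CGTCACGC",
                             gc_count = 397L,
                             p0_alleles = c(`122` = "C", `135` = "G",
                                            `226` = "C", `500` = "G")) {
  total <- its1_len + s58_len + its2_len
  if (its1_len <= 0 || s58_len <= 0 || its2_len <= 0) {
    stop("region lengths must be positive", call. = FALSE)
  }
  for (m in c(start_motif, end_motif, s58_start_motif, s58_end_motif)) {
    if (!grepl("^[ACGT]+$", m)) {
      stop("motifs must be plain ACGT strings", call. = FALSE)
    }
  }
  pos <- as.integer(names(p0_alleles))
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > total)) {
    stop("p0_alleles positions must be 1-based indices within the sequence",
         call. = FALSE)
  }
  structure(list(its1_len = as.integer(its1_len),
                 s58_len = as.integer(s58_len),
                 its2_len = as.integer(its2_len),
                 start_motif = start_motif, end_motif = end_motif,
                 s58_start_motif = s58_start_motif,
                 s58_end_motif = s58_end_motif,
                 gc_count = as.integer(gc_count),
                 p0_alleles = p0_alleles),
            class = "reference_layout")
}

## count (possibly overlapping) occurrences of motif in a character vector
.count_motif <- function(chars, motif) {
  m <- .seq_chars(motif)
  k <- length(m)
  n <- length(chars)
  if (n < k) return(0L)
  hits <- 0L
  for (i in seq_len(n - k + 1L)) {
    if (all(chars[i:(i + k - 1L)] == m)) hits <- hits + 1L
  }
  hits
}

#' Generate the baseline (P0) ITS reference sequence
#'
#' Builds a 655-nt sequence satisfying every layout constraint: boundary
#' motifs placed exactly at the region junctions, baseline alleles at the
#' variable positions, the exact total G+C count, and each motif occurring
#' exactly once.  Filler content outside the constrained positions is random
#' (deterministic for a fixed seed); its biological realism is a non-goal.
#'
#' @param layout A [reference_layout()].
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @return Sequence as a single uppercase string with attribute `layout`.
#' @examples
#' ref <- make_reference(seed = 1)
#' nchar(ref)  # 655
#' @export
make_reference <- function(layout = reference_layout(), seed = 1L) {
  total <- layout$its1_len + layout$s58_len + layout$its2_len
  tmpl <- rep(NA_character_, total)

  place <- function(tmpl, motif, at) {
    m <- .seq_chars(motif)
    idx <- at:(at + length(m) - 1L)
    if (any(idx < 1L) || any(idx > total)) {
      stop("motif '", motif, "' does not fit at position ", at, call. = FALSE)
    }
    clash <- !is.na(tmpl[idx]) & tmpl[idx] != m
    if (any(clash)) {
      stop("layout infeasible: motif '", motif,
           "' conflicts with previously fixed bases at position ",
           idx[clash][1L], call. = FALSE)
    }
    tmpl[idx] <- m
    tmpl
  }

  s58_start <- layout$its1_len + 1L
  s58_end <- layout$its1_len + layout$s58_len
  tmpl <- place(tmpl, layout$start_motif, 1L)
  tmpl <- place(tmpl, layout$end_motif, total - nchar(layout$end_motif) + 1L)
  tmpl <- place(tmpl, layout$s58_start_motif, s58_start)
  tmpl <- place(tmpl, layout$s58_end_motif,
                s58_end - nchar(layout$s58_end_motif) + 1L)
  for (p in names(layout$p0_alleles)) {
    i <- as.integer(p)
    a <- layout$p0_alleles[[p]]
    if (!is.na(tmpl[i]) && tmpl[i] != a) {
      stop("layout infeasible: variable-position allele at ", i,
           " conflicts with a motif base", call. = FALSE)
    }
    tmpl[i] <- a
  }

  fixed_gc <- sum(tmpl %in% c("G", "C"), na.rm = TRUE)
  free <- which(is.na(tmpl))
  need_gc <- layout$gc_count - fixed_gc
  if (need_gc < 0L || need_gc > length(free)) {
    stop("layout infeasible: gc_count ", layout$gc_count,
         " cannot be reached with ", fixed_gc, " fixed G+C bases and ",
         length(free), " free positions", call. = FALSE)
  }

  motifs <- c(layout$start_motif, layout$end_motif,
              layout$s58_start_motif, layout$s58_end_motif)
  .with_seed(seed, {
    for (attempt in seq_len(500L)) {
      out <- tmpl
      gc_pos <- if (need_gc > 0L) sample(free, need_gc) else integer(0)
      out[gc_pos] <- sample(c("G", "C"), need_gc, replace = TRUE)
      at_pos <- setdiff(free, gc_pos)
      out[at_pos] <- sample(c("A", "T"), length(at_pos), replace = TRUE)
      if (all(vapply(motifs, function(m) .count_motif(out, m), integer(1)) ==
              1L)) {
        res <- paste(out, collapse = "")
        attr(res, "layout") <- layout
        return(res)
      }
    }
    stop("could not place random filler without duplicating a boundary motif",
         call. = FALSE)
  })
}

#' Render the ITS sequence of a named ITS type
#'
#' Replaces the four variable positions of the baseline reference with the
#' alleles of the requested ITS type.  Heterozygous sites render as IUPAC
#' codes (Y, R); the major (taller-peak) base of each heterozygous site,
#' where the type definition specifies one, is returned in the `majors`
#' attribute as a named character vector keyed by position.
#'
#' @param type_label One of the 13 ITS type labels (P0, P1..P5, PM0..PM3,
#'   T0, T1, S0).
#' @param reference Baseline sequence from [make_reference()].
#' @return Sequence string with attributes `label`, `species` and `majors`.
#' @examples
#' ref <- make_reference(seed = 1)
#' p1 <- render_type_sequence("P1", ref)
#' substr(p1, 122, 122)  # "Y"
#' @export
render_type_sequence <- function(type_label, reference) {
  defs <- its_type_defs()
  if (!type_label %in% defs$label) {
    stop("unknown ITS type '", type_label, "'; valid labels: ",
         paste(defs$label, collapse = ", "), call. = FALSE)
  }
  row <- defs[defs$label == type_label, ]
  v <- .seq_chars(reference)
  sites <- c(122L, 135L, 226L, 500L)
  alleles <- c(row$b122, row$b135, row$b226, row$b500)
  majors <- c(row$m122, row$m135, row$m226, row$m500)
  v[sites] <- alleles
  out <- paste(v, collapse = "")
  keep <- !is.na(majors)
  attr(out, "label") <- type_label
  attr(out, "species") <- row$species
  attr(out, "majors") <- stats::setNames(majors[keep],
                                         as.character(sites[keep]))
  out
}

#' Simulate replicate (S, N) statistics for a mixed template
#'
#' Moment-level sampler: S replicates are truncated-normal draws around
#' `slope_a * fraction + intercept_b`, N replicates around
#' `noise_mean_frac / (1 + noise_mean_frac)`, both truncated to [0, 1].
#' This sampler is the canonical source for calibration statistics; the full
#' trace renderer ([render_trace()]) exists for pipeline I/O.
#'
#' @param fraction Minor-template fraction in [0, 0.5]; the calibration
#'   design never exceeds an equimolar mix.
#' @param n Number of replicates (>= 2).
#' @param params A [sim_params()].
#' @param seed Optional seed overriding `params$seed`.
#' @return `data.frame` with columns `s` and `n_val`, one row per replicate.
#' @examples
#' simulate_sn_replicates(0.5, 5, sim_params(seed = 1))
#' @export
simulate_sn_replicates <- function(fraction, n, params = sim_params(),
                                   seed = params$seed) {
  if (!is.numeric(fraction) || fraction < 0 || fraction > 0.5) {
    stop("fraction must lie in [0, 0.5]", call. = FALSE)
  }
  if (n < 2) stop("need at least 2 replicates", call. = FALSE)
  mu_s <- params$slope_a * fraction + params$intercept_b
  mu_n <- params$noise_mean_frac / (1 + params$noise_mean_frac)
  .with_seed(seed, {
    data.frame(s = .rtnorm(n, mu_s, params$s_rep_sd),
               n_val = .rtnorm(n, mu_n, params$noise_rep_sd))
  })
}

#' Render a full four-channel chromatogram trace
#'
#' Produces per-position A/C/G/T channel intensities for a sequence: the
#' called-base channel sits at `amplitude`, every other channel is noise
#' around `noise_mean_frac * amplitude`, and at each heterozygous site the
#' minor-base channel encodes an S-value drawn from the generator model
#' (truncated to [0, 0.5] so the called base stays the tallest peak).  On the
#' reverse strand the sequence is reverse-complemented and the heterozygous
#' sites are mirrored (position `p -> L - p + 1`, bases complemented).
#'
#' @param sequence Plain-base sequence string.
#' @param het_sites `NULL`, or `data.frame` with columns `pos`, `minor`,
#'   `fraction` describing the heterozygous sites.
#' @param params A [sim_params()].
#' @param strand `"forward"` or `"reverse"`.
#' @param seed Optional seed overriding `params$seed`.
#' @return A `sanger_trace` object (see [as_sanger_trace()]).
#' @examples
#' ref <- make_reference(seed = 1)
#' tr <- render_trace(ref, data.frame(pos = 122, minor = "T", fraction = 0.3),
#'                    sim_params(seed = 7))
#' @export
render_trace <- function(sequence, het_sites = NULL, params = sim_params(),
                         strand = c("forward", "reverse"),
                         seed = params$seed) {
  strand <- match.arg(strand)
  v <- .seq_chars(sequence)
  L <- length(v)
  if (!all(v %in% c("A", "C", "G", "T"))) {
    stop("render_trace needs a plain ACGT sequence; represent heterozygous ",
         "sites through het_sites", call. = FALSE)
  }
  if (!is.null(het_sites)) {
    stopifnot(all(c("pos", "minor", "fraction") %in% names(het_sites)))
    if (any(het_sites$pos < 1L | het_sites$pos > L)) {
      stop("het_sites positions outside the sequence", call. = FALSE)
    }
    if (any(het_sites$fraction < 0 | het_sites$fraction > 0.5)) {
      stop("het_sites fractions must lie in [0, 0.5]", call. = FALSE)
    }
    if (any(toupper(het_sites$minor) == v[het_sites$pos])) {
      stop("minor base equals the called base at a het site", call. = FALSE)
    }
  }
  if (strand == "reverse") {
    v <- .seq_chars(reverse_complement(sequence))
    if (!is.null(het_sites)) {
      het_sites$pos <- L - het_sites$pos + 1L
      het_sites$minor <- .complement1(het_sites$minor)
    }
  }

  bases <- c("A", "C", "G", "T")
  .with_seed(seed, {
    noise <- matrix(
      .rtnorm(4L * L, params$noise_mean_frac, params$noise_rep_sd,
              lower = 0, upper = 1) * params$amplitude,
      nrow = L, ncol = 4L, dimnames = list(NULL, bases))
    chan <- noise
    chan[cbind(seq_len(L), match(v, bases))] <- params$amplitude
    if (!is.null(het_sites)) {
      for (i in seq_len(nrow(het_sites))) {
        p <- het_sites$pos[i]
        s <- .rtnorm(1L, params$slope_a * het_sites$fraction[i] +
                       params$intercept_b, params$s_rep_sd,
                     lower = 0, upper = 0.5)
        chan[p, toupper(het_sites$minor[i])] <-
          params$amplitude * s / (1 - s)
      }
    }
    call <- bases[apply(chan, 1L, which.max)]  # ties break in A<C<G<T order
    as_sanger_trace(data.frame(pos = seq_len(L), A = chan[, "A"],
                               C = chan[, "C"], G = chan[, "G"],
                               T = chan[, "T"], call = call,
                               strand = strand))
  })
}
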