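## Variable-site genotyping, ITS type assignment, heterozygosity census and
## parental-lineage inference under a gamete model.

.VARIABLE_SITES <- c(122L, 135L, 226L, 500L)

.normalize_species <- function(species_context) {
  x <- trimws(species_context)
  if (tolower(x) %in% c("unidentified", "codonopsis sp.", "codonopsis sp",
                        "c. sp.", "c.sp.")) {
    return("Codonopsis sp.")
  }
  x
}

## allele (possibly IUPAC) of a type def at each variable site
.def_alleles <- function(row) {
  stats::setNames(c(row$b122, row$b135, row$b226, row$b500),
                  as.character(.VARIABLE_SITES))
}

.def_majors <- function(row) {
  stats::setNames(c(row$m122, row$m135, row$m226, row$m500),
                  as.character(.VARIABLE_SITES))
}

## base-set composition of a type def at each variable site
.def_compositions <- function(row) {
  lapply(.def_alleles(row), iupac_bases)
}

#' Genotype the variable sites of an ITS sequence
#'
#' Reads the four canonical variable positions (122, 135, 226, 500) plus
#' any additional position carrying an ambiguity code, and reports each as
#' a site genotype: IUPAC code, base composition, and the major
#' (taller-peak) base where known.  Majors come from the `majors` attribute
#' set by [render_type_sequence()] or from the `majors` argument (e.g.
#' measured peak heights); without trace data they are `NA`.
#'
#' @param seq Sequence string over the IUPAC alphabet.
#' @param majors Optional named character vector, position -> major base.
#' @param positions Variable positions always reported.
#' @return `data.frame` with columns `position`, `iupac`, `composition`
#'   (e.g. `"C/T"`), `major`.
#' @examples
#' ref <- make_reference(seed = 1)
#' genotype_variable_sites(render_type_sequence("T1", ref))
#' @export
genotype_variable_sites <- function(seq, majors = NULL,
                                    positions = .VARIABLE_SITES) {
  if (is.null(majors)) majors <- attr(seq, "majors")
  v <- .seq_chars(seq)
  bad <- setdiff(unique(v), names(.IUPAC_SETS))
  if (length(bad)) {
    stop("non-IUPAC characters in sequence: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  amb <- which(!v %in% c("A", "C", "G", "T"))
  pos <- sort(union(as.integer(positions), amb))
  out <- data.frame(
    position = pos,
    iupac = v[pos],
    composition = vapply(v[pos], function(code) {
      paste(iupac_bases(code), collapse = "/")
    }, character(1)),
    major = NA_character_)
  if (!is.null(majors)) {
    hit <- match(as.character(out$position), names(majors))
    out$major <- ifelse(is.na(hit), NA_character_, unname(majors[hit]))
  }
  ## a major base only makes sense at a heterozygous site, and must be one
  ## of the two bases present
  het <- nchar(out$composition) > 1L
  for (i in which(!is.na(out$major))) {
    if (!het[i] || !out$major[i] %in% iupac_bases(out$iupac[i])) {
      stop("major base ", out$major[i], " inconsistent with genotype ",
           out$iupac[i], " at position ", out$position[i], call. = FALSE)
    }
  }
  rownames(out) <- NULL
  out
}

#' Assign the ITS type of a genotyped specimen
#'
#' Matches the four-site genotype against the packaged type definitions:
#' the base composition must agree at every site, the major/minor peak
#' orientation must agree wherever both the definition and the genotype
#' specify one, and the species context must agree (P1 and PM1 share a
#' genotype and are told apart by species only).  Species assignment is
#' morphological and is never inferred from sequence.
#'
#' @param species_context Species name as in [its_type_defs()]
#'   (`"unidentified"` is accepted for Codonopsis sp.).
#' @param genotypes Output of [genotype_variable_sites()].
#' @param defs Type definitions (default [its_type_defs()]).
#' @return Type label; `"novel"` (with a message and a `candidates`
#'   attribute) when no unique definition matches.
#' @export
assign_type <- function(species_context, genotypes, defs = its_type_defs()) {
  ctx <- .normalize_species(species_context)
  gt <- genotypes[match(.VARIABLE_SITES, genotypes$position), ]
  if (any(is.na(gt$position))) {
    stop("genotypes must cover positions ",
         paste(.VARIABLE_SITES, collapse = ", "), call. = FALSE)
  }
  cand <- character(0)
  for (i in seq_len(nrow(defs))) {
    row <- defs[i, ]
    if (row$species != ctx) next
    if (!all(toupper(gt$iupac) == .def_alleles(row))) next
    dm <- .def_majors(row)
    both <- !is.na(dm) & !is.na(gt$major)
    if (any(both) && !all(gt$major[both] == dm[both])) next
    cand <- c(cand, row$label)
  }
  if (length(cand) == 1L) return(cand)
  out <- "novel"
  attr(out, "candidates") <- cand
  message("no unique type definition matches (",
          if (length(cand)) paste(cand, collapse = ", ") else "none",
          "); returning 'novel'")
  out
}

#' Heterozygosity census of a typed specimen panel
#'
#' A specimen is heterozygous when its assigned type carries at least one
#' ambiguity genotype; the remainder are pure lines.
#'
#' @param panel Panel data frame with `voucher`, `species`, `its_type`.
#' @param defs Type definitions.
#' @param exclude Optional vouchers to drop before counting.
#' @return List with `total`, `n_heterozygous`, `n_pure`, and `by_species`
#'   (data frame of per-species counts).
#' @examples
#' census_heterozygosity(build_specimen_panel(), exclude = "CT46")
#' @export
census_heterozygosity <- function(panel, defs = its_type_defs(),
                                  exclude = NULL) {
  het_types <- defs$label[apply(
    defs[, c("b122", "b135", "b226", "b500")], 1L,
    function(x) any(!x %in% c("A", "C", "G", "T")))]
  keep <- !(panel$voucher %in% exclude)
  p <- panel[keep, , drop = FALSE]
  het <- p$its_type %in% het_types
  by_species <- do.call(rbind, lapply(split(het, p$species), function(h) {
    data.frame(n = length(h), n_heterozygous = sum(h), n_pure = sum(!h))
  }))
  by_species <- cbind(species = rownames(by_species), by_species)
  rownames(by_species) <- NULL
  list(total = nrow(p), n_heterozygous = sum(het), n_pure = sum(!het),
       by_species = by_species)
}

## composition list for a target given as label or def row
.target_compositions <- function(target, defs) {
  if (is.character(target) && length(target) == 1L) {
    if (!target %in% defs$label) {
      stop("unknown type label '", target, "'", call. = FALSE)
    }
    .def_compositions(defs[defs$label == target, ])
  } else {
    .def_compositions(target)
  }
}

#' Enumerate pure-line crosses explaining a heterozygous type
#'
#' A pair of homozygous lines explains a target type when, at every
#' variable site, the two parental alleles together equal the target's base
#' composition.  Which parental repeat is the taller peak is not predicted
#' by a cross, so major/minor orientation is ignored.  All unordered pairs,
#' including self-pairs, are tried.
#'
#' @param target Type label or definition row.
#' @param lines Pure-line definitions (default [pure_line_defs()]).
#' @param defs Full type definitions used to resolve `target`.
#' @return `data.frame` with columns `parent_a`, `parent_b`; zero rows when
#'   no pure-line pair explains the type.
#' @examples
#' infer_single_cross("P1")   # P0 x S0
#' infer_single_cross("P2")   # no pair: 0 rows
#' @export
infer_single_cross <- function(target, lines = pure_line_defs(),
                               defs = its_type_defs()) {
  tcomp <- .target_compositions(target, defs)
  labs <- lines$label
  comp <- lapply(seq_len(nrow(lines)), function(i) .def_compositions(lines[i, ]))
  names(comp) <- labs
  out <- data.frame(parent_a = character(0), parent_b = character(0))
  for (i in seq_along(labs)) {
    for (j in i:length(labs)) {
      ok <- all(vapply(names(tcomp), function(site) {
        setequal(union(comp[[i]][[site]], comp[[j]][[site]]), tcomp[[site]])
      }, logical(1)))
      if (ok) {
        out <- rbind(out, data.frame(parent_a = labs[i], parent_b = labs[j]))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Can a cross of two (possibly heterozygous) parents yield a target type?
#'
#' Feasible when at every variable site one gamete from each parent can be
#' chosen so the two together equal the target's base composition.  The
#' witness gamete pair per site is reported.
#'
#' @param parent_a,parent_b,target Type labels or definition rows.
#' @param defs Type definitions.
#' @return List of class `cross_hypothesis`: `parent_a`, `parent_b`,
#'   `target`, `feasible`, `witness` (named per-site gamete pairs, or `NA`
#'   at the first infeasible site).
#' @examples
#' cross_feasible("PM2", "P0", "P1")$feasible  # TRUE
#' @export
cross_feasible <- function(parent_a, parent_b, target,
                           defs = its_type_defs()) {
  lab <- function(x) if (is.character(x)) x else x$label
  ca <- .target_compositions(parent_a, defs)
  cb <- .target_compositions(parent_b, defs)
  ct <- .target_compositions(target, defs)
  witness <- stats::setNames(rep(NA_character_, length(ct)), names(ct))
  feasible <- TRUE
  for (site in names(ct)) {
    found <- FALSE
    for (ga in ca[[site]]) {
      for (gb in cb[[site]]) {
        if (setequal(union(ga, gb), ct[[site]])) {
          witness[site] <- paste0(ga, "+", gb)
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) {
      feasible <- FALSE
      break
    }
  }
  structure(list(parent_a = lab(parent_a), parent_b = lab(parent_b),
                 target = lab(target), feasible = feasible,
                 witness = if (feasible) witness else witness),
            class = "cross_hypothesis")
}

#' Enumerate two-step cross chains explaining a heterozygous type
#'
#' Chains of the form `line x line -> intermediate` (a feasible single
#' cross) followed by `intermediate x line -> target` (gamete-model
#' feasible).  Homozygous targets need no hybridization and return zero
#' rows.
#'
#' @param target Type label or definition row.
#' @param lines Pure-line definitions.
#' @param intermediate_types Candidate intermediate type labels (default:
#'   all heterozygous types).
#' @param defs Type definitions.
#' @return `data.frame` with columns `step1_parent_a`, `step1_parent_b`,
#'   `intermediate`, `step2_parent`, deduplicated.
#' @examples
#' chains <- enumerate_two_step("P1")
#' subset(chains, intermediate == "PM2")
#' @export
enumerate_two_step <- function(target, lines = pure_line_defs(),
                               intermediate_types = NULL,
                               defs = its_type_defs()) {
  tcomp <- .target_compositions(target, defs)
  if (all(lengths(tcomp) == 1L)) {
    return(data.frame(step1_parent_a = character(0),
                      step1_parent_b = character(0),
                      intermediate = character(0),
                      step2_parent = character(0)))
  }
  if (is.null(intermediate_types)) {
    het <- apply(defs[, c("b122", "b135", "b226", "b500")], 1L,
                 function(x) any(!x %in% c("A", "C", "G", "T")))
    intermediate_types <- defs$label[het]
  }
  out <- data.frame(step1_parent_a = character(0),
                    step1_parent_b = character(0),
                    intermediate = character(0),
                    step2_parent = character(0))
  for (im in intermediate_types) {
    first <- infer_single_cross(im, lines, defs)
    if (nrow(first) == 0L) next
    for (second in lines$label) {
      if (!cross_feasible(im, second, target, defs)$feasible) next
      out <- rbind(out, data.frame(step1_parent_a = first$parent_a,
                                   step1_parent_b = first$parent_b,
                                   intermediate = im,
                                   step2_parent = second))
    }
  }
  unique(out)
}

#' Minimal hypothetical pure-line partner explaining a type
#'
#' For a target with no feasible pure-line pair, derives the homozygous
#' genotype an unsampled line would need, given each sampled line as the
#' other parent.  Clearly hypothetical: none of these genotypes were
#' observed.
#'
#' @param target Type label or definition row.
#' @param lines Pure-line definitions.
#' @param defs Type definitions.
#' @return `data.frame` with `known_parent` and the partner's alleles at
#'   the four sites (`NA` row when no homozygous partner works).
#' @export
hypothetical_partner <- function(target, lines = pure_line_defs(),
                                 defs = its_type_defs()) {
  tcomp <- .target_compositions(target, defs)
  rows <- list()
  for (i in seq_len(nrow(lines))) {
    lcomp <- .def_compositions(lines[i, ])
    partner <- stats::setNames(rep(NA_character_, length(tcomp)),
                               names(tcomp))
    ok <- TRUE
    for (site in names(tcomp)) {
      la <- lcomp[[site]][1L]
      need <- tcomp[[site]]
      other <- if (length(need) == 1L) need else setdiff(need, la)
      if (!setequal(union(la, other), need) || length(other) != 1L) {
        ok <- FALSE
        break
      }
      partner[site] <- other
    }
    if (ok) {
      rows[[length(rows) + 1L]] <- data.frame(
        known_parent = lines$label[i], t(partner))
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(known_parent = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
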