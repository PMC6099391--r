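#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run.  Defaults are the study
#' conditions: 5 sequencing replicates per calibration mixture, 3 per
#' specimen, significance at p < 0.01, direct confirmation at mean S >=
#' 0.15, noise window positions 117-127 for site 122, and 1000 bootstrap
#' replicates.
#'
#' @param seed Root seed for every stochastic stage.
#' @param fractions Calibration mixing fractions.
#' @param calibration_n,specimen_n Replicate counts.
#' @param alpha Significance level of the S-vs-N test.
#' @param direct_threshold Mean S confirming additivity directly.
#' @param noise_window Inclusive noise window for the site-122 statistics.
#' @param min_secondary Candidate-site secondary-ratio threshold.
#' @param bootstrap_replicates Bootstrap replicates for the NJ tree.
#' @param outdir Output directory for [run_pipeline()].
#' @param sim Named list of [sim_params()] overrides.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            fractions = c(0.10, 0.15, 0.20, 0.30, 0.40,
                                          0.50),
                            calibration_n = 5L, specimen_n = 3L,
                            alpha = 0.01, direct_threshold = 0.15,
                            noise_window = c(117L, 127L),
                            min_secondary = 0.14,
                            bootstrap_replicates = 1000L,
                            outdir = "itshybrid-output",
                            sim = list()) {
  stopifnot(length(noise_window) == 2L, alpha > 0, alpha < 1,
            direct_threshold > 0, bootstrap_replicates >= 1L)
  structure(list(seed = as.integer(seed), fractions = as.numeric(fractions),
                 calibration_n = as.integer(calibration_n),
                 specimen_n = as.integer(specimen_n),
                 alpha = as.numeric(alpha),
                 direct_threshold = as.numeric(direct_threshold),
                 noise_window = as.integer(noise_window),
                 min_secondary = as.numeric(min_secondary),
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 outdir = as.character(outdir), sim = sim),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' `read_pipeline_config()` rebuilds the object through
#' [pipeline_config()], so a write/read round trip reproduces the
#' configuration exactly.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `path` invisibly / the `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

.resolve_sim_params <- function(config) {
  args <- config$sim
  args$seed <- config$seed
  do.call(sim_params, args)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> calibrate -> type -> census -> ratios -> lineage ->
#' tree -> geography and writes every table (TSV), the 13 type sequences
#' (FASTA), the distance matrix (PHYLIP), the NJ tree (Newick) and a run
#' log into `config$outdir`.  All randomness derives from `config$seed`, so
#' two runs with the same configuration produce byte-identical tables.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every intermediate result and the output
#'   paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE)
    message("created output directory ", config$outdir)
  }
  out_path <- function(name) file.path(config$outdir, name)
  params <- .resolve_sim_params(config)
  log_lines <- c(sprintf("itshybrid %s | R %s.%s",
                         as.character(utils::packageVersion("itshybrid")),
                         R.version$major, R.version$minor),
                 sprintf("seed: %d", config$seed))

  ## reference + 13 rendered type sequences
  reference <- make_reference(seed = config$seed)
  defs <- its_type_defs()
  seqs <- vapply(defs$label,
                 function(l) as.character(render_type_sequence(l, reference)),
                 character(1))
  seqinr::write.fasta(as.list(c(P0_reference = as.character(reference))),
                      names = "P0_reference",
                      file.out = out_path("reference.fasta"))
  seqinr::write.fasta(as.list(seqs), names = names(seqs),
                      file.out = out_path("type_sequences.fasta"))

  ## region extraction on the reference
  regions <- extract_regions(reference)
  .write_tsv(regions$table, out_path("regions.tsv"))

  ## calibration of the detection limit
  calib <- calibration_table(config$fractions, config$calibration_n, params,
                             config$alpha)
  .write_tsv(calib, out_path("calibration.tsv"))

  ## packaged panel: typing round trip, census, hybrid ratios
  panel <- build_specimen_panel()
  disc <- panel_type_discrepancies(panel)
  if (length(disc)) {
    msg <- paste("packaged panel: type assignments differ between the",
                 "ratio table and the collection metadata for",
                 paste(disc, collapse = ", "),
                 "- the ratio table is canonical")
    warning(msg, call. = FALSE)
    log_lines <- c(log_lines, msg)
  }
  assigned <- vapply(seq_len(nrow(panel)), function(i) {
    seq_i <- render_type_sequence(panel$its_type[i], reference)
    assign_type(panel$species[i], genotype_variable_sites(seq_i), defs)
  }, character(1))
  typing <- data.frame(voucher = panel$voucher, species = panel$species,
                       its_type = panel$its_type, assigned_type = assigned,
                       concordant = panel$its_type == assigned)
  .write_tsv(typing, out_path("typing.tsv"))
  census <- census_heterozygosity(panel, defs)

  ratios <- aggregate_ratios_by_type(panel)
  multi <- ratios$its_type[ratios$n > 1L]
  note <- paste("per-type mean hybrid ratios are recomputed from the",
                "per-specimen values; for multi-specimen types",
                paste(sort(unique(multi)), collapse = ", "),
                "previously reported group averages differ from these",
                "arithmetic means and are not reproduced")
  log_lines <- c(log_lines, note)
  .write_tsv(ratios, out_path("hybrid_ratios.tsv"))

  ## lineage hypotheses for every heterozygous type
  het <- defs$label[apply(defs[, c("b122", "b135", "b226", "b500")], 1L,
                          function(x) any(!x %in% c("A", "C", "G", "T")))]
  single <- do.call(rbind, lapply(het, function(ty) {
    cr <- infer_single_cross(ty, defs = defs)
    if (nrow(cr) == 0L) {
      data.frame(its_type = ty, parent_a = NA_character_,
                 parent_b = NA_character_)
    } else {
      data.frame(its_type = ty, cr)
    }
  }))
  .write_tsv(single, out_path("lineage_single_cross.tsv"))
  twostep <- do.call(rbind, lapply(het, function(ty) {
    ch <- enumerate_two_step(ty, defs = defs)
    if (nrow(ch) == 0L) NULL else data.frame(its_type = ty, ch)
  }))
  if (is.null(twostep)) twostep <- data.frame()
  .write_tsv(twostep, out_path("lineage_two_step.tsv"))

  ## phylogeny over the 13 sequences
  dm <- distance_matrix(seqs)
  write_phylip(dm, out_path("distances.phy"))
  tree <- bootstrap_support(seqs, replicates = config$bootstrap_replicates,
                            seed = .derive_seed(config$seed, 7919L))
  ape::write.tree(tree, out_path("tree.nwk"))

  ## geography
  geo <- correlate_geography(panel)
  if (is.data.frame(geo)) .write_tsv(geo, out_path("geography.tsv"))

  writeLines(log_lines, out_path("run_log.txt"))
  invisible(list(config = config, reference = reference, sequences = seqs,
                 regions = regions, calibration = calib, panel = panel,
                 typing = typing, census = census, ratios = ratios,
                 lineage_single = single, lineage_two_step = twostep,
                 distances = dm, tree = tree, geography = geo,
                 outdir = config$outdir))
}

#' Correlation between hybrid ratio and altitude
#'
#' Pearson and Spearman correlations between each specimen's mean hybrid
#' ratio (over the measured sites) and its collection altitude.  The
#' coefficients and p-values are reported as such and never thresholded
#' into a claim; coordinates other than altitude are not in the panel and
#' are not invented.
#'
#' @param panel A [build_specimen_panel()]-style data frame with
#'   `altitude_m` and the per-site ratio means.
#' @return `data.frame` with columns `method`, `estimate`, `p_value`, `n`;
#'   or a list with `computable = FALSE` and a reason when fewer than 3
#'   complete pairs exist or the altitude is constant.
#' @export
correlate_geography <- function(panel) {
  stopifnot(all(c("altitude_m", "ratio122_mean", "ratio226_mean") %in%
                  names(panel)))
  ratio <- rowMeans(panel[, c("ratio122_mean", "ratio226_mean")],
                    na.rm = TRUE)
  ok <- is.finite(ratio) & is.finite(panel$altitude_m)
  x <- panel$altitude_m[ok]
  y <- ratio[ok]
  if (sum(ok) < 3L) {
    return(list(computable = FALSE,
                reason = "fewer than 3 complete (ratio, altitude) pairs"))
  }
  if (stats::sd(x) == 0) {
    return(list(computable = FALSE,
                reason = "altitude is constant; correlation undefined"))
  }
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  data.frame(method = c("pearson", "spearman"),
             estimate = c(unname(pe$estimate), unname(sp$estimate)),
             p_value = c(pe$p.value, sp$p.value),
             n = sum(ok))
}
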