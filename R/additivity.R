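#' Variance analysis between S and N replicates
#'
#' Two-group one-way ANOVA of the S-value replicates against the N-value
#' replicates.  With two groups the F statistic equals the square of the
#' pooled-variance t statistic, so the p-value is identical to a two-sample
#' t-test; `welch = TRUE` switches to the Welch (unequal-variance) form.
#'
#' @param s_reps,n_reps_list Numeric vectors of replicate fractions
#'   (length >= 2 each).
#' @param welch Use the Welch correction instead of the pooled form.
#' @return List with `statistic` (F), `p_value`, and the degrees of freedom.
#' @examples
#' anova_s_vs_n(c(0.15, 0.16, 0.14), c(0.10, 0.11, 0.09))
#' @export
anova_s_vs_n <- function(s_reps, n_reps_list, welch = FALSE) {
  if (length(s_reps) < 2L || length(n_reps_list) < 2L) {
    stop("need at least 2 replicates per group", call. = FALSE)
  }
  y <- c(s_reps, n_reps_list)
  g <- factor(rep(c("S", "N"), c(length(s_reps), length(n_reps_list))))
  if (stats::var(s_reps) == 0 && stats::var(n_reps_list) == 0) {
    # degenerate: no within-group variation
    same <- isTRUE(all.equal(mean(s_reps), mean(n_reps_list)))
    return(list(statistic = if (same) 0 else Inf,
                p_value = if (same) 1 else 0,
                df_num = 1L, df_den = length(y) - 2L))
  }
  fit <- stats::oneway.test(y ~ g, var.equal = !welch)
  list(statistic = unname(fit$statistic), p_value = unname(fit$p.value),
       df_num = unname(fit$parameter[1L]), df_den = unname(fit$parameter[2L]))
}

#' Decide whether a double peak is a confirmed additive nucleotide
#'
#' Decision rule: a mean S-value at or above `direct_threshold` confirms the
#' additive nucleotide directly (the secondary peak is unmistakable); below
#' the threshold the site is confirmed only if the S-vs-N variance analysis
#' is significant at `alpha` *and* the S mean exceeds the N mean (a
#' secondary peak significantly below the noise level is not evidence of a
#' second base); otherwise the secondary peak cannot be told from noise.
#'
#' @inheritParams anova_s_vs_n
#' @param alpha Significance level (default 0.01).
#' @param direct_threshold Mean S confirming directly (default 0.15).
#' @param site Optional site index carried into the result.
#' @return Object of class `additivity_decision` with the summary fields and
#'   a `verdict` in `confirmed_direct`, `confirmed_by_test`, `not_confirmed`.
#' @export
decide_additivity <- function(s_reps, n_reps_list, alpha = 0.01,
                              direct_threshold = 0.15, welch = FALSE,
                              site = NA_integer_) {
  test <- anova_s_vs_n(s_reps, n_reps_list, welch = welch)
  s_mean <- mean(s_reps)
  verdict <- if (s_mean >= direct_threshold) {
    "confirmed_direct"
  } else if (test$p_value < alpha && s_mean > mean(n_reps_list)) {
    "confirmed_by_test"
  } else {
    "not_confirmed"
  }
  structure(list(site = site, s_mean = s_mean, s_sd = stats::sd(s_reps),
                 n_mean = mean(n_reps_list), n_sd = stats::sd(n_reps_list),
                 n_reps = length(s_reps), p_value = test$p_value,
                 statistic = test$statistic, alpha = alpha,
                 direct_threshold = direct_threshold, verdict = verdict),
            class = "additivity_decision")
}

#' @export
print.additivity_decision <- function(x, ...) {
  cat(sprintf(
    "additivity decision%s: %s\n  S = %.4f +/- %.4f, N = %.4f +/- %.4f (n = %d), p = %.4g\n",
    if (is.na(x$site)) "" else paste0(" at site ", x$site),
    x$verdict, x$s_mean, x$s_sd, x$n_mean, x$n_sd, x$n_reps, x$p_value))
  invisible(x)
}

#' Candidate double-peak sites confirmed on both strands
#'
#' A position is a candidate only if its per-position secondary-peak ratio
#' exceeds `min_secondary` on the forward strand and at the mirrored
#' position of the reverse strand; requiring both reads removes one-strand
#' artifacts before any statistics are run.
#'
#' @param fwd,rev Forward- and reverse-strand `sanger_trace` objects over
#'   the same coordinates.
#' @param min_secondary Secondary-ratio threshold (default 0.14, about four
#'   replicate SDs above the default noise ratio of 0.099, so noise
#'   excursions are effectively never flagged while any confirmable
#'   heterozygous fraction still is).
#' @return Sorted integer vector of forward-strand (ITS) positions.
#' @export
detect_candidate_sites <- function(fwd, rev, min_secondary = 0.14) {
  stopifnot(inherits(fwd, "sanger_trace"), inherits(rev, "sanger_trace"))
  if (nrow(fwd) != nrow(rev)) {
    stop("forward and reverse traces differ in length", call. = FALSE)
  }
  s_f <- .per_position_s(fwd)
  s_r <- rev(.per_position_s(rev))  # reverse position p maps to L - p + 1
  sort(which(s_f > min_secondary & s_r > min_secondary))
}

#' Simulated calibration table for a mixing series
#'
#' Simulates `n` (S, N) replicate pairs per mixing fraction, summarizes each
#' fraction as percent mean +/- SD (2 decimals), and applies the S-vs-N
#' variance analysis at `alpha`.  A fraction is flagged significant only
#' when the S mean also exceeds the N mean, mirroring [decide_additivity()].
#'
#' @param fractions Mixing fractions in [0, 0.5].
#' @param n Replicates per fraction (default 5).
#' @param params A [sim_params()]; its `seed` makes the table reproducible.
#' @param alpha Significance level (default 0.01).
#' @return `data.frame` of class `calibration_table` with columns
#'   `fraction_pct`, `s_mean`, `s_sd`, `n_mean`, `n_sd`, `p_value`,
#'   `significant`.
#' @examples
#' calibration_table(params = sim_params(seed = 1))
#' @export
calibration_table <- function(fractions = c(0.10, 0.15, 0.20, 0.30, 0.40,
                                            0.50),
                              n = 5L, params = sim_params(), alpha = 0.01) {
  if (length(fractions) == 0L) stop("no fractions given", call. = FALSE)
  rows <- lapply(seq_along(fractions), function(i) {
    seed <- if (is.null(params$seed)) NULL else .derive_seed(params$seed, i)
    reps <- simulate_sn_replicates(fractions[i], n, params, seed = seed)
    test <- anova_s_vs_n(reps$s, reps$n_val)
    data.frame(fraction_pct = 100 * fractions[i],
               s_mean = round(100 * mean(reps$s), 2L),
               s_sd = round(100 * stats::sd(reps$s), 2L),
               n_mean = round(100 * mean(reps$n_val), 2L),
               n_sd = round(100 * stats::sd(reps$n_val), 2L),
               p_value = test$p_value,
               significant = test$p_value < alpha &&
                 mean(reps$s) > mean(reps$n_val))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' Detection limit of the calibration design across seeds
#'
#' Runs [calibration_table()] once per seed and records the smallest
#' fraction whose S-vs-N test is significant; the majority value across
#' seeds is the empirical detection limit of the design.
#'
#' @param seeds Integer vector of root seeds (>= 20 recommended).
#' @inheritParams calibration_table
#' @return List with `per_seed_pct` (smallest significant fraction per seed,
#'   `NA` if none) and `majority_pct`.
#' @export
detection_limit <- function(seeds, fractions = c(0.10, 0.15, 0.20, 0.30,
                                                 0.40, 0.50),
                            n = 5L, params = sim_params(), alpha = 0.01) {
  per_seed <- vapply(seeds, function(sd) {
    p <- params
    p$seed <- as.integer(sd)
    tab <- calibration_table(fractions, n, p, alpha)
    hit <- tab$fraction_pct[tab$significant]
    if (length(hit)) min(hit) else NA_real_
  }, numeric(1))
  counts <- table(per_seed, useNA = "no")
  majority <- as.numeric(names(counts)[which.max(counts)])
  list(per_seed_pct = per_seed, majority_pct = majority)
}

#' Hybrid ratio from S-value replicates
#'
#' The mean S-value of a confirmed additive site, expressed as a percent,
#' estimates the proportion of the minor parental repeat type.
#'
#' @param s_reps Numeric vector of replicate S fractions (>= 2).
#' @return Named numeric `c(mean_pct, sd_pct)`, rounded to 2 decimals.
#' @examples
#' hybrid_ratio(c(0.334, 0.335, 0.333))
#' @export
hybrid_ratio <- function(s_reps) {
  if (length(s_reps) < 2L) stop("need at least 2 replicates", call. = FALSE)
  c(mean_pct = round(100 * mean(s_reps), 2L),
    sd_pct = round(100 * stats::sd(s_reps), 2L))
}

#' Mean hybrid ratio per (ITS type, site)
#'
#' Arithmetic mean over specimens of each type of the per-specimen hybrid
#' ratio means at positions 122 and 226.  Type/site cells with no measured
#' specimen are omitted.
#'
#' @param panel A [build_specimen_panel()]-style data frame.
#' @param digits Decimals for the reported mean (default 2).
#' @return `data.frame` with columns `its_type`, `site`, `mean_ratio`, `n`.
#' @examples
#' agg <- aggregate_ratios_by_type(build_specimen_panel())
#' agg[agg$its_type == "PM3", ]
#' @export
aggregate_ratios_by_type <- function(panel, digits = 2L) {
  stopifnot(all(c("its_type", "ratio122_mean", "ratio226_mean") %in%
                  names(panel)))
  rows <- list()
  for (site in c(122L, 226L)) {
    col <- paste0("ratio", site, "_mean")
    for (ty in sort(unique(panel$its_type))) {
      vals <- panel[[col]][panel$its_type == ty]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        its_type = ty, site = site,
        mean_ratio = round(mean(vals), digits), n = length(vals))
    }
  }
  do.call(rbind, rows)
}
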