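test_that("reference generator satisfies every layout constraint", {
  layout <- reference_layout()
  ref <- as.character(test_ref)
  expect_equal(nchar(ref), 655L)
  expect_equal(gc_content(ref), 60.61)
  v <- strsplit(ref, "")[[1]]
  expect_equal(sum(v %in% c("G", "C")), 397L)
  # motifs exactly once, at the stated boundaries
  for (m in c("TCGAA", "TCCGACC", "AAACGACTCT", "CGTCACGC")) {
    hits <- gregexpr(m, ref, fixed = TRUE)[[1]]
    expect_length(hits, 1L)
  }
  expect_equal(substr(ref, 1, 5), "TCGAA")
  expect_equal(substr(ref, 649, 655), "TCCGACC")
  expect_equal(substr(ref, 258, 267), "AAACGACTCT")
  expect_equal(substr(ref, 413, 420), "CGTCACGC")
  # baseline alleles at the variable positions
  expect_equal(v[c(122, 135, 226, 500)], c("C", "G", "C", "G"))
})

test_that("reference generation is deterministic per seed and varies across seeds", {
  r1a <- make_reference(seed = 7)
  r1b <- make_reference(seed = 7)
  r2 <- make_reference(seed = 8)
  expect_identical(as.character(r1a), as.character(r1b))
  expect_false(identical(as.character(r1a), as.character(r2)))
  # different filler, same invariants
  expect_equal(gc_content(r2), 60.61)
  expect_equal(substr(as.character(r2), 122, 122), "C")
})

test_that("infeasible layouts fail constructively", {
  expect_error(make_reference(reference_layout(gc_count = 650L)),
               "gc_count")
  expect_error(make_reference(reference_layout(gc_count = 10L)), "gc_count")
})

test_that("type rendering applies the variable-site table", {
  expect_identical(as.character(render_type_sequence("P0", test_ref)),
                   as.character(test_ref))
  t1 <- as.character(render_type_sequence("T1", test_ref))
  expect_equal(substr(t1, 122, 122), "T")
  expect_equal(substr(t1, 135, 135), "R")
  expect_equal(substr(t1, 226, 226), "C")  # unchanged from baseline
  expect_equal(substr(t1, 500, 500), "R")
  pm2 <- as.character(render_type_sequence("PM2", test_ref))
  expect_equal(substr(pm2, 122, 122), "T")
  expect_equal(substr(pm2, 226, 226), "Y")
  expect_equal(substr(pm2, 135, 135), "G")
  # major/minor orientation travels with the sequence
  p1 <- render_type_sequence("P1", test_ref)
  expect_equal(attr(p1, "majors"), c(`122` = "T", `226` = "C"))
  expect_error(render_type_sequence("XX", test_ref), "valid labels")
})

test_that("moment sampler matches its closed form and stays in range", {
  params <- sim_params(seed = 11)
  reps0 <- simulate_sn_replicates(0, 5000, params)
  # truncation at 0 lifts the mean slightly above the intercept
  expect_lt(abs(mean(reps0$s) - params$intercept_b), 0.005)
  expect_lt(abs(mean(reps0$n_val) - 0.11 / 1.11), 0.005)
  reps3 <- simulate_sn_replicates(0.3, 5000, params)
  expect_lt(abs(mean(reps3$s) - 0.2965), 0.005)
  expect_true(all(reps3$s >= 0 & reps3$s <= 1))
  expect_error(simulate_sn_replicates(0.6, 5), "\\[0, 0.5\\]")
  expect_error(simulate_sn_replicates(0.3, 1), "2 replicates")
  # reproducible under seed
  expect_identical(simulate_sn_replicates(0.2, 5, params),
                   simulate_sn_replicates(0.2, 5, params))
})

test_that("simulated S means recover the calibration series moments", {
  params <- sim_params(seed = 5)
  ref_tab <- calibration_reference()
  means <- vapply(seq_len(nrow(ref_tab)), function(i) {
    mean(simulate_sn_replicates(ref_tab$fraction_pct[i] / 100, 10000,
                                params, seed = 100 + i)$s)
  }, numeric(1))
  expect_true(all(abs(means - ref_tab$s_mean / 100) < 0.02))
  expect_true(all(diff(means) > 0))  # strictly increasing in fraction
})

test_that("rendered traces are valid and round-trip the S-value", {
  params <- sim_params(seed = 3)
  seq <- as.character(test_ref)
  pure <- render_trace(seq, NULL, params)
  expect_identical(trace_sequence(pure), seq)

  het <- data.frame(pos = 122, minor = "T", fraction = 0.5)
  tr <- render_trace(seq, het, params, seed = 21)
  s <- s_value(extract_peaks(tr, 122, c(117, 127)))
  expect_equal(s, 0.905 * 0.5 + 0.025, tolerance = 3 * params$s_rep_sd)

  # forward and reverse renderings report the same ITS coordinate
  fwd <- render_trace(seq, data.frame(pos = 122, minor = "T",
                                      fraction = 0.3), params, seed = 31)
  rev <- render_trace(seq, data.frame(pos = 122, minor = "T",
                                      fraction = 0.3), params,
                      strand = "reverse", seed = 32)
  expect_equal(detect_candidate_sites(fwd, rev), 122L)
  expect_error(render_trace(seq, data.frame(pos = 122, minor = "C",
                                            fraction = 0.3), params),
               "minor base")
  expect_error(render_trace(seq, data.frame(pos = 122, minor = "T",
                                            fraction = 0.7), params),
               "\\[0, 0.5\\]")
})

test_that("packaged specimen panel matches the published records", {
  panel <- build_specimen_panel()
  expect_s3_class(panel, "specimen_panel")
  expect_equal(nrow(panel), 46L)
  cp01 <- panel[panel$voucher == "CP01", ]
  expect_equal(cp01$its_type, "P1")
  expect_equal(cp01$ratio122_mean, 33.46)
  expect_equal(cp01$ratio122_sd, 1.29)
  expect_equal(cp01$ratio226_mean, 46.89)
  expect_equal(cp01$ratio226_sd, 1.35)
  ct46 <- panel[panel$voucher == "CT46", ]
  expect_equal(ct46$species, "C. tangshen")
  expect_equal(ct46$altitude_m, 1775)
  # canonical type counts match the type-definition table
  defs <- its_type_defs()
  for (l in defs$label[!is.na(defs$n_specimens)]) {
    expect_equal(sum(panel$its_type == l),
                 as.integer(defs$n_specimens[defs$label == l]),
                 info = l)
  }
  expect_setequal(panel_type_discrepancies(panel),
                  c("CP34", "CP37", "CP38", "CPM42", "CPM43", "CPM44",
                    "CPM45"))
})
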