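test_that("variable-site genotyping reads compositions and majors", {
  g0 <- genotype_variable_sites(test_ref)
  expect_equal(g0$position, c(122L, 135L, 226L, 500L))
  expect_equal(g0$iupac, c("C", "G", "C", "G"))
  expect_true(all(is.na(g0$major)))

  p1 <- render_type_sequence("P1", test_ref)
  g1 <- genotype_variable_sites(p1)
  expect_equal(g1$composition[g1$position == 122], "C/T")
  expect_equal(g1$major[g1$position == 122], "T")
  expect_equal(g1$major[g1$position == 226], "C")

  t1 <- genotype_variable_sites(render_type_sequence("T1", test_ref))
  expect_equal(t1$composition[t1$position == 135], "A/G")

  # an ambiguity outside the canonical four is still reported
  extra <- as.character(test_ref)
  substr(extra, 300, 300) <- "Y"
  ge <- genotype_variable_sites(extra)
  expect_true(300L %in% ge$position)
  expect_error(genotype_variable_sites("ACGX"), "non-IUPAC")
  expect_error(genotype_variable_sites(p1, majors = c(`122` = "G")),
               "inconsistent")
})

test_that("type assignment is the inverse of type rendering", {
  for (l in its_type_defs()$label) {
    s <- render_type_sequence(l, test_ref)
    expect_identical(assign_type(attr(s, "species"),
                                 genotype_variable_sites(s)), l)
  }
})

test_that("species context and orientation disambiguate identical genotypes", {
  p1 <- render_type_sequence("P1", test_ref)
  gt <- genotype_variable_sites(p1)
  # same genotype + orientation, different species: P1 vs PM1
  expect_identical(assign_type("C. pilosula", gt), "P1")
  expect_identical(assign_type("C. pilosula var. modesta", gt), "PM1")
  # orientation flips the pilosula label: Y(C>T) at both sites is P4
  gt4 <- gt
  gt4$major <- c("C", NA, "C", NA)
  expect_identical(assign_type("C. pilosula", gt4), "P4")
  # Y(C>T)@122 with plain C@226 is P5; Y(T>C) in var. modesta is PM3
  p5 <- render_type_sequence("P5", test_ref)
  expect_identical(assign_type("C. pilosula",
                               genotype_variable_sites(p5)), "P5")
  pm3 <- render_type_sequence("PM3", test_ref)
  expect_identical(assign_type("C. pilosula var. modesta",
                               genotype_variable_sites(pm3)), "PM3")
  # unidentified species resolves the S0 pure line
  s0 <- render_type_sequence("S0", test_ref)
  expect_identical(assign_type("unidentified",
                               genotype_variable_sites(s0)), "S0")
  # an unknown genotype is reported as novel, not an error
  weird <- as.character(test_ref)
  substr(weird, 135, 135) <- "W"
  expect_message(lab <- assign_type("C. pilosula",
                                    genotype_variable_sites(weird)),
                 "novel")
  expect_equal(as.character(lab), "novel")
})

test_that("heterozygosity census counts ambiguity-carrying types", {
  panel <- build_specimen_panel()
  cen45 <- census_heterozygosity(panel, exclude = "CT46")
  expect_equal(cen45$total, 45L)
  expect_equal(cen45$n_heterozygous, 45L)
  expect_equal(cen45$n_pure, 0L)
  # the tangshen specimen carries R genotypes, so the full panel is 46/46
  cen46 <- census_heterozygosity(panel)
  expect_equal(cen46$n_heterozygous, 46L)
  # a panel typed to a pure line has no heterozygotes
  pure_panel <- data.frame(voucher = c("X1", "X2"),
                           species = "C. pilosula", its_type = "P0")
  expect_equal(census_heterozygosity(pure_panel)$n_heterozygous, 0L)
})

test_that("single-cross inference matches a brute-force pair oracle", {
  lines <- pure_line_defs()
  expect_setequal(lines$label, c("P0", "PM0", "T0", "S0"))
  # oracle: enumerate all C(4,2) + 4 = 10 unordered pairs independently
  oracle <- function(target) {
    tcomp <- type_compositions(target)
    hits <- character(0)
    labs <- lines$label
    for (i in seq_along(labs)) {
      for (j in i:length(labs)) {
        ca <- type_compositions(labs[i])
        cb <- type_compositions(labs[j])
        ok <- all(vapply(names(tcomp), function(s) {
          setequal(union(ca[[s]], cb[[s]]), tcomp[[s]])
        }, logical(1)))
        if (ok) hits <- c(hits, paste(labs[i], labs[j]))
      }
    }
    hits
  }
  expected <- list(P1 = "P0 S0", P2 = character(0), P3 = "P0 S0",
                   P4 = "P0 S0", P5 = "P0 PM0", PM1 = "P0 S0",
                   PM2 = "PM0 S0", PM3 = "P0 PM0", T1 = character(0))
  for (ty in names(expected)) {
    got <- infer_single_cross(ty)
    got_pairs <- if (nrow(got)) paste(got$parent_a, got$parent_b) else
      character(0)
    expect_setequal(got_pairs, oracle(ty))
    expect_setequal(got_pairs, expected[[ty]])
  }
})

test_that("gamete-model feasibility generalizes single crosses", {
  # reduces to single-cross membership when both parents are homozygous
  for (ty in c("P1", "P5", "PM2")) {
    singles <- infer_single_cross(ty)
    lines <- pure_line_defs()$label
    for (i in seq_along(lines)) {
      for (j in i:length(lines)) {
        inferred <- any(singles$parent_a == lines[i] &
                          singles$parent_b == lines[j])
        expect_equal(cross_feasible(lines[i], lines[j], ty)$feasible,
                     inferred, info = paste(ty, lines[i], lines[j]))
      }
    }
  }
  # heterozygous parent contributes one gamete per site
  expect_true(cross_feasible("PM2", "P0", "P1")$feasible)
  expect_true(cross_feasible("PM3", "S0", "P1")$feasible)
  expect_false(cross_feasible("S0", "S0", "P1")$feasible)
})

test_that("two-step enumeration contains the documented chains", {
  chains <- enumerate_two_step("P1")
  key <- paste(chains$step1_parent_a, chains$step1_parent_b,
               chains$intermediate, chains$step2_parent)
  expect_true("PM0 S0 PM2 P0" %in% key)
  expect_true("P0 PM0 PM3 S0" %in% key)
  expect_false(anyDuplicated(key) > 0)
  # a homozygous target needs no hybridization
  expect_equal(nrow(enumerate_two_step("P0")), 0L)
})

test_that("the unexplained type admits a hypothetical unsampled parent", {
  hp <- hypothetical_partner("P2")
  expect_true(nrow(hp) >= 1L)
  row <- hp[hp$known_parent == "P0", ]
  expect_equal(unname(unlist(row[, c("X122", "X135", "X226", "X500")])),
               c("C", "G", "T", "G"))
  # T1 has no sampled pair, but crossing T0 with an unsampled line that
  # carries A at 135 would explain it
  expect_equal(nrow(infer_single_cross("T1")), 0L)
  hpt <- hypothetical_partner("T1")
  t0row <- hpt[hpt$known_parent == "T0", ]
  expect_equal(unname(unlist(t0row[, c("X122", "X135", "X226", "X500")])),
               c("T", "A", "C", "G"))
})
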