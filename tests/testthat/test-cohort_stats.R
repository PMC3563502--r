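obs_row <- function(pid, eth, key, zyg = "het") {
  data.frame(patient_id = pid, ethnicity = eth, key = key, zygosity = zyg,
             stringsAsFactors = FALSE)
}

test_that("observation_count weighs homozygotes twice", {
  obs <- rbind(obs_row("p1", "Caucasian", "c.1A>G"),
               obs_row("p2", "Caucasian", "c.2T>C", "hom"),
               obs_row("p3", "Caucasian", "c.3G>A"),
               obs_row("p4", "Caucasian", "c.3G>A"),
               obs_row("p5", "Caucasian", "c.3G>A"),
               obs_row("p6", "Caucasian", "c.3G>A", "hom"),
               obs_row("p7", "Caucasian", "c.3G>A", "hom"))
  expect_equal(unname(observation_count(obs, "c.1A>G")), 1L)
  expect_equal(unname(observation_count(obs, "c.2T>C")), 2L)
  expect_equal(unname(observation_count(obs, "c.3G>A")), 7L)
  expect_equal(unname(observation_count(obs, "c.9C>T")), 0L)
})

test_that("most_common_variants ranks by observations with key tie-break", {
  obs <- rbind(obs_row("p1", "Caucasian", "c.2T>C", "hom"),
               obs_row("p2", "Caucasian", "c.2T>C"),
               obs_row("p1", "Caucasian", "c.10A>G"),
               obs_row("p2", "Caucasian", "c.10A>G"),
               obs_row("p3", "Caucasian", "c.10A>G"),
               obs_row("p1", "Caucasian", "c.5G>T"),
               obs_row("p2", "Caucasian", "c.5G>T", "hom"),
               obs_row("p4", "Caucasian", "c.1A>G"))
  top <- most_common_variants(obs, 10)
  expect_equal(top$key, c("c.10A>G", "c.2T>C", "c.5G>T", "c.1A>G"))
  expect_equal(top$observations, c(3L, 3L, 3L, 1L))
  expect_equal(nrow(most_common_variants(obs, 2)), 2L)
  expect_error(most_common_variants(obs, 0), ">= 1")
})

test_that("ethnic-specific accounting honours the Other/Mixed rules", {
  obs <- rbind(
    obs_row("a1", "African American", "c.1A>G"),
    obs_row("a2", "African American", "c.2T>C"),
    obs_row("c1", "Caucasian", "c.2T>C"),
    obs_row("c2", "Caucasian", "c.3G>A"),
    obs_row("o1", "Other/Mixed", "c.3G>A"),
    obs_row("o2", "Other/Mixed", "c.4C>T"))
  es <- ethnic_summary(obs, novel_keys = c("c.1A>G", "c.4C>T"))
  aa <- es[es$ethnicity == "African American", ]
  ca <- es[es$ethnicity == "Caucasian", ]
  om <- es[es$ethnicity == "Other/Mixed", ]
  expect_equal(aa$total_snvs, 2L)
  expect_equal(aa$ethnic_specific, 1L)       # c.1A>G only
  expect_equal(aa$ethnic_specific_pct, 50)
  expect_equal(aa$novel_ethnic_specific, 1L)
  # c.3G>A is shared with Other/Mixed, so not Caucasian-specific by default
  expect_equal(ca$ethnic_specific, 0L)
  expect_true(is.na(om$ethnic_specific))
  expect_equal(om$novel_ethnic_specific, 1L)  # c.4C>T seen only there

  # ignoring Other/Mixed support flips c.3G>A to Caucasian-specific
  es2 <- ethnic_summary(obs, novel_keys = character(0),
                        count_other_mixed_support = FALSE)
  expect_equal(es2[es2$ethnicity == "Caucasian", "ethnic_specific"], 1L)
})

test_that("in a single-group cohort every variant is group-specific", {
  obs <- rbind(obs_row("h1", "Hispanic", "c.1A>G"),
               obs_row("h2", "Hispanic", "c.2T>C"))
  es <- ethnic_summary(obs)
  hi <- es[es$ethnicity == "Hispanic", ]
  expect_equal(hi$ethnic_specific, hi$total_snvs)
  expect_equal(hi$ethnic_specific_pct, 100)
  expect_error(ethnic_summary(obs_row("x", "Martian", "c.1A>G")), "Martian")
})

test_that("summary matches a brute-force recomputation on the fixture cohort", {
  fx <- study_fixture()
  obs <- fx$cohort$observations
  es <- ethnic_summary(obs, novel_keys = fx$novel_keys)
  # independent recomputation from per-variant group-support sets
  support <- tapply(obs$ethnicity, obs$key,
                    function(g) sort(unique(g)), simplify = FALSE)
  for (g in setdiff(ethnicity_levels, "Other/Mixed")) {
    keys_g <- unique(obs$key[obs$ethnicity == g])
    spec_g <- keys_g[vapply(support[keys_g], function(s) identical(s, g),
                            logical(1))]
    row <- es[es$ethnicity == g, ]
    expect_equal(row$total_snvs, length(keys_g), label = g)
    expect_equal(row$ethnic_specific, length(spec_g), label = g)
    expect_equal(row$novel_ethnic_specific,
                 length(intersect(spec_g, fx$novel_keys)), label = g)
    expect_equal(row$n_patients,
                 length(unique(obs$patient_id[obs$ethnicity == g])), label = g)
  }
  # generator ground truth agrees with the pipeline's support sets
  truth_support <- fx$cohort$truth$group_support
  names(truth_support) <- fx$cohort$truth$key
  got_support <- vapply(support, paste, "", collapse = ";")
  expect_equal(got_support[names(truth_support)], truth_support)
  # each ethnic-specific variant counts for exactly one group
  expect_lte(sum(es$ethnic_specific, na.rm = TRUE),
             length(unique(obs$key)))
})

test_that("dropping a group never shrinks other groups' specific counts", {
  fx <- study_fixture()
  obs <- fx$cohort$observations
  base <- ethnic_summary(obs)
  drop <- ethnic_summary(obs[obs$ethnicity != "Hispanic", , drop = FALSE])
  for (g in setdiff(ethnicity_levels, c("Hispanic", "Other/Mixed"))) {
    expect_gte(drop[drop$ethnicity == g, "ethnic_specific"],
               base[base$ethnicity == g, "ethnic_specific"])
    expect_lte(drop[drop$ethnicity == g, "total_snvs"],
               base[base$ethnicity == g, "total_snvs"])
  }
})

test_that("cohort files round-trip and are validated on read", {
  fx <- study_fixture()
  f <- tempfile(fileext = ".tsv")
  write_cohort(fx$cohort$observations, f)
  back <- read_cohort(f)
  expect_equal(back, fx$cohort$observations)

  writeLines("patient_id\tethnicity\tvariant\tzygosity", f)
  expect_error(read_cohort(f), "no observations")
  writeLines(c("patient_id\tethnicity\tvariant\tzygosity",
               "p1\tKlingon\tc.1A>G\thet"), f)
  expect_error(read_cohort(f), "Klingon")
  writeLines(c("patient_id\tethnicity\tvariant\tzygosity",
               "p1\tCaucasian\tc.1A>G\thet",
               "p1\tCaucasian\tc.1 A > G\thom"), f)
  expect_error(read_cohort(f), "duplicate")
  unlink(f)
})
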