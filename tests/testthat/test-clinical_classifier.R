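bundle <- function(key = "c.100A>G", db = "none", lit = "none",
                   freq = NA_real_, score = NA_real_, recorded = TRUE,
                   labels = "missense", deep = NA) {
  data.frame(key = key, db_assertions = db, literature_status = lit,
             population_frequency = freq, insilico_score = score,
             recorded = recorded, labels = labels, deep_intronic = deep,
             stringsAsFactors = FALSE)
}

tier_of <- function(...) classify_variants(bundle(...))$tier

test_that("the rule ladder reproduces the laboratory heuristics", {
  # deep intronic, nothing else known -> suspected benign
  expect_equal(tier_of(labels = "intronic", deep = TRUE), "suspected_benign")
  # literature-reported pathogenic nonsense -> pathogenic (rule 1 dominates)
  expect_equal(tier_of(lit = "reported_pathogenic", labels = "nonsense"),
               "pathogenic")
  # rare missense with neutral in-silico stays of unknown significance
  expect_equal(tier_of(freq = 0.0001, score = 0.5), "unknown_significance")
  # common synonymous variant -> benign via the frequency rule
  expect_equal(tier_of(freq = 0.30, labels = "synonymous"), "benign")
  # sub-threshold synonymous -> suspected benign
  expect_equal(tier_of(freq = 0.001, labels = "synonymous"),
               "suspected_benign")
  # database assertions
  expect_equal(tier_of(db = "HGMD:pathogenic"), "pathogenic")
  expect_equal(tier_of(db = "CFMDB:suspected_pathogenic"),
               "suspected_pathogenic")
  expect_equal(tier_of(db = "dbSNP132:benign"), "benign")
  expect_equal(tier_of(db = "CFMDB:suspected_benign"), "suspected_benign")
  # shallow intronic with no evidence is a VUS, not suspected benign
  expect_equal(tier_of(labels = "intronic", deep = FALSE),
               "unknown_significance")
})

test_that("in-silico scores only move within the uncertain tiers", {
  expect_equal(tier_of(score = 0.99), "suspected_pathogenic")
  expect_equal(tier_of(score = 0.01), "suspected_benign")
  # never override an assertion-based or frequency-based call
  expect_equal(tier_of(db = "HGMD:pathogenic", score = 0.01), "pathogenic")
  expect_equal(tier_of(freq = 0.3, score = 0.99), "benign")
  # and never reach pathogenic/benign on their own
  expect_false(tier_of(score = 1.0) %in% c("pathogenic", "benign"))
  expect_false(tier_of(score = 0.0) %in% c("pathogenic", "benign"))
})

test_that("unrecorded variants get the unrecorded tier with empty trace", {
  calls <- classify_variants(bundle(recorded = FALSE))
  expect_equal(calls$tier, "unrecorded")
  expect_equal(calls$rule_trace, "")
  # every recorded call carries a non-empty trace
  calls2 <- classify_variants(bundle())
  expect_gt(nchar(calls2$rule_trace), 0L)
})

test_that("frequencies outside [0,1] and unknown assertions are rejected", {
  expect_error(classify_variants(bundle(freq = 1.5)), "\\[0, 1\\]")
  expect_error(classify_variants(bundle(db = "HGMD:oracular")),
               "assertion level")
})

test_that("the rule trace replays to the assigned tier", {
  fx <- study_fixture()
  calls <- classify_variants(fx$evidence)
  recorded <- calls[calls$tier != "unrecorded", ]
  last_rule <- sub(".*->", "", sub(".*\\|", "", recorded$rule_trace))
  expect_equal(last_rule, recorded$tier)
})

test_that("classification is monotone in evidence", {
  rank <- c(benign = 1, suspected_benign = 2, unknown_significance = 3,
            suspected_pathogenic = 4, pathogenic = 5)
  set.seed(99)
  for (i in 1:200) {
    b <- bundle(
      db = sample(c("none", "HGMD:pathogenic", "CFMDB:benign",
                    "CFMDB:suspected_pathogenic", "dbSNP132:suspected_benign"), 1),
      lit = sample(c("none", "reported_pathogenic", "reported_benign"), 1),
      freq = sample(c(NA, runif(1)), 1),
      score = sample(c(NA, runif(1)), 1),
      labels = sample(c("missense", "synonymous", "intronic"), 1),
      deep = sample(c(NA, TRUE, FALSE), 1))
    t0 <- rank[classify_variants(b)$tier]
    # adding a pathogenic assertion never moves toward benign
    b_path <- b
    b_path$db_assertions <- ifelse(b$db_assertions == "none",
                                   "HGMD:pathogenic",
                                   paste0(b$db_assertions, ";HGMD:pathogenic"))
    expect_gte(rank[classify_variants(b_path)$tier], t0)
    # raising the frequency never moves toward pathogenic
    b_freq <- b
    b_freq$population_frequency <- if (is.na(b$population_frequency)) 0.5 else
      min(1, b$population_frequency + 0.5)
    expect_lte(rank[classify_variants(b_freq)$tier], t0)
  }
})

test_that("tier tallies always sum to the number of calls", {
  fx <- study_fixture()
  calls <- classify_variants(fx$evidence)
  tal <- tally_tiers(calls)
  expect_equal(sum(tal$n_variants), nrow(calls))
  expect_equal(attr(tal, "total"), nrow(calls))
  empty <- tally_tiers(data.frame(key = character(0), tier = character(0)))
  expect_true(all(empty$n_variants == 0L))
  expect_error(tally_tiers(data.frame(key = "k", tier = "limbo")),
               "unknown tier")
})
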