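test_that("gen_transcript builds a CFTR-sized gene deterministically", {
  m <- gen_transcript(1L)
  expect_equal(nrow(m$exons), 27L)
  expect_equal(n_introns(m), 26L)
  expect_equal(cds_length(m), 4443L)  # 1480 codons + stop
  expect_equal(substr(m$coding_sequence, 1, 3), "ATG")
  # no internal stops
  codons <- substring(m$coding_sequence, seq(1, 4440, 3), seq(3, 4442, 3))
  expect_false(any(codons[-1] %in% c("TAA", "TAG", "TGA")))
  expect_identical(gen_transcript(1L), m)
  expect_false(identical(gen_transcript(2L), m))
  expect_equal(n_introns(gen_transcript(3L, n_exons = 1L, n_codons = 10L)), 0L)
  expect_error(gen_transcript(1L, n_exons = 50L, n_codons = 5L), "infeasible")
})

test_that("gen_cohort plants the headline counts exactly", {
  fx <- study_fixture()
  truth <- fx$cohort$truth
  obs <- fx$cohort$observations
  expect_equal(nrow(truth), 184L)
  expect_equal(length(unique(obs$key)), 184L)
  expect_equal(sum(truth$is_singleton), 107L)
  expect_equal(length(unique(obs$patient_id)), 555L)
  # planted observation counts are recovered by the cohort bookkeeping
  counts <- observation_count(obs, truth$key)
  expect_equal(unname(counts), truth$planted_count)
  top4 <- most_common_variants(obs, 4L)
  expect_equal(top4$observations, c(955L, 728L, 427L, 236L))
  expect_setequal(top4$key, truth$key[truth$is_common])
  # singletons really are single het observations
  expect_true(all(counts[truth$is_singleton] == 1L))
})

test_that("gen_cohort is reproducible and respects tiny cohorts", {
  m <- gen_transcript(21L, n_exons = 4L, n_codons = 60L)
  spec <- cohort_spec(seed = 5L)
  a <- gen_cohort(spec, gen_transcript(1L))
  b <- gen_cohort(spec, gen_transcript(1L))
  expect_identical(a, b)

  tiny <- cohort_spec(n_patients = 1L, n_distinct_variants = 3L,
                      singleton_fraction = 2 / 3,
                      common_variant_counts = 2L,
                      class_counts = c(missense = 1L, intronic = 1L,
                                       synonymous = 1L, splice_site = 0L,
                                       nonsense = 0L, promoter = 0L),
                      seed = 6L)
  co <- gen_cohort(tiny, m)
  expect_equal(unique(co$observations$patient_id), "P0001")
  expect_error(cohort_spec(n_patients = 1L, common_variant_counts = 5L,
                           seed = 1L), "exceeds")
})

test_that("gen_snapshots withholds exactly the forced novel set", {
  fx <- study_fixture()
  keys <- fx$cohort$truth$key
  all_db_keys <- unlist(lapply(fx$snapshots, `[[`, "keys"))
  expect_equal(length(fx$novel_keys), 21L)
  expect_equal(length(intersect(fx$novel_keys, all_db_keys)), 0L)
  # every non-novel key is in at least one snapshot
  expect_setequal(setdiff(keys, all_db_keys), fx$novel_keys)

  # inclusion probability 1 with no forced novels leaves nothing novel
  sp <- snapshot_spec(inclusion_probs = c(A = 1, B = 1),
                      forced_novel_count = 0L, seed = 9L)
  sn <- gen_snapshots(sp, keys)
  expect_equal(length(sn$novel_keys), 0L)
  expect_equal(cross_reference(keys, unname(sn$snapshots))$novel_count, 0L)

  sp2 <- snapshot_spec(seed = 10L)
  expect_identical(gen_snapshots(sp2, keys), gen_snapshots(sp2, keys))
  expect_error(gen_snapshots(snapshot_spec(forced_novel_count = 500L,
                                           seed = 1L), keys), "exceeds")
  expect_error(snapshot_spec(inclusion_probs = c(A = 1.2), seed = 1L),
               "\\[0, 1\\]")
})

test_that("snapshot coverage follows the conditional inclusion model", {
  # membership triples are drawn conditional on >=1 inclusion, so each
  # database's marginal is p / (1 - prod(1 - p)); check the mean coverage
  # over repeated draws against a 3-SE binomial band
  p <- c(CFMDB = 0.85, HGMD = 0.64, dbSNP132 = 0.40)
  p_cond <- p / (1 - prod(1 - p))
  keys <- sprintf("c.%dA>G", 1:184)
  n_rep <- 40L
  hits <- matrix(0, nrow = n_rep, ncol = 3,
                 dimnames = list(NULL, names(p)))
  for (r in seq_len(n_rep)) {
    sn <- gen_snapshots(snapshot_spec(seed = 1000L + r), keys)
    known <- setdiff(keys, sn$novel_keys)
    for (db in names(p)) {
      hits[r, db] <- mean(known %in% sn$snapshots[[db]]$keys)
    }
  }
  n_draws <- n_rep * 163L
  for (db in names(p)) {
    se <- sqrt(p_cond[db] * (1 - p_cond[db]) / n_draws)
    expect_lt(abs(mean(hits[, db]) - p_cond[db]), 3 * se, label = db)
  }
})

test_that("gen_evidence plants tier targets the classifier recovers exactly", {
  fx <- study_fixture()
  calls <- classify_variants(fx$evidence)
  expect_equal(calls$tier, fx$tier_truth$planted_tier)
  tal <- tally_tiers(calls)
  expect_equal(sum(tal$n_variants), 184L)
  counts <- setNames(tal$n_variants, tal$tier)
  expect_equal(unname(counts["pathogenic"]), 97L)
  expect_equal(unname(counts["suspected_pathogenic"]), 8L)
  expect_equal(unname(counts["benign"]), 37L)
  expect_equal(unname(counts["unknown_significance"]), 30L)
  expect_equal(unname(counts["suspected_benign"]), 6L)
  expect_equal(unname(counts["unrecorded"]), 6L)
  # novel-variant tier mix is planted and recovered as well
  novel_calls <- calls[calls$key %in% fx$novel_keys, ]
  nc <- table(novel_calls$tier)
  expect_equal(unname(nc[["pathogenic"]]), 4L)
  expect_equal(unname(nc[["benign"]]), 8L)
  expect_equal(unname(nc[["suspected_benign"]]), 3L)
  expect_equal(unname(nc[["unknown_significance"]]), 6L)
  # database assertions only cite databases that actually hold the key
  with_assert <- fx$evidence[fx$evidence$db_assertions != "none", ]
  for (i in seq_len(nrow(with_assert))) {
    db <- sub(":.*", "", with_assert$db_assertions[i])
    expect_true(with_assert$key[i] %in% fx$snapshots[[db]]$keys,
                label = with_assert$key[i])
  }
})

test_that("same master seed writes byte-identical fixture files", {
  d1 <- tempfile("fx1_")
  d2 <- tempfile("fx2_")
  fx1 <- write_fixtures(d1, seed = 77L)
  fx2 <- write_fixtures(d2, seed = 77L)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
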