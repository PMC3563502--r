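# Shared in-code fixtures and independent oracles.

# 3-exon toy gene: CDS ATG AAA CCC GGG TTT TAG (M K P G F *), 18 coding nt
# split 6/7/5 over exons with 50 nt introns. Donor anchors at c.6 and c.13.
toy_model <- function() {
  transcript_model("TOY",
                   exon_starts = c(101L, 157L, 214L),
                   exon_ends = c(106L, 163L, 218L),
                   coding_sequence = "ATGAAACCCGGGTTTTAG")
}

# single-exon toy used for codon-level consequence examples
mini_model <- function() {
  transcript_model("MINI", 1L, 9L, "ATGAAATAG")
}

# map a genomic position to an HGVS-style descriptor anchor by direct scan
# of the exon table (independent of classify_region's arithmetic)
genomic_to_anchor <- function(model, gpos) {
  ex <- model$exons
  n <- nrow(ex)
  if (gpos < ex$start[1L]) {
    return(list(coding_pos = ex$start[1L] - gpos, intron_offset = 0L,
                upstream = TRUE))
  }
  cum <- 0L
  for (i in seq_len(n)) {
    if (gpos >= ex$start[i] && gpos <= ex$end[i]) {
      cp <- cum + (gpos - ex$start[i]) + 1L - (model$cds_start_exon_offset - 1L)
      return(list(coding_pos = cp, intron_offset = 0L, upstream = FALSE))
    }
    cum <- cum + ex$width[i]
    if (i < n && gpos > ex$end[i] && gpos < ex$start[i + 1L]) {
      d_donor <- gpos - ex$end[i]
      d_accept <- ex$start[i + 1L] - gpos
      if (d_donor <= d_accept) {
        return(list(coding_pos = cum - (model$cds_start_exon_offset - 1L),
                    intron_offset = d_donor, upstream = FALSE))
      }
      return(list(coding_pos = cum + 1L - (model$cds_start_exon_offset - 1L),
                  intron_offset = -d_accept, upstream = FALSE))
    }
  }
  NULL
}

# brute-force region label by direct scan of exon boundaries
scan_region_label <- function(model, gpos, halfwidth = 2L) {
  ex <- model$exons
  if (gpos < ex$start[1L]) return("promoter")
  for (i in seq_len(nrow(ex))) {
    if (gpos >= ex$start[i] && gpos <= ex$end[i]) return("exonic")
  }
  dist <- min(abs(gpos - c(ex$start, ex$end)))
  if (dist <= halfwidth) "splice_site" else "intronic"
}

# random valid descriptors for round-trip property tests
random_descriptors <- function(n, seed) {
  snvcohort:::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    kind <- sample(c("exonic", "intronic", "upstream"), n, replace = TRUE,
                   prob = c(0.6, 0.3, 0.1))
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    variant_descriptor(
      coding_pos = sample.int(5000L, n, replace = TRUE),
      intron_offset = ifelse(kind == "intronic",
                             sample(c(-200:-1, 1:200), n, replace = TRUE), 0L),
      upstream = kind == "upstream",
      ref = ref, alt = alt)
  })
}

# default synthetic study fixture, built once per test run
study_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      model <- gen_transcript(101L)
      cohort <- gen_cohort(cohort_spec(seed = 102L), model)
      ann <- annotate_variants(parse_c(cohort$truth$key), model)
      snaps <- gen_snapshots(snapshot_spec(seed = 103L), cohort$truth$key)
      evid <- gen_evidence(ann, snaps$snapshots, snaps$novel_keys,
                           seed = 104L)
      cache <<- list(model = model, cohort = cohort, ann = ann,
                     snapshots = snaps$snapshots,
                     novel_keys = snaps$novel_keys,
                     evidence = evid$evidence, tier_truth = evid$truth)
    }
    cache
  }
})
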