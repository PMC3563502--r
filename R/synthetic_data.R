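#' @title Seeded synthetic referral-cohort generator
#' @description
#' Generates every input the pipeline consumes — a CFTR-like transcript
#' model, a rare-variant-enriched referral cohort, mutation-database
#' snapshots and per-variant evidence bundles — with recorded ground truth,
#' so that every downstream table can be checked against what was planted.
#' All randomness flows through an explicit seed; the same seed always
#' reproduces byte-identical fixtures. Headline quantities (distinct-variant
#' total, singleton count, the planted observation counts of the common
#' polymorphisms, the forced novel count) are planted exactly, not sampled,
#' so the bookkeeping of the pipeline is verifiable deterministically; only
#' per-database membership of known variants is sampled.
#' @name synthetic_data
NULL

.stop_codons <- c("TAA", "TAG", "TGA")

#' Cohort generation parameters
#'
#' Defaults emulate the study conditions of a six-year CFTR referral
#' dataset: 555 patients over eight self-reported ethnicity groups (weights
#' proportional to observed group sizes 61/1/4/403/40/3/1/42), 184 distinct
#' variants of which 107 are singletons, four common polymorphisms planted
#' at 955/728/427/236 observations, and a functional-class mix dominated by
#' missense (105 of 184).
#'
#' @param n_patients cohort size.
#' @param ethnicity_weights named probabilities over [ethnicity_levels]
#'   (normalized internally).
#' @param n_distinct_variants number of distinct variants to plant.
#' @param singleton_fraction fraction of variants observed exactly once.
#' @param common_variant_counts planted observation counts for the common
#'   polymorphisms (each at most `2 * n_patients`).
#' @param hom_fraction probability that an allele-pair opportunity is
#'   homozygous when planting mid-frequency variants.
#' @param class_counts named integer vector over the six functional classes;
#'   must sum to `n_distinct_variants`.
#' @param group_exclusive_fraction probability that a non-common variant's
#'   carriers are confined to a single ethnicity group.
#' @param seed mandatory integer seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 555L,
                        ethnicity_weights = c(
                          "African American" = 61, "Ashkenazi Jewish" = 1,
                          "Asian/Oriental" = 4, "Caucasian" = 403,
                          "Hispanic" = 40, "Middle Eastern" = 3,
                          "Native American" = 1, "Other/Mixed" = 42),
                        n_distinct_variants = 184L,
                        singleton_fraction = 107 / 184,
                        common_variant_counts = c(955L, 728L, 427L, 236L),
                        hom_fraction = 0.05,
                        class_counts = c(missense = 105L, intronic = 20L,
                                         synonymous = 33L, splice_site = 12L,
                                         nonsense = 11L, promoter = 3L),
                        group_exclusive_fraction = 0.7,
                        seed) {
  if (missing(seed)) stop("cohort_spec() requires a seed", call. = FALSE)
  if (!setequal(names(ethnicity_weights), ethnicity_levels)) {
    stop("ethnicity_weights must be named by ethnicity_levels", call. = FALSE)
  }
  if (singleton_fraction < 0 || singleton_fraction > 1) {
    stop("singleton_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(common_variant_counts > 2L * n_patients)) {
    stop("a planted observation count exceeds 2 * n_patients", call. = FALSE)
  }
  if (sum(class_counts) != n_distinct_variants) {
    stop("class_counts must sum to n_distinct_variants", call. = FALSE)
  }
  n_singleton <- as.integer(round(singleton_fraction * n_distinct_variants))
  if (n_singleton + length(common_variant_counts) > n_distinct_variants) {
    stop("singletons plus common variants exceed the distinct total",
         call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients),
    ethnicity_weights = ethnicity_weights[ethnicity_levels] /
      sum(ethnicity_weights),
    n_distinct_variants = as.integer(n_distinct_variants),
    n_singleton = n_singleton,
    common_variant_counts = as.integer(common_variant_counts),
    hom_fraction = hom_fraction,
    class_counts = class_counts,
    group_exclusive_fraction = group_exclusive_fraction,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate a synthetic transcript model
#'
#' Builds a random multi-exon gene: an open reading frame of `n_codons`
#' amino acids plus one stop (no internal stops), partitioned into `n_exons`
#' exons of random sizes with random intron lengths. Defaults give a
#' CFTR-sized gene: 27 exons coding for a 1480-residue protein (CDS length
#' 4443 nt including the stop).
#'
#' @param seed integer seed; same seed, same model.
#' @param n_exons number of exons (>= 1).
#' @param n_codons protein length in amino acids (>= 2).
#' @param min_exon minimum exon width in bp.
#' @param intron_range inclusive bounds for intron lengths in bp.
#' @return a [transcript_model()] named `SYNTH1`.
#' @export
gen_transcript <- function(seed, n_exons = 27L, n_codons = 1480L,
                           min_exon = 12L, intron_range = c(60L, 3000L)) {
  n_exons <- as.integer(n_exons)
  n_codons <- as.integer(n_codons)
  if (n_exons < 1L || n_codons < 2L) {
    stop("need n_exons >= 1 and n_codons >= 2", call. = FALSE)
  }
  cds_len <- 3L * (n_codons + 1L)
  if (n_exons * min_exon > cds_len) {
    stop("exon count infeasible for this CDS length", call. = FALSE)
  }
  with_seed(seed, {
    codons <- c("ATG",
                sample(setdiff(names(Biostrings::GENETIC_CODE), .stop_codons),
                       n_codons - 1L, replace = TRUE),
                sample(.stop_codons, 1L))
    cds <- paste(codons, collapse = "")
    extra <- as.vector(stats::rmultinom(1L, cds_len - n_exons * min_exon,
                                        rep(1 / n_exons, n_exons)))
    widths <- min_exon + extra
    introns <- if (n_exons > 1L) {
      sample(seq(intron_range[1L], intron_range[2L]), n_exons - 1L,
             replace = TRUE)
    } else integer(0)
    starts <- integer(n_exons)
    ends <- integer(n_exons)
    pos <- 2001L  # leave upstream room for promoter coordinates
    for (i in seq_len(n_exons)) {
      starts[i] <- pos
      ends[i] <- pos + widths[i] - 1L
      pos <- ends[i] + 1L + if (i < n_exons) introns[i] else 0L
    }
    transcript_model("SYNTH1", starts, ends, cds)
  })
}

# draw one exonic variant of the requested class; returns a descriptor row
.draw_exonic <- function(model, target, used) {
  cds <- model$coding_sequence
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  for (attempt in seq_len(20000L)) {
    p <- sample.int(nchar(cds), 1L)
    ref <- substring(cds, p, p)
    ci <- codon_index(p)
    cstart <- 3L * (ci$codon - 1L) + 1L
    ref_codon <- substring(cds, cstart, cstart + 2L)
    for (alt in sample(setdiff(bases, ref))) {
      alt_codon <- ref_codon
      substr(alt_codon, ci$phase, ci$phase) <- alt
      ref_aa <- unname(code[ref_codon])
      alt_aa <- unname(code[alt_codon])
      cls <- if (ref_aa == alt_aa) "synonymous"
             else if (alt_aa == "*") "nonsense"
             else "missense"
      if (cls != target) next
      key <- sprintf("c.%d%s>%s", p, ref, alt)
      if (key %in% used) next
      return(variant_descriptor(p, 0L, FALSE, ref, alt))
    }
  }
  stop("could not place a ", target, " variant in this CDS", call. = FALSE)
}

# draw one intron-offset variant; splice = TRUE for |offset| <= halfwidth
.draw_intronic <- function(model, splice, used, deep_prob = 0.7,
                           max_depth = 200L) {
  jx <- transcript_junctions(model)
  if (nrow(jx) == 0L) stop("model has no introns", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  for (attempt in seq_len(20000L)) {
    row <- jx[sample.int(nrow(jx), 1L), ]
    donor <- sample(c(TRUE, FALSE), 1L)
    if (splice) {
      depth <- sample.int(2L, 1L)
    } else {
      hi <- min(row$intron_length, max_depth)
      depth <- if (stats::runif(1) < deep_prob && hi > 21L) {
        sample(21L:hi, 1L)
      } else {
        sample(3L:20L, 1L)
      }
    }
    anchor <- if (donor) row$donor_anchor else row$acceptor_anchor
    off <- if (donor) depth else -depth
    ref <- sample(bases, 1L)
    alt <- sample(setdiff(bases, ref), 1L)
    key <- sprintf("c.%d%+dd", anchor, off)  # position-level dedup
    if (key %in% used) next
    return(variant_descriptor(anchor, off, FALSE, ref, alt))
  }
  stop("could not place an intron-offset variant", call. = FALSE)
}

#' Generate a synthetic referral cohort
#'
#' Plants `spec$n_distinct_variants` distinct variants across the six
#' functional classes, assigns exact observation counts (common
#' polymorphisms at their planted counts, singletons once, the remainder at
#' 2–9 observations with occasional homozygotes), and distributes carriers
#' over patients whose ethnicities follow the spec weights. A configurable
#' fraction of non-common variants is confined to a single ethnicity group,
#' producing the ethnic-specific structure the stratified summary measures.
#'
#' @param spec a [cohort_spec()].
#' @param model a [transcript_model()] with at least one intron when the
#'   class mix requests intronic or splice-site variants.
#' @return list with `observations` (patient_id, ethnicity, key, zygosity),
#'   `patients` (patient_id, ethnicity), and `truth`: one row per planted
#'   variant with `key`, `class`, `planted_count`, `is_singleton`,
#'   `is_common`, `exclusive_group` (`NA` when carriers were drawn
#'   cohort-wide) and `group_support` (`;`-joined groups actually carrying
#'   it).
#' @export
gen_cohort <- function(spec, model) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(model, "transcript_model"))
  if (n_introns(model) == 0L &&
      sum(spec$class_counts[c("intronic", "splice_site")]) > 0L) {
    stop("class mix requests intron variants but the model has no introns",
         call. = FALSE)
  }
  with_seed(spec$seed, {
    used <- character(0)
    rows <- list()
    classes <- character(0)
    for (cls in names(spec$class_counts)) {
      for (i in seq_len(spec$class_counts[[cls]])) {
        d <- switch(cls,
          promoter = {
            repeat {
              up <- sample.int(2000L, 1L)
              ref <- sample(c("A", "C", "G", "T"), 1L)
              alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
              dd <- variant_descriptor(up, 0L, TRUE, ref, alt)
              if (!sprintf("u%d", up) %in% used) break
            }
            used <- c(used, sprintf("u%d", up))
            dd
          },
          intronic = {
            dd <- .draw_intronic(model, splice = FALSE, used)
            used <- c(used, sprintf("c.%d%+dd", dd$coding_pos, dd$intron_offset))
            dd
          },
          splice_site = {
            dd <- .draw_intronic(model, splice = TRUE, used)
            used <- c(used, sprintf("c.%d%+dd", dd$coding_pos, dd$intron_offset))
            dd
          },
          {
            dd <- .draw_exonic(model, cls, used)
            used <- c(used, dd$key)
            dd
          })
        rows[[length(rows) + 1L]] <- d
        classes <- c(classes, cls)
      }
    }
    variants <- do.call(rbind, rows)
    variants$class <- classes
    n_var <- nrow(variants)

    # planted observation counts: common variants get the exact headline
    # counts (classes mirroring the reported ones: missense, 2x synonymous,
    # intronic, when available), singletons one observation, the rest 2-9
    n_common <- length(spec$common_variant_counts)
    want_cls <- c("missense", "synonymous", "synonymous", "intronic")
    common_idx <- integer(0)
    for (j in seq_len(n_common)) {
      cand <- setdiff(which(variants$class == want_cls[min(j, 4L)]), common_idx)
      if (length(cand) == 0L) cand <- setdiff(seq_len(n_var), common_idx)
      common_idx <- c(common_idx, cand[1L])
    }
    rest <- setdiff(seq_len(n_var), common_idx)
    singleton_idx <- sort(sample(rest, spec$n_singleton))
    mid_idx <- setdiff(rest, singleton_idx)

    counts <- integer(n_var)
    counts[common_idx] <- spec$common_variant_counts
    counts[singleton_idx] <- 1L
    counts[mid_idx] <- sample(2:9, length(mid_idx), replace = TRUE)

    patients <- data.frame(
      patient_id = sprintf("P%04d", seq_len(spec$n_patients)),
      ethnicity = sample(names(spec$ethnicity_weights), spec$n_patients,
                         replace = TRUE, prob = spec$ethnicity_weights),
      stringsAsFactors = FALSE
    )
    by_group <- split(patients$patient_id, patients$ethnicity)

    obs <- vector("list", n_var)
    exclusive_group <- rep(NA_character_, n_var)
    for (v in seq_len(n_var)) {
      cnt <- counts[v]
      n_hom <- max(cnt - spec$n_patients,
                   stats::rbinom(1L, cnt %/% 2L, spec$hom_fraction))
      n_hom <- min(n_hom, cnt %/% 2L)
      n_carrier <- cnt - n_hom
      confine <- !(v %in% common_idx) &&
        stats::runif(1) < spec$group_exclusive_fraction
      pool <- patients$patient_id
      if (confine) {
        fits <- names(by_group)[lengths(by_group) >= n_carrier]
        if (length(fits) > 0L) {
          wts <- spec$ethnicity_weights[fits]
          g <- sample(fits, 1L, prob = wts / sum(wts))
          pool <- by_group[[g]]
          exclusive_group[v] <- g
        }
      }
      carriers <- sample(pool, n_carrier)
      zyg <- rep("het", n_carrier)
      if (n_hom > 0L) zyg[seq_len(n_hom)] <- "hom"
      obs[[v]] <- data.frame(patient_id = carriers,
                             key = variants$key[v],
                             zygosity = zyg,
                             stringsAsFactors = FALSE)
    }
    observations <- do.call(rbind, obs)
    observations$ethnicity <- patients$ethnicity[
      match(observations$patient_id, patients$patient_id)]
    observations <- observations[order(observations$patient_id,
                                       observations$key),
                                 c("patient_id", "ethnicity", "key",
                                   "zygosity")]
    rownames(observations) <- NULL

    support <- tapply(observations$ethnicity, observations$key,
                      function(g) paste(sort(unique(g)), collapse = ";"))
    truth <- data.frame(
      key = variants$key,
      class = variants$class,
      coding_pos = variants$coding_pos,
      intron_offset = variants$intron_offset,
      upstream = variants$upstream,
      planted_count = counts,
      is_singleton = seq_len(n_var) %in% singleton_idx,
      is_common = seq_len(n_var) %in% common_idx,
      exclusive_group = exclusive_group,
      group_support = unname(support[variants$key]),
      stringsAsFactors = FALSE
    )
    list(observations = observations, patients = patients, truth = truth)
  })
}

#' Snapshot generation parameters
#'
#' Per-database inclusion probabilities default to the coverage a
#' locus-specific database (0.85), a disease-mutation database (0.64) and a
#' general SNP catalogue (0.40) showed for this gene, with 21 variants
#' forced novel (absent from all three).
#'
#' @param inclusion_probs named per-database probabilities in `[0, 1]`.
#' @param forced_novel_count number of keys excluded from every snapshot.
#' @param seed mandatory integer seed.
#' @return a `snapshot_spec` list.
#' @export
snapshot_spec <- function(inclusion_probs = c(CFMDB = 0.85, HGMD = 0.64,
                                              dbSNP132 = 0.40),
                          forced_novel_count = 21L, seed) {
  if (missing(seed)) stop("snapshot_spec() requires a seed", call. = FALSE)
  if (any(inclusion_probs < 0 | inclusion_probs > 1)) {
    stop("inclusion probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(names(inclusion_probs)) || anyDuplicated(names(inclusion_probs))) {
    stop("inclusion_probs must have unique database names", call. = FALSE)
  }
  structure(list(
    inclusion_probs = inclusion_probs,
    forced_novel_count = as.integer(forced_novel_count),
    seed = as.integer(seed)
  ), class = "snapshot_spec")
}

#' Generate database snapshots over a variant set
#'
#' Exactly `forced_novel_count` keys are withheld from every snapshot; each
#' remaining key's membership triple is drawn from independent Bernoulli
#' draws conditioned on inclusion in at least one database (rejection
#' sampling), so the novel count is exact by construction and each
#' database's marginal coverage of known variants is
#' `p / (1 - prod(1 - p))`.
#'
#' @param spec a [snapshot_spec()].
#' @param variant_keys canonical keys to allocate.
#' @return list with `snapshots` (list of [database_snapshot()]) and
#'   `novel_keys` (the withheld keys, sorted).
#' @export
gen_snapshots <- function(spec, variant_keys) {
  stopifnot(inherits(spec, "snapshot_spec"))
  variant_keys <- unique(variant_keys)
  if (spec$forced_novel_count > length(variant_keys)) {
    stop("forced_novel_count exceeds the number of variant keys", call. = FALSE)
  }
  p <- spec$inclusion_probs
  with_seed(spec$seed, {
    novel <- sort(sample(variant_keys, spec$forced_novel_count))
    known <- setdiff(variant_keys, novel)
    if (length(known) > 0L && all(p == 0)) {
      stop("all inclusion probabilities are 0 but known variants remain",
           call. = FALSE)
    }
    member <- matrix(FALSE, nrow = length(known), ncol = length(p),
                     dimnames = list(known, names(p)))
    for (i in seq_along(known)) {
      repeat {
        draw <- stats::runif(length(p)) < p
        if (any(draw)) break
      }
      member[i, ] <- draw
    }
    snapshots <- lapply(names(p), function(db) {
      database_snapshot(db, rownames(member)[member[, db]])
    })
    names(snapshots) <- names(p)
    list(snapshots = snapshots, novel_keys = novel)
  })
}

.default_overall_tiers <- c(pathogenic = 97L, suspected_pathogenic = 8L,
                            benign = 37L, unknown_significance = 30L,
                            suspected_benign = 6L, unrecorded = 6L)
.default_novel_tiers <- c(pathogenic = 4L, suspected_pathogenic = 0L,
                          benign = 8L, unknown_significance = 6L,
                          suspected_benign = 3L, unrecorded = 0L)

#' Generate evidence bundles that plant a target tier mix
#'
#' Builds a per-variant evidence table whose rule-based classification
#' reproduces a target tier distribution, honouring the rule ladder's
#' constraints: suspected_benign (via the heuristic rule) needs a
#' synonymous or deep-intronic variant, unknown_significance needs a variant
#' those heuristics do not catch, novel variants can carry literature but
#' not database assertions, and database assertions only name databases that
#' actually contain the key. When the randomly drawn novel set lacks enough
#' compatible variants for a quota, the shortfall is reassigned to a
#' compatible tier; the returned `truth` records what was actually planted.
#'
#' @param annotations data.frame from [annotate_variants()] for every
#'   distinct variant.
#' @param snapshots list of [database_snapshot()] (for assertion sources).
#' @param novel_keys keys absent from every snapshot.
#' @param seed integer seed.
#' @param overall_tiers named quotas over all variants (default
#'   97/8/37/30/6/6).
#' @param novel_tiers named quotas over the novel subset (default 4 path, 8
#'   benign, 3 suspected benign, 6 unknown).
#' @param common_threshold frequency used when planting common variants as
#'   benign.
#' @return list with `evidence` (classifier input) and `truth`
#'   (`key`, `planted_tier`).
#' @export
gen_evidence <- function(annotations, snapshots, novel_keys, seed,
                         overall_tiers = .default_overall_tiers,
                         novel_tiers = .default_novel_tiers,
                         common_threshold = 0.01) {
  n <- nrow(annotations)
  if (sum(overall_tiers) != n) {
    stop("overall_tiers must sum to the number of variants", call. = FALSE)
  }
  if (sum(novel_tiers) != length(novel_keys)) {
    stop("novel_tiers must sum to the number of novel keys", call. = FALSE)
  }
  if (any(novel_tiers > overall_tiers)) {
    stop("novel tier quotas exceed overall quotas", call. = FALSE)
  }
  synod <- grepl("synonymous", annotations$labels) |
    (!is.na(annotations$deep_intronic) & annotations$deep_intronic)
  is_novel <- annotations$key %in% novel_keys

  with_seed(seed, {
    tier <- rep(NA_character_, n)
    take <- function(idx, k) {
      idx <- idx[is.na(tier[idx])]
      if (k <= 0L || length(idx) == 0L) return(integer(0))
      idx[sample.int(length(idx), min(k, length(idx)))]
    }
    # novel subset first: the constrained tiers, then the free ones
    plant <- function(subset_idx, quotas, allow_db_assert) {
      q <- quotas
      sel <- take(subset_idx[synod[subset_idx]], q[["suspected_benign"]])
      tier[sel] <<- "suspected_benign"
      short <- q[["suspected_benign"]] - length(sel)
      if (short > 0L && allow_db_assert) {
        # non-novel variants can reach suspected_benign via a limited
        # database assertion regardless of class
        sel2 <- take(subset_idx, short)
        tier[sel2] <<- "suspected_benign"
        short <- short - length(sel2)
      }
      q[["unknown_significance"]] <- q[["unknown_significance"]] + short
      sel <- take(subset_idx[!synod[subset_idx]],
                  q[["unknown_significance"]])
      tier[sel] <<- "unknown_significance"
      short <- q[["unknown_significance"]] - length(sel)
      q[["benign"]] <- q[["benign"]] + short  # always plantable
      for (t in c("pathogenic", "suspected_pathogenic", "benign",
                  "unrecorded")) {
        sel <- take(subset_idx, q[[t]])
        tier[sel] <<- t
      }
    }
    plant(which(is_novel), novel_tiers, allow_db_assert = FALSE)
    remaining <- overall_tiers - table(factor(tier, names(overall_tiers)))
    remaining <- pmax(as.integer(remaining), 0L)
    names(remaining) <- names(overall_tiers)
    plant(which(!is_novel), remaining, allow_db_assert = TRUE)
    tier[is.na(tier)] <- "unknown_significance"  # unreachable fallback

    # snapshot membership lookup for assertion sources
    dbs_for <- function(key) {
      nm <- names(snapshots)[vapply(snapshots,
                                    function(s) key %in% s$keys, logical(1))]
      nm
    }
    ev <- data.frame(
      key = annotations$key,
      db_assertions = "none",
      literature_status = "none",
      population_frequency = NA_real_,
      insilico_score = NA_real_,
      recorded = TRUE,
      labels = annotations$labels,
      deep_intronic = annotations$deep_intronic,
      stringsAsFactors = FALSE
    )
    for (i in seq_len(n)) {
      t_i <- tier[i]
      dbs <- if (is_novel[i]) character(0) else dbs_for(ev$key[i])
      pick_db <- function() sample(dbs, 1L)
      if (t_i == "pathogenic") {
        if (length(dbs) > 0L) {
          ev$db_assertions[i] <- paste0(pick_db(), ":pathogenic")
        } else {
          ev$literature_status[i] <- "reported_pathogenic"
        }
        ev$insilico_score[i] <- stats::runif(1, 0.7, 1)
      } else if (t_i == "suspected_pathogenic") {
        if (length(dbs) > 0L) {
          ev$db_assertions[i] <- paste0(pick_db(), ":suspected_pathogenic")
        } else {
          # novel quota for this tier is 0 by default; keep total correct
          tier[i] <- "unknown_significance"
        }
      } else if (t_i == "benign") {
        if (length(dbs) > 0L && stats::runif(1) < 0.5) {
          ev$db_assertions[i] <- paste0(pick_db(), ":benign")
        } else if (is_novel[i]) {
          ev$literature_status[i] <- "reported_benign"
        } else {
          ev$population_frequency[i] <- stats::runif(1, common_threshold, 0.5)
        }
      } else if (t_i == "suspected_benign") {
        if (!synod[i]) {
          ev$db_assertions[i] <- paste0(pick_db(), ":suspected_benign")
        } else if (stats::runif(1) < 0.5) {
          ev$population_frequency[i] <- stats::runif(1, 0, common_threshold * 0.9)
        }
      } else if (t_i == "unknown_significance") {
        if (stats::runif(1) < 0.5) {
          ev$insilico_score[i] <- stats::runif(1, 0.2, 0.8)
        }
      } else if (t_i == "unrecorded") {
        ev$recorded[i] <- FALSE
      }
    }
    list(evidence = ev,
         truth = data.frame(key = annotations$key, planted_tier = tier,
                            stringsAsFactors = FALSE))
  })
}

#' Write a full fixture set to a directory
#'
#' Generates transcript, cohort, snapshots and evidence under one master
#' seed and writes them in the formats the pipeline reads (GFF3 + FASTA,
#' TSV), together with ground-truth TSVs.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed; module seeds are derived from it.
#' @param spec optional [cohort_spec()] (default spec under the derived
#'   seed).
#' @param snap_spec optional [snapshot_spec()].
#' @return invisibly, a list with all generated objects and the file paths.
#' @export
write_fixtures <- function(dir, seed, spec = NULL, snap_spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  if (is.null(spec)) spec <- cohort_spec(seed = seed + 1L)
  if (is.null(snap_spec)) snap_spec <- snapshot_spec(seed = seed + 2L)
  model <- gen_transcript(seed)
  cohort <- gen_cohort(spec, model)
  ann <- annotate_variants(parse_c(unique(cohort$truth$key)), model)
  snaps <- gen_snapshots(snap_spec, cohort$truth$key)
  evid <- gen_evidence(ann, snaps$snapshots, snaps$novel_keys,
                       seed = seed + 3L)
  paths <- list(
    gff = file.path(dir, "transcript.gff3"),
    fasta = file.path(dir, "cds.fa"),
    cohort = file.path(dir, "cohort.tsv"),
    evidence = file.path(dir, "evidence.tsv"),
    truth_variants = file.path(dir, "truth_variants.tsv"),
    truth_tiers = file.path(dir, "truth_tiers.tsv")
  )
  write_transcript_model(model, paths$gff, paths$fasta)
  write_cohort(cohort$observations, paths$cohort)
  utils::write.table(evid$evidence, paths$evidence, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$truth, paths$truth_variants, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(evid$truth, paths$truth_tiers, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$snapshots <- character(0)
  for (db in names(snaps$snapshots)) {
    p <- file.path(dir, sprintf("snapshot_%s.tsv", db))
    writeLines(c(sprintf("# %s snapshot (synthetic)", db),
                 snaps$snapshots[[db]]$keys), p)
    paths$snapshots[db] <- p
  }
  invisible(list(model = model, cohort = cohort, annotations = ann,
                 snapshots = snaps$snapshots, novel_keys = snaps$novel_keys,
                 evidence = evid$evidence, tier_truth = evid$truth,
                 paths = paths))
}
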