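#' @title Stepwise rule-based clinical classification
#' @description
#' Implements the laboratory-style decision ladder for assigning each variant
#' one of six significance tiers: pathogenic, suspected_pathogenic, benign,
#' suspected_benign, unknown_significance, or unrecorded (legacy variants
#' that were never scored). Evidence per variant comprises database
#' assertions, literature status, a population frequency, an optional
#' in-silico consensus score, the functional class labels and a
#' deep-intronic flag. The ladder is:
#'
#' 1. A database or literature pathogenic assertion wins: full assertion ->
#'    pathogenic, weaker/limited ("suspected") assertion ->
#'    suspected_pathogenic.
#' 2. Otherwise a benign assertion wins: benign -> benign, suspected ->
#'    suspected_benign.
#' 3. Absent contrary evidence: population frequency at or above the
#'    common-variant threshold -> benign; synonymous or deep-intronic
#'    variants with unknown or sub-threshold frequency -> suspected_benign.
#' 4. Everything else -> unknown_significance.
#' 5. In-silico scores may only nudge between the uncertain tiers (a strong
#'    consensus moves unknown_significance to suspected_pathogenic or
#'    suspected_benign); no classification is ever based solely on in-silico
#'    predictors, so they can never set pathogenic or benign.
#'
#' Every evaluated rule is appended to a `rule_trace`, so each call is
#' auditable and replayable.
#' @name clinical_classifier
NULL

.tier_levels <- c("pathogenic", "suspected_pathogenic", "benign",
                  "unknown_significance", "suspected_benign", "unrecorded")

.assertion_levels <- c("pathogenic", "suspected_pathogenic",
                       "benign", "suspected_benign")

# parse "HGMD:pathogenic;CFMDB:benign" -> character vector of levels
.assertion_set <- function(db_assertions) {
  if (is.na(db_assertions) || db_assertions %in% c("", "none")) return(character(0))
  parts <- strsplit(db_assertions, ";", fixed = TRUE)[[1L]]
  lev <- sub("^[^:]*:", "", parts)
  bad <- !lev %in% .assertion_levels
  if (any(bad)) {
    stop("unknown database assertion level(s): ",
         paste(unique(lev[bad]), collapse = ", "), call. = FALSE)
  }
  lev
}

#' Classify variants from evidence bundles
#'
#' @param evidence data.frame, one row per variant, with columns:
#'   `key`; `db_assertions` (semicolon-joined `DB:level` pairs with levels in
#'   pathogenic / suspected_pathogenic / benign / suspected_benign, or
#'   `"none"`); `literature_status` (`reported_pathogenic`,
#'   `reported_benign`, `none`); `population_frequency` (fraction in `[0,1]`
#'   or `NA` for unknown); `insilico_score` (consensus deleteriousness in
#'   `[0,1]`, `NA` if unscored); `recorded` (logical; `FALSE` marks legacy
#'   variants with no recorded significance); `labels` (`;`-joined class
#'   labels from [annotate_variants()]); `deep_intronic` (logical, `NA` for
#'   exonic/promoter).
#' @param common_threshold population frequency at or above which a variant
#'   counts as common (default 0.01; laboratories differ, so this is a
#'   parameter, and reports echo it).
#' @param insilico_high,insilico_low consensus score bounds beyond which an
#'   unknown_significance call is nudged to suspected_pathogenic /
#'   suspected_benign (defaults 0.9 / 0.1).
#' @return data.frame `key`, `tier`, `rule_trace` (pipe-joined fired rules;
#'   empty only for unrecorded).
#' @examples
#' e <- data.frame(key = "c.869+21A>G", db_assertions = "none",
#'                 literature_status = "none", population_frequency = NA,
#'                 insilico_score = NA, recorded = TRUE,
#'                 labels = "intronic", deep_intronic = TRUE)
#' classify_variants(e)$tier  # "suspected_benign"
#' @export
classify_variants <- function(evidence, common_threshold = 0.01,
                              insilico_high = 0.9, insilico_low = 0.1) {
  freq <- evidence$population_frequency
  if (any(!is.na(freq) & (freq < 0 | freq > 1))) {
    stop("population frequencies must lie in [0, 1]", call. = FALSE)
  }
  n <- nrow(evidence)
  tier <- character(n)
  trace <- character(n)
  for (i in seq_len(n)) {
    if (!isTRUE(evidence$recorded[i])) {
      tier[i] <- "unrecorded"
      trace[i] <- ""
      next
    }
    fired <- character(0)
    asserts <- .assertion_set(evidence$db_assertions[i])
    lit <- evidence$literature_status[i]
    labels <- strsplit(evidence$labels[i], ";", fixed = TRUE)[[1L]]
    t_i <- NA_character_

    if ("pathogenic" %in% asserts || identical(lit, "reported_pathogenic")) {
      t_i <- "pathogenic"
      fired <- c(fired, "R1:pathogenic-assertion->pathogenic")
    } else if ("suspected_pathogenic" %in% asserts) {
      t_i <- "suspected_pathogenic"
      fired <- c(fired, "R1:limited-pathogenic-assertion->suspected_pathogenic")
    } else if ("benign" %in% asserts || identical(lit, "reported_benign")) {
      t_i <- "benign"
      fired <- c(fired, "R2:benign-assertion->benign")
    } else if ("suspected_benign" %in% asserts) {
      t_i <- "suspected_benign"
      fired <- c(fired, "R2:limited-benign-assertion->suspected_benign")
    } else if (!is.na(freq[i]) && freq[i] >= common_threshold) {
      t_i <- "benign"
      fired <- c(fired, sprintf("R3:common-frequency(%.4g>=%.4g)->benign",
                                freq[i], common_threshold))
    } else if ("synonymous" %in% labels || isTRUE(evidence$deep_intronic[i])) {
      t_i <- "suspected_benign"
      fired <- c(fired, "R3:synonymous-or-deep-intronic->suspected_benign")
    } else {
      t_i <- "unknown_significance"
      fired <- c(fired, "R4:no-evidence->unknown_significance")
    }

    score <- evidence$insilico_score[i]
    if (!is.na(score) && t_i == "unknown_significance") {
      if (score >= insilico_high) {
        t_i <- "suspected_pathogenic"
        fired <- c(fired, "R5:insilico-damaging->suspected_pathogenic")
      } else if (score <= insilico_low) {
        t_i <- "suspected_benign"
        fired <- c(fired, "R5:insilico-tolerated->suspected_benign")
      }
    }
    tier[i] <- t_i
    trace[i] <- paste(fired, collapse = "|")
  }
  data.frame(key = evidence$key, tier = tier, rule_trace = trace,
             stringsAsFactors = FALSE)
}

#' Tally clinical tiers
#'
#' @param calls data.frame from [classify_variants()].
#' @return data.frame `tier`, `n_variants` over the six tiers (fixed order),
#'   with attribute `total` equal to the number of calls.
#' @export
tally_tiers <- function(calls) {
  tiers <- if (nrow(calls) > 0L) calls$tier else character(0)
  bad <- !tiers %in% .tier_levels
  if (any(bad)) {
    stop("unknown tier(s): ", paste(unique(tiers[bad]), collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(tiers, levels = .tier_levels))
  out <- data.frame(tier = .tier_levels, n_variants = as.integer(counts))
  attr(out, "total") <- nrow(calls)
  out
}

#' Read a per-variant evidence TSV
#'
#' Columns as documented in [classify_variants()]; `NA` and empty cells mean
#' unknown frequency / unscored in-silico.
#'
#' @param path TSV path.
#' @return evidence data.frame.
#' @export
read_evidence <- function(path) {
  if (!file.exists(path)) stop("evidence file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("key", "db_assertions", "literature_status",
            "population_frequency", "insilico_score", "recorded",
            "labels", "deep_intronic")
  if (!all(need %in% names(tab))) {
    stop("evidence file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab$key <- canonical_key(tab$key)
  tab$db_assertions[is.na(tab$db_assertions)] <- "none"
  tab$literature_status[is.na(tab$literature_status)] <- "none"
  tab$recorded <- as.logical(tab$recorded)
  tab$deep_intronic <- as.logical(tab$deep_intronic)
  tab
}

#' Write per-variant clinical calls as TSV (tier plus rule trace)
#' @param calls data.frame from [classify_variants()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
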