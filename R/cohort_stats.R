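#' Self-reported ethnicity categories
#'
#' The eight analysis groups used for stratified summaries. Intake forms may
#' offer more granular choices (e.g. Mediterranean, or combinations); those
#' fold into `Other/Mixed` before analysis, which is also why `Other/Mixed`
#' is excluded from ethnic-specific accounting.
#'
#' @export
ethnicity_levels <- c("African American", "Ashkenazi Jewish", "Asian/Oriental",
                      "Caucasian", "Hispanic", "Middle Eastern",
                      "Native American", "Other/Mixed")

#' Read a cohort observation file
#'
#' TSV with header columns `patient_id`, `ethnicity`, `variant`, `zygosity`;
#' one row per patient-variant observation. Variant strings are
#' canonicalized, ethnicities validated against [ethnicity_levels], zygosity
#' must be `het` or `hom`, and `(patient_id, variant)` pairs must be unique.
#'
#' @param path TSV path.
#' @return observations data.frame: `patient_id`, `ethnicity`, `key`,
#'   `zygosity`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "ethnicity", "variant", "zygosity")
  if (!all(need %in% names(tab))) {
    stop("cohort file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("cohort file has no observations", call. = FALSE)
  bad_eth <- !tab$ethnicity %in% ethnicity_levels
  if (any(bad_eth)) {
    stop("unknown ethnicity value(s) at row(s) ",
         paste(utils::head(which(bad_eth), 10L), collapse = ", "), ": ",
         paste(unique(tab$ethnicity[bad_eth]), collapse = ", "), call. = FALSE)
  }
  bad_zyg <- !tab$zygosity %in% c("het", "hom")
  if (any(bad_zyg)) {
    stop("zygosity must be 'het' or 'hom'; offending row(s): ",
         paste(utils::head(which(bad_zyg), 10L), collapse = ", "), call. = FALSE)
  }
  obs <- data.frame(
    patient_id = as.character(tab$patient_id),
    ethnicity = tab$ethnicity,
    key = canonical_key(tab$variant),
    zygosity = tab$zygosity,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(obs[c("patient_id", "key")])) {
    dup <- which(duplicated(obs[c("patient_id", "key")]))
    stop("duplicate (patient_id, variant) pair(s) at row(s) ",
         paste(utils::head(dup, 10L), collapse = ", "), call. = FALSE)
  }
  obs
}

#' Write a cohort observation file
#' @param observations observations data.frame.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_cohort <- function(observations, path) {
  out <- data.frame(patient_id = observations$patient_id,
                    ethnicity = observations$ethnicity,
                    variant = observations$key,
                    zygosity = observations$zygosity)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Observation count of a variant
#'
#' A heterozygous carrier contributes one observation, a homozygous carrier
#' two (both alleles carry the variant).
#'
#' @param observations observations data.frame.
#' @param variant_key canonical key (vector allowed).
#' @return named integer vector of observation counts (0 for unseen keys).
#' @export
observation_count <- function(observations, variant_key) {
  w <- ifelse(observations$zygosity == "hom", 2L, 1L)
  vapply(variant_key,
         function(k) sum(w[observations$key == k]),
         integer(1))
}

#' Rank variants by observation count
#'
#' @param observations observations data.frame.
#' @param k number of top variants to return (>= 1); truncated to the number
#'   of distinct variants.
#' @return data.frame `key`, `observations`, descending by count with ties
#'   broken by canonical key order.
#' @export
most_common_variants <- function(observations, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1", call. = FALSE)
  w <- ifelse(observations$zygosity == "hom", 2L, 1L)
  counts <- tapply(w, observations$key, sum)
  out <- data.frame(key = names(counts), observations = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$observations, out$key), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, k)
}

#' Ethnic-stratified cohort summary
#'
#' Per ethnicity group: number of distinct patients, distinct variants
#' observed in the group, ethnic-specific variants (observed in exactly that
#' one group across the whole cohort) and the subset of those that are also
#' novel. `Other/Mixed` is a catch-all, not an ethnicity, so its
#' ethnic-specific cell is not applicable (`NA`); by default it still
#' participates in the exclusivity test, i.e. a variant seen in one named
#' group and in Other/Mixed is not specific to the named group. Percentages
#' are of the group's distinct-variant total, rounded half-up to 2 decimals.
#'
#' @param observations observations data.frame.
#' @param novel_keys character vector of novel variant keys (from
#'   [cross_reference()]).
#' @param count_other_mixed_support if `FALSE`, Other/Mixed observations are
#'   ignored when deciding whether a variant is specific to a named group.
#' @return data.frame with one row per group in [ethnicity_levels] order:
#'   `ethnicity`, `n_patients`, `total_snvs`, `ethnic_specific`,
#'   `ethnic_specific_pct`, `novel_ethnic_specific`,
#'   `novel_ethnic_specific_pct`. Specific cells are `NA` for Other/Mixed;
#'   percentage cells are `NA` where the group has no variants.
#' @export
ethnic_summary <- function(observations, novel_keys = character(0),
                           count_other_mixed_support = TRUE) {
  bad <- !observations$ethnicity %in% ethnicity_levels
  if (any(bad)) {
    stop("unknown ethnicity value(s): ",
         paste(unique(observations$ethnicity[bad]), collapse = ", "),
         call. = FALSE)
  }
  support_obs <- observations
  if (!count_other_mixed_support) {
    support_obs <- observations[observations$ethnicity != "Other/Mixed", ,
                                drop = FALSE]
  }
  support <- tapply(support_obs$ethnicity, support_obs$key,
                    function(g) unique(g), simplify = FALSE)
  single_group <- vapply(support, function(g) length(g) == 1L, logical(1))
  specific_group <- rep(NA_character_, length(support))
  specific_group[single_group] <- vapply(support[single_group], `[`, "", 1L)

  rows <- lapply(ethnicity_levels, function(g) {
    sub <- observations[observations$ethnicity == g, , drop = FALSE]
    keys <- unique(sub$key)
    total <- length(keys)
    if (g == "Other/Mixed") {
      spec <- NA_integer_
      # novel & ethnic-specific is still reported for Other/Mixed (a novel
      # variant seen only there is seen in no named group either)
      spec_keys <- names(support)[!is.na(specific_group) &
                                    specific_group == g]
    } else {
      spec_keys <- intersect(keys,
                             names(support)[!is.na(specific_group) &
                                              specific_group == g])
      spec <- length(spec_keys)
    }
    novel_spec <- length(intersect(spec_keys, novel_keys))
    data.frame(
      ethnicity = g,
      n_patients = length(unique(sub$patient_id)),
      total_snvs = total,
      ethnic_specific = spec,
      ethnic_specific_pct = if (is.na(spec)) NA_real_
                            else percent_of(spec, total),
      novel_ethnic_specific = novel_spec,
      novel_ethnic_specific_pct = percent_of(novel_spec, total),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an ethnic summary as a formatted TSV
#'
#' Cells are `count (percent%)` strings with the literal `N/A` for
#' non-applicable ethnic-specific cells.
#'
#' @param summary data.frame from [ethnic_summary()].
#' @param path output TSV path.
#' @return invisibly, the data.frame written.
#' @export
write_ethnic_table <- function(summary, path) {
  tab <- data.frame(
    ethnicity = summary$ethnicity,
    n_patients = summary$n_patients,
    total_snvs = summary$total_snvs,
    ethnic_specific = fmt_count_pct(summary$ethnic_specific,
                                    summary$total_snvs),
    novel_ethnic_specific = fmt_count_pct(summary$novel_ethnic_specific,
                                          summary$total_snvs),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
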