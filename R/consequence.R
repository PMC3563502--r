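#' Functional annotation of variants against a transcript model
#'
#' Each variant receives a non-empty set of class labels drawn from
#' \{promoter, splice_site, intronic, missense, nonsense, synonymous\}.
#' Positional labels come from [classify_region()]; exonic variants are then
#' translated by substituting the alternate base into the affected codon and
#' comparing amino acids under the standard nuclear genetic code
#' (`Biostrings::GENETIC_CODE`): identical residue is synonymous, a gained
#' stop is nonsense, anything else is missense (stop-loss and start-loss fold
#' into missense). For exonic variants the model's coding sequence must carry
#' the stated reference base; a mismatch is an error, never silently
#' re-anchored, because cohort files are trusted laboratory output.
#'
#' An exonic variant within `splice_halfwidth` bases of an exon/intron
#' boundary additionally carries the `splice_site` label only when
#' `exonic_splice = TRUE`; the default counts the flanking intronic bases
#' only, matching the canonical GT/AG dinucleotide view of a splice site.
#'
#' @param d descriptor data.frame ([parse_c()] output).
#' @param model a `transcript_model`.
#' @param splice_halfwidth intronic bases per boundary side that count as
#'   splice site (default 2).
#' @param exonic_splice also tag exonic bases within `splice_halfwidth` of a
#'   boundary as splice site (default `FALSE`).
#' @param deep_intronic_threshold depth in bp beyond which an intron-offset
#'   variant is flagged deep intronic (strict `>`, default 20).
#' @return data.frame, one row per variant: `key`, `labels` (`;`-joined),
#'   `region`, `intron_offset`, `upstream_offset`, `deep_intronic` (`NA` for
#'   exonic/promoter), `codon`, `ref_aa`, `alt_aa`, `protein_change`
#'   (one-letter, `*` for stop; `NA` for non-exonic).
#' @examples
#' m <- transcript_model("TOY", 1, 9, "ATGAAATAG")
#' annotate_variants(parse_c("c.4A>T"), m)$labels  # "nonsense"
#' @export
annotate_variants <- function(d, model, splice_halfwidth = 2L,
                              exonic_splice = FALSE,
                              deep_intronic_threshold = 20L) {
  region <- classify_region(d, model, splice_halfwidth = splice_halfwidth)
  n <- nrow(d)
  labels <- region$label
  codon <- rep(NA_integer_, n)
  ref_aa <- rep(NA_character_, n)
  alt_aa <- rep(NA_character_, n)
  deep <- rep(NA, n)

  in_intron <- region$label %in% c("intronic", "splice_site")
  deep[in_intron] <- is_deep_intronic(region[in_intron, , drop = FALSE],
                                      threshold = deep_intronic_threshold)

  ex_rows <- which(region$label == "exonic")
  if (length(ex_rows) > 0L) {
    cds <- model$coding_sequence
    pos <- d$coding_pos[ex_rows]
    have <- substring(cds, pos, pos)
    mism <- have != d$ref[ex_rows]
    if (any(mism)) {
      stop("reference allele mismatch against coding sequence: ",
           paste(sprintf("%s (CDS has %s)", d$key[ex_rows][mism], have[mism]),
                 collapse = ", "), call. = FALSE)
    }
    ci <- codon_index(pos)
    code <- Biostrings::GENETIC_CODE
    for (j in seq_along(ex_rows)) {
      i <- ex_rows[j]
      cstart <- 3L * (ci$codon[j] - 1L) + 1L
      ref_codon <- substring(cds, cstart, cstart + 2L)
      alt_codon <- ref_codon
      substr(alt_codon, ci$phase[j], ci$phase[j]) <- d$alt[i]
      codon[i] <- ci$codon[j]
      ref_aa[i] <- unname(code[ref_codon])
      alt_aa[i] <- unname(code[alt_codon])
      labels[i] <- if (ref_aa[i] == alt_aa[i]) "synonymous"
                   else if (alt_aa[i] == "*") "nonsense"
                   else "missense"
      if (isTRUE(exonic_splice)) {
        jx <- transcript_junctions(model)
        p <- d$coding_pos[i]
        near <- any(jx$donor_anchor - p >= 0L & jx$donor_anchor - p < splice_halfwidth) ||
                any(p - jx$acceptor_anchor >= 0L & p - jx$acceptor_anchor < splice_halfwidth)
        if (near) labels[i] <- paste(labels[i], "splice_site", sep = ";")
      }
    }
  }
  data.frame(
    key = d$key,
    labels = labels,
    region = region$label,
    intron_offset = region$intron_offset,
    upstream_offset = region$upstream_offset,
    deep_intronic = deep,
    codon = codon,
    ref_aa = ref_aa,
    alt_aa = alt_aa,
    protein_change = ifelse(is.na(codon), NA_character_,
                            paste0("p.", ref_aa, codon, alt_aa)),
    stringsAsFactors = FALSE
  )
}

.class_levels <- c("missense", "intronic", "synonymous", "splice_site",
                   "nonsense", "promoter")

#' Tally variant class labels
#'
#' Counts variants per functional class. A multi-label variant (e.g. missense
#' and splice site) increments every class it carries, so the column sum can
#' exceed the distinct-variant total; both are reported and never forced to
#' agree.
#'
#' @param annotations data.frame from [annotate_variants()], one row per
#'   distinct variant.
#' @return data.frame with columns `class` and `n_variants` (fixed class
#'   order), with attributes `n_distinct` (number of variants tallied) and
#'   `column_sum`.
#' @export
tally_classes <- function(annotations) {
  lab <- if (nrow(annotations) > 0L) {
    unlist(strsplit(annotations$labels, ";", fixed = TRUE))
  } else character(0)
  counts <- table(factor(lab, levels = .class_levels))
  out <- data.frame(class = .class_levels, n_variants = as.integer(counts))
  attr(out, "n_distinct") <- nrow(annotations)
  attr(out, "column_sum") <- sum(out$n_variants)
  out
}
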