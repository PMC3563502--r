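#' Construct a transcript model
#'
#' A transcript model holds the exon architecture and coding sequence that
#' anchor every coordinate computation in the package. Coordinates follow the
#' HGVS c. convention: c.1 is the A of the initiator ATG, intronic positions
#' hang off the nearest exonic base (`c.N+k` after a donor, `c.N-k` before an
#' acceptor), and upstream positions are `c.-N`. Exons are given as 1-based
#' closed genomic intervals already ordered in transcription direction; no
#' genomic liftover or strand handling is performed beyond that ordering.
#'
#' @param gene_symbol gene name, e.g. `"CFTR"`.
#' @param exon_starts,exon_ends integer vectors of exon boundaries
#'   (1-based, closed, strictly increasing, non-overlapping).
#' @param coding_sequence CDS nucleotide string: starts with `ATG`, length a
#'   multiple of 3, final codon a stop.
#' @param cds_start_exon_offset position of the A of the ATG within the
#'   concatenated exonic sequence (1 when the first exonic base is c.1).
#' @return object of class `transcript_model`: the validated inputs plus
#'   derived per-exon coding spans and intron lengths.
#' @examples
#' m <- transcript_model("TOY", c(1, 101), c(9, 106), "ATGAAATTTTAG")
#' cds_length(m)  # 12
#' @export
transcript_model <- function(gene_symbol, exon_starts, exon_ends,
                             coding_sequence, cds_start_exon_offset = 1L) {
  exon_starts <- as.integer(exon_starts)
  exon_ends <- as.integer(exon_ends)
  n <- length(exon_starts)
  if (n < 1L || length(exon_ends) != n) {
    stop("need at least one exon, with matching starts and ends", call. = FALSE)
  }
  if (any(exon_ends < exon_starts)) {
    stop("exon end before exon start", call. = FALSE)
  }
  if (n > 1L && any(exon_starts[-1L] <= exon_ends[-n])) {
    stop("exons must be non-overlapping and strictly ordered", call. = FALSE)
  }
  cds <- toupper(as.character(coding_sequence))
  if (nchar(cds) %% 3L != 0L) {
    stop("coding sequence length must be divisible by 3", call. = FALSE)
  }
  if (grepl("[^ACGT]", cds)) {
    stop("coding sequence may contain only A/C/G/T", call. = FALSE)
  }
  if (substr(cds, 1L, 3L) != "ATG") {
    stop("coding sequence must begin with ATG", call. = FALSE)
  }
  last_codon <- substr(cds, nchar(cds) - 2L, nchar(cds))
  if (!last_codon %in% c("TAA", "TAG", "TGA")) {
    stop("coding sequence must end in a stop codon", call. = FALSE)
  }
  off <- as.integer(cds_start_exon_offset)
  widths <- exon_ends - exon_starts + 1L
  if (off < 1L || sum(widths) < off - 1L + nchar(cds)) {
    stop("exons too short to contain the CDS at the given start offset",
         call. = FALSE)
  }
  cumw <- cumsum(widths)
  # coding span of each exon (first > last for pure-UTR exons)
  first_cp <- pmax(1L, c(0L, cumw[-n]) + 1L - (off - 1L))
  last_cp <- pmin(nchar(cds), cumw - (off - 1L))
  structure(list(
    gene_symbol = as.character(gene_symbol),
    exons = data.frame(start = exon_starts, end = exon_ends, width = widths),
    cds_start_exon_offset = off,
    coding_sequence = cds,
    exon_first_cp = first_cp,
    exon_last_cp = last_cp,
    intron_lengths = if (n > 1L) exon_starts[-1L] - exon_ends[-n] - 1L
                     else integer(0)
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model: %s | %d exon(s), %d intron(s), CDS %d nt (%d codons)\n",
              x$gene_symbol, nrow(x$exons), n_introns(x), cds_length(x),
              cds_length(x) %/% 3L))
  invisible(x)
}

#' CDS length of a transcript model
#' @param model a `transcript_model`.
#' @return integer number of coding bases (including the stop codon).
#' @export
cds_length <- function(model) nchar(model$coding_sequence)

#' Number of introns of a transcript model
#' @param model a `transcript_model`.
#' @return integer, `n_exons - 1`.
#' @export
n_introns <- function(model) nrow(model$exons) - 1L

#' Exon/intron junction table
#'
#' One row per intron: the donor anchor (last coding base of the upstream
#' exon, the `N` of `c.N+k`), the acceptor anchor (first coding base of the
#' downstream exon, the `N` of `c.N-k`) and the intron length. This is the
#' lookup used to validate intron-offset descriptors.
#'
#' @param model a `transcript_model`.
#' @return data.frame with columns `intron`, `donor_anchor`,
#'   `acceptor_anchor`, `intron_length`.
#' @export
transcript_junctions <- function(model) {
  n <- nrow(model$exons)
  if (n < 2L) {
    return(data.frame(intron = integer(0), donor_anchor = integer(0),
                      acceptor_anchor = integer(0), intron_length = integer(0)))
  }
  data.frame(
    intron = seq_len(n - 1L),
    donor_anchor = model$exon_last_cp[-n],
    acceptor_anchor = model$exon_first_cp[-1L],
    intron_length = model$intron_lengths
  )
}

#' Map coding positions to codon number and phase
#'
#' With c.1 the A of the ATG, coding position `p` lies in codon
#' `floor((p - 1) / 3) + 1` at phase `((p - 1) mod 3) + 1`; e.g. c.1408 sits
#' at the first base of codon 470, which is why a substitution there is
#' annotated p.M470V. The mapping is a bijection: `p = 3 * (codon - 1) + phase`.
#'
#' @param coding_pos vector of positive integers.
#' @return data.frame with integer columns `codon` and `phase` (phase in 1..3).
#' @examples
#' codon_index(1408)  # codon 470, phase 1
#' @export
codon_index <- function(coding_pos) {
  coding_pos <- as.integer(coding_pos)
  if (length(coding_pos) == 0L || anyNA(coding_pos) || any(coding_pos < 1L)) {
    stop("coding positions must be positive integers", call. = FALSE)
  }
  data.frame(
    codon = (coding_pos - 1L) %/% 3L + 1L,
    phase = (coding_pos - 1L) %% 3L + 1L
  )
}

#' Classify variant positions relative to the gene architecture
#'
#' Assigns each descriptor one region label: `promoter` for any position
#' upstream of the translational start, `splice_site` for intronic offsets
#' within `splice_halfwidth` bases of an exon/intron boundary (the "four
#' positions flanking" each boundary when the halfwidth is 2: donor +1/+2 and
#' acceptor -1/-2), `intronic` for deeper offsets, and `exonic` otherwise.
#' Intron-offset descriptors are validated against the model: a `c.N+k`
#' anchor must be a donor-side exon-final base, `c.N-k` an acceptor-side
#' exon-first base, and `|k|` cannot exceed the intron length.
#'
#' @param d descriptor data.frame from [parse_c()] or [variant_descriptor()].
#' @param model a `transcript_model`.
#' @param splice_halfwidth number of intronic bases on each side of a
#'   boundary that count as splice site (default 2).
#' @return data.frame with columns `label` (character), `intron_offset`
#'   (signed integer, 0 when exonic/promoter) and `upstream_offset`
#'   (non-negative, >0 only for promoter).
#' @export
classify_region <- function(d, model, splice_halfwidth = 2L) {
  stopifnot(inherits(model, "transcript_model"))
  splice_halfwidth <- as.integer(splice_halfwidth)
  if (splice_halfwidth < 0L) stop("splice_halfwidth must be >= 0", call. = FALSE)
  jx <- transcript_junctions(model)
  n <- nrow(d)
  label <- character(n)
  for (i in seq_len(n)) {
    if (isTRUE(d$upstream[i])) {
      label[i] <- "promoter"
      next
    }
    o <- d$intron_offset[i]
    p <- d$coding_pos[i]
    if (o != 0L) {
      row <- if (o > 0L) which(jx$donor_anchor == p)
             else which(jx$acceptor_anchor == p)
      if (length(row) != 1L) {
        stop(sprintf("invalid intron anchor: c.%d%+d does not sit at an exon/intron boundary of %s",
                     p, o, model$gene_symbol), call. = FALSE)
      }
      if (abs(o) > jx$intron_length[row]) {
        stop(sprintf("intron offset %+d exceeds intron %d length (%d)",
                     o, jx$intron[row], jx$intron_length[row]), call. = FALSE)
      }
      label[i] <- if (abs(o) <= splice_halfwidth) "splice_site" else "intronic"
    } else {
      if (p > cds_length(model)) {
        stop(sprintf("coding position %d is beyond the CDS (length %d)",
                     p, cds_length(model)), call. = FALSE)
      }
      label[i] <- "exonic"
    }
  }
  data.frame(
    label = label,
    intron_offset = ifelse(label %in% c("splice_site", "intronic"),
                           d$intron_offset, 0L),
    upstream_offset = ifelse(label == "promoter", d$coding_pos, 0L)
  )
}

#' Deep-intronic test
#'
#' An intron-offset position is deep intronic when it lies more than
#' `threshold` base pairs into the intron (strict inequality: offset 21 is
#' deep at the default threshold of 20, offset 20 is not). Only meaningful
#' for intronic or splice-site regions; other labels are a contract
#' violation.
#'
#' @param region data.frame from [classify_region()].
#' @param threshold intronic depth cut-off in base pairs (default 20).
#' @return logical vector.
#' @export
is_deep_intronic <- function(region, threshold = 20L) {
  if (any(!region$label %in% c("intronic", "splice_site"))) {
    stop("is_deep_intronic() applies only to intronic/splice_site regions",
         call. = FALSE)
  }
  abs(region$intron_offset) > as.integer(threshold)
}
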