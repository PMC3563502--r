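#' Read a transcript model from GFF3 + FASTA
#'
#' The on-disk representation is a GFF3 file holding `exon` features (the
#' architecture) and `CDS` features (the coding span across those exons),
#' plus a FASTA file carrying the coding sequence itself. Files are read with
#' `rtracklayer` and `Biostrings`; the CDS start offset is recovered from the
#' first CDS base's position within the concatenated exonic sequence.
#'
#' @param gff_path path to the GFF3 file.
#' @param fasta_path path to the CDS FASTA file (first record used).
#' @return a [transcript_model()].
#' @export
read_transcript_model <- function(gff_path, fasta_path) {
  if (!file.exists(gff_path)) stop("GFF3 file not found: ", gff_path, call. = FALSE)
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path, call. = FALSE)
  gr <- rtracklayer::import(gff_path)
  type <- as.character(gr$type)
  ex <- gr[type == "exon"]
  if (length(ex) == 0L) stop("no exon features in ", gff_path, call. = FALSE)
  ex <- ex[order(GenomicRanges::start(ex))]
  cds_feats <- gr[type == "CDS"]
  gene <- if (!is.null(ex$gene_id) && !is.na(ex$gene_id[1L])) {
    as.character(ex$gene_id[1L])
  } else {
    as.character(GenomicRanges::seqnames(ex)[1L])
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("no sequences in ", fasta_path, call. = FALSE)
  cds_seq <- as.character(seqs[[1L]])

  starts <- GenomicRanges::start(ex)
  ends <- GenomicRanges::end(ex)
  off <- 1L
  if (length(cds_feats) > 0L) {
    first_cds <- min(GenomicRanges::start(cds_feats))
    cumw <- cumsum(ends - starts + 1L)
    i <- findInterval(first_cds, starts)
    if (i < 1L || first_cds > ends[i]) {
      stop("first CDS base does not fall in an exon", call. = FALSE)
    }
    off <- (if (i > 1L) cumw[i - 1L] else 0L) + (first_cds - starts[i]) + 1L
  }
  transcript_model(gene, starts, ends, cds_seq, cds_start_exon_offset = off)
}

#' Write a transcript model to GFF3 + FASTA
#'
#' Inverse of [read_transcript_model()]: emits one `gene` feature, one `exon`
#' feature per exon and the `CDS` features obtained by intersecting the
#' coding span with the exons.
#'
#' @param model a `transcript_model`.
#' @param gff_path output GFF3 path.
#' @param fasta_path output FASTA path for the coding sequence.
#' @return invisibly, the paths written.
#' @export
write_transcript_model <- function(model, gff_path, fasta_path) {
  ex <- model$exons
  n <- nrow(ex)
  cumw <- cumsum(ex$width)
  concat_first <- c(0L, cumw[-n]) + 1L
  off <- model$cds_start_exon_offset
  cds_span <- c(off, off + cds_length(model) - 1L)

  feats <- data.frame(
    start = c(ex$start[1L], ex$start),
    end = c(ex$end[n], ex$end),
    type = c("gene", rep("exon", n)),
    phase = NA_integer_
  )
  # intersect coding concat-span with each exon's concat-span
  coding_sofar <- 0L
  for (i in seq_len(n)) {
    lo <- max(cds_span[1L], concat_first[i])
    hi <- min(cds_span[2L], cumw[i])
    if (lo <= hi) {
      g_lo <- ex$start[i] + (lo - concat_first[i])
      g_hi <- ex$start[i] + (hi - concat_first[i])
      phase <- (3L - coding_sofar %% 3L) %% 3L
      feats <- rbind(feats, data.frame(start = g_lo, end = g_hi,
                                       type = "CDS", phase = phase))
      coding_sofar <- coding_sofar + (hi - lo + 1L)
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = model$gene_symbol,
    ranges = IRanges::IRanges(start = feats$start, end = feats$end),
    strand = "+",
    type = feats$type,
    phase = feats$phase,
    gene_id = model$gene_symbol,
    source = "snvcohort"
  )
  rtracklayer::export(gr, gff_path, format = "gff3")
  seq <- Biostrings::DNAStringSet(stats::setNames(model$coding_sequence,
                                                  model$gene_symbol))
  Biostrings::writeXStringSet(seq, fasta_path, width = 70L)
  invisible(c(gff = gff_path, fasta = fasta_path))
}
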