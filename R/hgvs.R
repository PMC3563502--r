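#' @title HGVS coding-DNA substitution parsing
#' @description Parse and format HGVS c. single-nucleotide substitutions.
#'   Three positional forms are supported, matching how referral-laboratory
#'   reports and mutation-database dumps write CFTR-style variants:
#'   exonic (`c.1408A>G`), intron-offset (`c.869+11C>T`, `c.870-2A>G`) and
#'   upstream-of-ATG (`c.-10G>A`). The canonical formatted string is the join
#'   key for every set operation in the package.
#' @name hgvs
NULL

.hgvs_regex <- "^c\\.(-?[0-9]+)((?:[+-][0-9]+)?)([ACGT])>([ACGT])$"

#' Build variant descriptors from components
#'
#' A descriptor is one row per variant with columns `coding_pos` (positive
#' integer; the anchor exonic base, or the upstream distance when
#' `upstream = TRUE`), `intron_offset` (signed; 0 for exonic/upstream),
#' `upstream` (logical), `ref`, `alt` (single bases) and `key`, the canonical
#' HGVS string.
#'
#' @param coding_pos positive integer vector.
#' @param intron_offset signed integer vector; non-zero only for intronic or
#'   splice-region variants.
#' @param upstream logical; `TRUE` for positions upstream of the
#'   translational start (written `c.-N`).
#' @param ref,alt reference and alternate bases, each one of A/C/G/T.
#' @return data.frame of validated descriptors with canonical `key` column.
#' @examples
#' variant_descriptor(1408, 0, FALSE, "A", "G")$key  # "c.1408A>G"
#' @export
variant_descriptor <- function(coding_pos, intron_offset = 0L,
                               upstream = FALSE, ref, alt) {
  n <- max(length(coding_pos), length(intron_offset), length(upstream),
           length(ref), length(alt))
  d <- data.frame(
    coding_pos    = as.integer(rep_len(coding_pos, n)),
    intron_offset = as.integer(rep_len(intron_offset, n)),
    upstream      = rep_len(as.logical(upstream), n),
    ref           = rep_len(as.character(ref), n),
    alt           = rep_len(as.character(alt), n),
    stringsAsFactors = FALSE
  )
  bad <- .descriptor_problems(d)
  if (any(!is.na(bad))) {
    stop("invalid variant descriptor: ",
         paste(unique(stats::na.omit(bad)), collapse = "; "), call. = FALSE)
  }
  d$key <- format_c(d)
  d
}

# vector of problem messages (NA where the row is fine)
.descriptor_problems <- function(d) {
  msg <- rep(NA_character_, nrow(d))
  bases <- c("A", "C", "G", "T")
  bad_pos <- is.na(d$coding_pos) | d$coding_pos < 1L
  msg[bad_pos] <- "coding position must be a positive integer"
  bad_base <- !(d$ref %in% bases) | !(d$alt %in% bases)
  msg[bad_base & is.na(msg)] <- "alleles must be one of A/C/G/T"
  same <- !is.na(d$ref) & !is.na(d$alt) & d$ref == d$alt
  msg[same & is.na(msg)] <- "ref and alt alleles are identical"
  up_off <- d$upstream & d$intron_offset != 0L
  msg[up_off & is.na(msg)] <- "upstream positions cannot carry an intron offset"
  msg
}

#' Parse HGVS c. substitution strings
#'
#' Whitespace anywhere in the string is tolerated (reports often print
#' `"c.2562 T > G"`); the parsed result always reformats to the spaceless
#' canonical form, so `format_c(parse_c(x))` is the canonicalizer.
#'
#' @param text character vector of HGVS c. substitution strings.
#' @param strict if `TRUE` (default) any malformed string is an error naming
#'   the offending token; if `FALSE`, malformed entries yield `NA` rows and
#'   are collected into a `rejects` attribute (a data.frame with columns
#'   `input` and `reason`) for reporting.
#' @return descriptor data.frame (see [variant_descriptor()]), one row per
#'   input, with canonical `key`.
#' @examples
#' parse_c("c.869+11C>T")$intron_offset  # 11
#' parse_c("c.-10G>A")$upstream          # TRUE
#' @export
parse_c <- function(text, strict = TRUE) {
  if (length(text) == 0L) {
    stop("no variant strings supplied", call. = FALSE)
  }
  raw <- as.character(text)
  cleaned <- gsub("[[:space:]]+", "", raw)
  m <- regmatches(cleaned, regexec(.hgvs_regex, cleaned))
  ok <- lengths(m) == 5L
  reason <- rep(NA_character_, length(raw))
  reason[!ok] <- "does not match c.<pos>[+/-<offset>]<ref>><alt>"

  d <- data.frame(
    coding_pos    = rep(NA_integer_, length(raw)),
    intron_offset = rep(0L, length(raw)),
    upstream      = rep(FALSE, length(raw)),
    ref           = rep(NA_character_, length(raw)),
    alt           = rep(NA_character_, length(raw)),
    stringsAsFactors = FALSE
  )
  if (any(ok)) {
    pos_tok <- vapply(m[ok], `[`, "", 2L)
    off_tok <- vapply(m[ok], `[`, "", 3L)
    up <- startsWith(pos_tok, "-")
    if (any(up & off_tok != "")) {
      # c.-N+k is not a form this grammar admits
      bad <- which(ok)[up & off_tok != ""]
      ok[bad] <- FALSE
      reason[bad] <- "upstream position with intron offset"
      keep <- !(up & off_tok != "")
      pos_tok <- pos_tok[keep]; off_tok <- off_tok[keep]; up <- up[keep]
      m_ok <- m[ok]
    } else {
      m_ok <- m[ok]
    }
    d$coding_pos[ok] <- abs(as.integer(pos_tok))
    d$intron_offset[ok] <- ifelse(off_tok == "", 0L, as.integer(off_tok))
    d$upstream[ok] <- up
    d$ref[ok] <- vapply(m_ok, `[`, "", 4L)
    d$alt[ok] <- vapply(m_ok, `[`, "", 5L)
  }
  prob <- .descriptor_problems(d)
  prob[!ok] <- reason[!ok]
  bad <- !is.na(prob)
  if (any(bad)) {
    if (strict) {
      stop("malformed HGVS string(s): ",
           paste(sprintf("'%s' (%s)", raw[bad], prob[bad]), collapse = "; "),
           call. = FALSE)
    }
    d[bad, c("coding_pos", "ref", "alt")] <- NA
    d$intron_offset[bad] <- NA_integer_
    d$upstream[bad] <- NA
  }
  d$key <- NA_character_
  d$key[!bad] <- format_c(d[!bad, , drop = FALSE])
  attr(d, "rejects") <- data.frame(input = raw[bad], reason = prob[bad],
                                   stringsAsFactors = FALSE)
  d
}

#' Format descriptors as canonical HGVS c. strings
#'
#' Inverse of [parse_c()]: emits the spaceless canonical form, e.g.
#' `"c.2562T>G"`, `"c.869+11C>T"`, `"c.-10G>A"`.
#'
#' @param d descriptor data.frame.
#' @return character vector of canonical HGVS strings.
#' @export
format_c <- function(d) {
  off <- ifelse(d$intron_offset > 0L, paste0("+", d$intron_offset),
         ifelse(d$intron_offset < 0L, as.character(d$intron_offset), ""))
  pos <- ifelse(d$upstream, paste0("-", d$coding_pos),
                paste0(d$coding_pos, off))
  paste0("c.", pos, d$ref, ">", d$alt)
}

#' Canonicalize variant strings
#'
#' `canonical_key(x)` is shorthand for `parse_c(x)$key`: one canonical string
#' per input, used as the join key across cohort, snapshot and evidence files.
#'
#' @inheritParams parse_c
#' @return character vector of canonical keys (`NA` for rejects when
#'   `strict = FALSE`).
#' @export
canonical_key <- function(text, strict = TRUE) {
  parse_c(text, strict = strict)$key
}
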