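#' Construct a mutation-database snapshot
#'
#' A snapshot is a named set of canonical variant keys — a local dump of what
#' a mutation database (dbSNP, a locus-specific database such as CFMDB, or
#' HGMD) contained for the gene at accession time. All matching is exact
#' canonical-string equality; novelty is defined purely as absence from every
#' provided snapshot.
#'
#' @param name database name, e.g. `"dbSNP132"`; must be unique within any
#'   collection passed to [cross_reference()].
#' @param keys character vector of variant strings; canonicalized and
#'   de-duplicated.
#' @param total_gene_entries optional integer: the database's total entry
#'   count for the gene (metadata only).
#' @return object of class `db_snapshot` with elements `name`, `keys`
#'   (canonical, unique, sorted) and `total_gene_entries`.
#' @export
database_snapshot <- function(name, keys, total_gene_entries = NA_integer_) {
  keys <- if (length(keys) > 0L) canonical_key(keys) else character(0)
  structure(list(
    name = as.character(name),
    keys = sort(unique(keys)),
    total_gene_entries = as.integer(total_gene_entries)
  ), class = "db_snapshot")
}

#' @export
print.db_snapshot <- function(x, ...) {
  cat(sprintf("db_snapshot '%s': %d keys\n", x$name, length(x$keys)))
  invisible(x)
}

#' Load a database snapshot from a TSV/one-per-line file
#'
#' Reads one variant string per line; lines starting with `#` and blank
#' lines are ignored. Malformed lines are collected into a rejects report
#' (attribute `rejects`) rather than aborting, but a file where more than
#' half the lines fail to parse is treated as the wrong format and is an
#' error. Duplicate lines collapse under set semantics and are noted in the
#' `duplicates` attribute.
#'
#' @param path file path.
#' @param name database name for the snapshot.
#' @return a [database_snapshot()] with `rejects` and `duplicates`
#'   attributes.
#' @export
load_snapshot <- function(path, name) {
  if (!file.exists(path)) {
    stop("snapshot file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop("snapshot file has no variant lines: ", path, call. = FALSE)
  }
  d <- parse_c(lines, strict = FALSE)
  rejects <- attr(d, "rejects")
  if (nrow(rejects) > length(lines) / 2) {
    stop(sprintf("snapshot file %s looks malformed: %d of %d lines rejected",
                 path, nrow(rejects), length(lines)), call. = FALSE)
  }
  keys <- d$key[!is.na(d$key)]
  dup <- unique(keys[duplicated(keys)])
  snap <- database_snapshot(name, keys)
  attr(snap, "rejects") <- rejects
  attr(snap, "duplicates") <- dup
  snap
}

#' Cross-reference variants against database snapshots
#'
#' For each snapshot, counts how many of the observed variants are present
#' and absent (the two columns of a presence table, with percentages of the
#' distinct-variant total rounded half-up to 2 decimals); variants absent
#' from every snapshot form the novel set.
#'
#' @param variants character vector of canonical variant keys (non-empty;
#'   de-duplicated internally).
#' @param snapshots list of [database_snapshot()] objects with unique names.
#' @return object of class `xref_summary`: `per_database` data.frame
#'   (`database`, `present`, `absent`, `present_pct`, `absent_pct`),
#'   `n_variants`, `union_present`, `union_present_pct`, `novel_count`,
#'   `novel_pct`, `novel_keys`.
#' @examples
#' snaps <- list(database_snapshot("A", "c.1408A>G"))
#' cross_reference(c("c.1408A>G", "c.869+11C>T"), snaps)$novel_count  # 1
#' @export
cross_reference <- function(variants, snapshots) {
  if (length(variants) == 0L) {
    stop("cross_reference() needs a non-empty variant set", call. = FALSE)
  }
  if (length(snapshots) == 0L) {
    stop("cross_reference() needs at least one snapshot", call. = FALSE)
  }
  if (inherits(snapshots, "db_snapshot")) snapshots <- list(snapshots)
  nm <- vapply(snapshots, function(s) s$name, "")
  if (anyDuplicated(nm)) {
    stop("duplicate snapshot names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  variants <- sort(unique(canonical_key(variants)))
  total <- length(variants)
  present_mat <- vapply(snapshots, function(s) variants %in% s$keys,
                        logical(total))
  present_mat <- matrix(present_mat, nrow = total)
  present <- colSums(present_mat)
  in_any <- rowSums(present_mat) > 0L
  novel_keys <- variants[!in_any]
  structure(list(
    per_database = data.frame(
      database = nm,
      present = as.integer(present),
      absent = as.integer(total - present),
      present_pct = percent_of(present, total),
      absent_pct = percent_of(total - present, total),
      stringsAsFactors = FALSE
    ),
    n_variants = total,
    union_present = as.integer(sum(in_any)),
    union_present_pct = percent_of(sum(in_any), total),
    novel_count = length(novel_keys),
    novel_pct = percent_of(length(novel_keys), total),
    novel_keys = novel_keys
  ), class = "xref_summary")
}

#' @export
print.xref_summary <- function(x, ...) {
  cat(sprintf("xref_summary: %d distinct variants vs %d database(s)\n",
              x$n_variants, nrow(x$per_database)))
  print(x$per_database, row.names = FALSE)
  cat(sprintf("in >=1 database: %d (%.2f%%) | novel: %d (%.2f%%)\n",
              x$union_present, x$union_present_pct,
              x$novel_count, x$novel_pct))
  invisible(x)
}

#' Write a presence table (database, in/out counts and percentages) as TSV
#'
#' One row per database plus a `Total` row for the union across databases,
#' with `count (percent%)` cells.
#'
#' @param xref an `xref_summary`.
#' @param path output TSV path.
#' @return invisibly, the data.frame written.
#' @export
write_xref_table <- function(xref, path) {
  pd <- xref$per_database
  tab <- data.frame(
    database = c(pd$database, "Total"),
    snvs_in_database = c(
      fmt_count_pct(pd$present, xref$n_variants),
      fmt_count_pct(xref$union_present, xref$n_variants)
    ),
    snvs_not_in_database = c(
      fmt_count_pct(pd$absent, xref$n_variants),
      fmt_count_pct(xref$novel_count, xref$n_variants)
    ),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
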