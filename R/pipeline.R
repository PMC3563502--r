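#' Assemble and validate a pipeline run configuration
#'
#' @param transcript_gff path to the transcript GFF3.
#' @param cds_fasta path to the CDS FASTA.
#' @param cohort_tsv path to the cohort observation TSV.
#' @param snapshot_tsvs named character vector of database snapshot TSVs
#'   (names are the database names).
#' @param evidence_tsv path to the per-variant evidence TSV.
#' @param out_dir output directory (created if needed).
#' @param splice_halfwidth intronic bases per boundary side counted as
#'   splice site.
#' @param deep_intronic_threshold deep-intronic depth cut-off in bp.
#' @param common_threshold common-variant population frequency threshold.
#' @param count_other_mixed_support whether Other/Mixed observations defeat
#'   ethnic specificity of named groups (see [ethnic_summary()]).
#' @return a validated `run_config` list.
#' @export
run_config <- function(transcript_gff, cds_fasta, cohort_tsv, snapshot_tsvs,
                       evidence_tsv, out_dir,
                       splice_halfwidth = 2L, deep_intronic_threshold = 20L,
                       common_threshold = 0.01,
                       count_other_mixed_support = TRUE) {
  files <- c(transcript_gff, cds_fasta, cohort_tsv, snapshot_tsvs,
             evidence_tsv)
  missing_files <- files[!file.exists(files)]
  if (length(missing_files) > 0L) {
    stop("input file(s) not found: ", paste(missing_files, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(names(snapshot_tsvs)) || any(names(snapshot_tsvs) == "")) {
    stop("snapshot_tsvs must be a named vector (names = database names)",
         call. = FALSE)
  }
  if (splice_halfwidth < 0L || deep_intronic_threshold <= 0L ||
      common_threshold <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  structure(list(
    transcript_gff = transcript_gff, cds_fasta = cds_fasta,
    cohort_tsv = cohort_tsv, snapshot_tsvs = snapshot_tsvs,
    evidence_tsv = evidence_tsv, out_dir = out_dir,
    splice_halfwidth = as.integer(splice_halfwidth),
    deep_intronic_threshold = as.integer(deep_intronic_threshold),
    common_threshold = common_threshold,
    count_other_mixed_support = isTRUE(count_other_mixed_support)
  ), class = "run_config")
}

#' Load a run configuration from a JSON file
#'
#' JSON fields mirror the arguments of [run_config()]; `snapshot_tsvs` is an
#' object mapping database names to paths. Relative paths are resolved
#' against the JSON file's directory.
#'
#' @param path JSON file path.
#' @return a `run_config`.
#' @export
run_config_from_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(startsWith(p, "/"), p, file.path(base, p))
  snaps <- unlist(cfg$snapshot_tsvs)
  args <- list(
    transcript_gff = resolve(cfg$transcript_gff),
    cds_fasta = resolve(cfg$cds_fasta),
    cohort_tsv = resolve(cfg$cohort_tsv),
    snapshot_tsvs = stats::setNames(resolve(snaps), names(snaps)),
    evidence_tsv = resolve(cfg$evidence_tsv),
    out_dir = resolve(cfg$out_dir)
  )
  for (f in c("splice_halfwidth", "deep_intronic_threshold",
              "common_threshold", "count_other_mixed_support")) {
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  }
  do.call(run_config, args)
}

# run expr, rethrowing any error prefixed with the pipeline stage name
.run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) stage_stop(name, conditionMessage(e)))
}

#' Write a functional-class tally as TSV
#'
#' One row per class plus a `Total` row holding the distinct-variant count
#' (which can be below the column sum when variants carry multiple labels).
#'
#' @param tally data.frame from [tally_classes()].
#' @param path output TSV path.
#' @return invisibly, the data.frame written.
#' @export
write_class_table <- function(tally, path) {
  tab <- rbind(
    data.frame(variant_class = tally$class, n_variants = tally$n_variants),
    data.frame(variant_class = "Total", n_variants = attr(tally, "n_distinct"))
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Run the full referral-cohort pipeline
#'
#' Executes parse -> annotate -> cross-reference -> ethnic summary ->
#' clinical classification -> tallies, writing `table1.tsv` (ethnic
#' summary), `table2.tsv` (database presence), `table3.tsv` (class tally),
#' `annotations.tsv`, `calls.tsv`, `rejects.tsv` and `run_log.txt` to the
#' configured output directory. Any stage failure aborts with the stage
#' name and the offending records. The pipeline is deterministic: rerunning
#' an identical configuration rewrites byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with every intermediate object (`model`,
#'   `observations`, `annotations`, `xref`, `ethnic`, `calls`,
#'   `class_tally`, `tier_tally`) and the output `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("# snvcohort pipeline run",
                 paste0("splice_halfwidth\t", config$splice_halfwidth),
                 paste0("deep_intronic_threshold\t",
                        config$deep_intronic_threshold),
                 paste0("common_threshold\t", config$common_threshold),
                 paste0("count_other_mixed_support\t",
                        config$count_other_mixed_support))
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  model <- .run_stage("gene-model",
                      read_transcript_model(config$transcript_gff,
                                            config$cds_fasta))
  note("gene\t", model$gene_symbol, "\texons\t", nrow(model$exons),
       "\tcds_nt\t", cds_length(model))

  observations <- .run_stage("cohort", read_cohort(config$cohort_tsv))
  keys <- sort(unique(observations$key))
  note("observations\t", nrow(observations),
       "\tpatients\t", length(unique(observations$patient_id)),
       "\tdistinct_variants\t", length(keys))

  annotations <- .run_stage("consequence",
    annotate_variants(parse_c(keys), model,
                      splice_halfwidth = config$splice_halfwidth,
                      deep_intronic_threshold = config$deep_intronic_threshold))

  snapshots <- .run_stage("xref", {
    lapply(stats::setNames(names(config$snapshot_tsvs),
                           names(config$snapshot_tsvs)),
           function(db) load_snapshot(config$snapshot_tsvs[[db]], db))
  })
  rejects <- do.call(rbind, lapply(snapshots, function(s) {
    r <- attr(s, "rejects")
    if (nrow(r) > 0L) cbind(source = s$name, r) else NULL
  }))
  if (is.null(rejects)) {
    rejects <- data.frame(source = character(0), input = character(0),
                          reason = character(0))
  }
  xref <- .run_stage("xref", cross_reference(keys, unname(snapshots)))
  note("union_present\t", xref$union_present, "\tnovel\t", xref$novel_count)

  ethnic <- .run_stage("cohort-stats",
    ethnic_summary(observations, novel_keys = xref$novel_keys,
                   count_other_mixed_support =
                     config$count_other_mixed_support))

  evidence <- .run_stage("classify", {
    ev <- read_evidence(config$evidence_tsv)
    missing_keys <- setdiff(keys, ev$key)
    if (length(missing_keys) > 0L) {
      stop("evidence file lacks ",
           length(missing_keys), " cohort variant(s): ",
           paste(utils::head(missing_keys, 5L), collapse = ", "))
    }
    ev[match(keys, ev$key), , drop = FALSE]
  })
  calls <- .run_stage("classify",
    classify_variants(evidence, common_threshold = config$common_threshold))

  class_tally <- tally_classes(annotations)
  tier_tally <- tally_tiers(calls)
  note("class_column_sum\t", attr(class_tally, "column_sum"),
       "\ttier_total\t", attr(tier_tally, "total"))

  paths <- list(
    table1 = file.path(config$out_dir, "table1.tsv"),
    table2 = file.path(config$out_dir, "table2.tsv"),
    table3 = file.path(config$out_dir, "table3.tsv"),
    annotations = file.path(config$out_dir, "annotations.tsv"),
    calls = file.path(config$out_dir, "calls.tsv"),
    rejects = file.path(config$out_dir, "rejects.tsv"),
    log = file.path(config$out_dir, "run_log.txt")
  )
  write_ethnic_table(ethnic, paths$table1)
  write_xref_table(xref, paths$table2)
  write_class_table(class_tally, paths$table3)
  utils::write.table(annotations, paths$annotations, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_calls(calls, paths$calls)
  utils::write.table(rejects, paths$rejects, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(log_lines, paths$log)
  invisible(list(model = model, observations = observations,
                 annotations = annotations, snapshots = snapshots,
                 xref = xref, ethnic = ethnic, evidence = evidence,
                 calls = calls, class_tally = class_tally,
                 tier_tally = tier_tally, rejects = rejects, paths = paths))
}
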