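#' Summary counts over a candidate table
#'
#' @param records Candidate records ([load_candidate_table()]).
#' @return A `candidate_report` list: `n_candidates`, localization tally,
#'   extracellular count, hypothetical count and percentage (one-decimal
#'   reporting), extracellular-hypothetical count, functional-group counts.
#' @export
candidate_report <- function(records) {
  hyp <- classify_hypothetical(records$product_name)
  tal <- tally_localizations(records)
  tal_hyp <- tally_localizations(records, hyp)
  n <- nrow(records)
  structure(list(
    n_candidates = n,
    localization_tally = tal,
    n_extracellular = if ("Ext" %in% names(tal)) tal[["Ext"]] else 0L,
    n_hypothetical = sum(hyp),
    pct_hypothetical = if (n > 0) 100 * sum(hyp) / n else NaN,
    n_hypothetical_extracellular =
      if ("Ext" %in% names(tal_hyp)) tal_hyp[["Ext"]] else 0L,
    group_counts = table(records$functional_group)
  ), class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.candidate_report <- function(x, ...) {
  lines <- c(
    sprintf("%d candidate genes", x$n_candidates),
    sprintf("%d extracellular", x$n_extracellular),
    sprintf("%d hypothetical (%.1f%%)", x$n_hypothetical, x$pct_hypothetical),
    sprintf("%d extracellular hypothetical", x$n_hypothetical_extracellular),
    "localization tally:",
    sprintf("  %s: %d", names(x$localization_tally), x$localization_tally)
  )
  lines
}

#' Run the full screening pipeline
#'
#' Stages: load the matrix and scheme, screen, build the candidate table
#' (joining screen hits to any supplied annotations), parse optional
#' domain-scan and localization outputs, profile composition of an optional
#' protein FASTA, and write all outputs plus a plain-text report and a YAML
#' run manifest into `out_dir`. Any stage failure aborts with the stage
#' name and cause. Data goes to files; progress messages to stderr.
#'
#' @param matrix_path RPKM TSV ([load_rpkm_table()] dialect).
#' @param scheme_path Group-scheme YAML ([load_group_scheme()]).
#' @param out_dir Output directory, created if needed.
#' @param annotations_path Optional candidate-table TSV of per-gene
#'   annotations (protein IDs, product names).
#' @param domains_path Optional domain-scan TSV.
#' @param localization_path Optional localization-predictor TSV.
#' @param fasta_path Optional protein FASTA for composition profiling.
#' @param reference_stat,strict_threshold,relaxed_threshold Screen
#'   parameters; thresholds override the scheme file when given.
#' @return Invisibly, a list with the screen results, summary, candidate
#'   records, report, and output paths.
#' @export
run_pipeline <- function(matrix_path, scheme_path, out_dir,
                         annotations_path = NULL, domains_path = NULL,
                         localization_path = NULL, fasta_path = NULL,
                         reference_stat = "max",
                         strict_threshold = NULL, relaxed_threshold = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  mat <- stage("screen", load_rpkm_table(matrix_path, quiet = TRUE))
  scheme <- stage("screen", load_group_scheme(scheme_path))
  if (!is.null(strict_threshold) || !is.null(relaxed_threshold))
    scheme <- stage("screen", group_scheme(
      scheme$groups, scheme$roles,
      strict_threshold = strict_threshold %||% scheme$strict_threshold,
      relaxed_threshold = relaxed_threshold %||% scheme$relaxed_threshold))
  results <- stage("screen", screen_genes(mat, scheme, reference_stat))
  summary <- summarize_screen(results)
  write_screen_results(results, file.path(out_dir, "screen_results.tsv"))
  message(sprintf("screen: %d of %d genes selected", summary$n_selected,
                  summary$n_genes_total))

  hits <- results$gene_id[results$selected]
  records <- stage("annotate", {
    if (!is.null(annotations_path)) {
      ann <- load_candidate_table(annotations_path)
      kept <- ann[ann$gene_id %in% hits, , drop = FALSE]
      unknown <- setdiff(hits, ann$gene_id)
      if (length(unknown))
        kept <- rbind(kept, data.frame(
          gene_id = unknown, protein_id = NA_character_,
          product_name = paste("Hypothetical protein", unknown),
          functional_group = "Hypothetical protein",
          compartment = NA_character_, loc_score = NA_real_,
          stringsAsFactors = FALSE))
      kept[match(hits, kept$gene_id), , drop = FALSE]
    } else {
      data.frame(gene_id = hits,
                 protein_id = rep(NA_character_, length(hits)),
                 product_name = if (length(hits))
                   paste("Hypothetical protein", hits) else character(0),
                 functional_group = rep("Hypothetical protein", length(hits)),
                 compartment = rep(NA_character_, length(hits)),
                 loc_score = rep(NA_real_, length(hits)),
                 stringsAsFactors = FALSE)
    }
  })
  if (!is.null(localization_path)) {
    loc <- stage("annotate", parse_localization_output(localization_path))
    idx <- match(records$protein_id, loc$protein_id)
    hit <- !is.na(idx)
    records$compartment[hit] <- loc$compartment[idx[hit]]
    records$loc_score[hit] <- loc$score[idx[hit]]
  }
  write_candidate_table(records, file.path(out_dir, "candidate_table.tsv"))

  domains <- NULL
  if (!is.null(domains_path)) {
    dhits <- stage("annotate", parse_domain_scan(domains_path))
    domains <- domain_architecture_summary(
      dhits, records$protein_id[!is.na(records$protein_id)])
    utils::write.table(
      data.frame(protein_id = names(domains$n_hits),
                 n_domain_hits = as.integer(domains$n_hits)),
      file.path(out_dir, "domain_counts.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  comp <- NULL
  if (!is.null(fasta_path)) {
    profiles <- stage("compose", batch_composition(fasta_path))
    comp <- composition_table(profiles)
    utils::write.table(comp, file.path(out_dir, "composition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report <- candidate_report(records)
  report_lines <- c(
    sprintf("%d of %d genes selected (%.4f%% of the matrix)",
            summary$n_selected, summary$n_genes_total,
            100 * summary$fraction_selected),
    format(report),
    if (!is.null(domains))
      sprintf("%d candidates with >= 1 conserved domain", domains$n_with_domain),
    if (!is.null(comp))
      sprintf("%d composition profiles (%d flagged)", nrow(comp),
              sum(nzchar(comp$flags)))
  )
  writeLines(report_lines, file.path(out_dir, "report.txt"))

  manifest <- list(
    subcommand = "run_pipeline",
    inputs = list(matrix = matrix_path, scheme = scheme_path,
                  annotations = annotations_path, domains = domains_path,
                  localization = localization_path, fasta = fasta_path),
    parameters = list(reference_stat = reference_stat,
                      strict_threshold = scheme$strict_threshold,
                      relaxed_threshold = scheme$relaxed_threshold),
    tool_version = as.character(utils::packageVersion("stagescreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(results = results, summary = summary, records = records,
                 report = report, domains = domains, composition = comp,
                 out_dir = out_dir))
}
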