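#' Screen a matrix for genes specific to the reference stage
#'
#' For each gene, the reference level R is a summary statistic (default the
#' maximum) of its RPKM over the reference samples. The gene is selected iff
#' R > 0 and every sample in every non-reference group lies *strictly* below
#' its role's threshold times R: `rpkm < strict_threshold * R` for strict
#' groups, `rpkm < relaxed_threshold * R` for relaxed groups. A gene silent
#' in the reference group (R = 0) is never selected and its ratios are NA.
#'
#' Comparing each sample individually is equivalent to comparing the group
#' maximum, which is what the per-group ratios report. Comparisons use raw
#' double precision with no epsilon: the thresholds are exact decimal
#' fractions of data values, so a value exactly at the boundary (e.g. 20.0
#' against R = 100 at threshold 0.20) is deterministically rejected.
#'
#' Results are returned for every gene, selection being a flag, so near
#' misses remain inspectable.
#'
#' @param mat An [expression_matrix()] or named numeric matrix.
#' @param scheme A [group_scheme()]; every scheme sample must be a column of
#'   `mat`.
#' @param reference_stat How to summarize reference samples into R:
#'   `"max"` (default; a candidate must be low relative to the larger of the
#'   reference samples), `"min"`, or `"mean"`. Exposed because the source
#'   data's "that of P1 or P2" admits several readings.
#' @return A data.frame with one row per gene: `gene_id`, `selected`,
#'   `reference_level`, one `ratio_<group>` column per non-reference group
#'   (group max RPKM divided by R; NA when R = 0), and
#'   `first_failing_group` (NA when no group fails). Scheme and statistic
#'   are attached as attributes `scheme` and `reference_stat`.
#' @export
screen_genes <- function(mat, scheme, reference_stat = c("max", "min", "mean")) {
  reference_stat <- match.arg(reference_stat)
  stopifnot(inherits(scheme, "group_scheme"))
  mat <- unclass(mat)
  scheme_samples <- unlist(scheme$groups, use.names = FALSE)
  missing <- setdiff(scheme_samples, colnames(mat))
  if (length(missing))
    stop("scheme sample(s) absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(colnames(mat), scheme_samples)
  if (length(extra))
    warning("sample(s) in no group are ignored: ",
            paste(extra, collapse = ", "), call. = FALSE)

  ref_groups <- names(scheme$groups)[scheme$roles == "reference"]
  test_groups <- names(scheme$groups)[scheme$roles != "reference"]
  ref_samples <- unlist(scheme$groups[ref_groups], use.names = FALSE)

  group_max <- function(samples) {
    sub <- mat[, samples, drop = FALSE]
    apply(sub, 1, max)
  }
  stat_fun <- switch(reference_stat,
    max  = function(x) apply(x, 1, max),
    min  = function(x) apply(x, 1, min),
    mean = rowMeans)
  R <- stat_fun(mat[, ref_samples, drop = FALSE])

  n <- nrow(mat)
  res <- data.frame(gene_id = rownames(mat) %||% character(0),
                    selected = rep(R > 0, length.out = n),
                    reference_level = as.numeric(R),
                    stringsAsFactors = FALSE)
  first_fail <- rep(NA_character_, n)
  for (g in test_groups) {
    gmax <- group_max(scheme$groups[[g]])
    thr <- if (scheme$roles[[g]] == "strict") scheme$strict_threshold
           else scheme$relaxed_threshold
    ratio <- ifelse(R > 0, gmax / R, NA_real_)
    fails <- R > 0 & !(gmax < thr * R)
    res[[paste0("ratio_", g)]] <- ratio
    res$selected <- res$selected & !fails
    first_fail[is.na(first_fail) & fails] <- g
  }
  res$first_failing_group <- first_fail
  rownames(res) <- NULL
  attr(res, "scheme") <- scheme
  attr(res, "reference_stat") <- reference_stat
  res
}

#' Naive reference implementation of the specificity screen
#'
#' Walks genes, groups, and samples in explicit loops, applying the
#' selection rule one comparison at a time. Intended as an independent test
#' oracle for [screen_genes()] on small matrices (it is quadratic and slow);
#' verdicts are identical on any input.
#'
#' @inheritParams screen_genes
#' @return Data.frame of `gene_id`, `selected` (no diagnostics).
#' @export
screen_oracle <- function(mat, scheme, reference_stat = c("max", "min", "mean")) {
  reference_stat <- match.arg(reference_stat)
  mat <- unclass(mat)
  ref_samples <- unlist(scheme$groups[scheme$roles == "reference"], use.names = FALSE)
  out <- data.frame(gene_id = rownames(mat), selected = logical(nrow(mat)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(mat))) {
    ref_vals <- c()
    for (s in ref_samples) ref_vals <- c(ref_vals, mat[i, s])
    R <- switch(reference_stat, max = max(ref_vals), min = min(ref_vals),
                mean = mean(ref_vals))
    ok <- R > 0
    if (ok) {
      for (g in names(scheme$groups)) {
        role <- scheme$roles[[g]]
        if (role == "reference") next
        thr <- if (role == "strict") scheme$strict_threshold else scheme$relaxed_threshold
        for (s in scheme$groups[[g]]) {
          if (!(mat[i, s] < thr * R)) ok <- FALSE
        }
      }
    }
    out$selected[i] <- ok
  }
  out
}

#' Summarize screen results
#'
#' @param results Data.frame from [screen_genes()].
#' @return A `screen_summary`: total and selected gene counts, the selected
#'   fraction (NaN when the matrix was empty), thresholds used, and counts
#'   of genes per first failing group.
#' @export
summarize_screen <- function(results) {
  scheme <- attr(results, "scheme")
  n_total <- nrow(results)
  n_sel <- sum(results$selected)
  fails <- table(factor(results$first_failing_group,
                        levels = if (is.null(scheme)) NULL else
                          names(scheme$groups)[scheme$roles != "reference"]))
  structure(list(
    n_genes_total = n_total,
    n_selected = n_sel,
    fraction_selected = if (n_total > 0) n_sel / n_total else NaN,
    strict_threshold = if (is.null(scheme)) NA_real_ else scheme$strict_threshold,
    relaxed_threshold = if (is.null(scheme)) NA_real_ else scheme$relaxed_threshold,
    reference_stat = attr(results, "reference_stat"),
    first_fail_counts = fails
  ), class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("<screen_summary>\n")
  cat(sprintf("  %d of %d genes selected (%.4f%%)\n",
              x$n_selected, x$n_genes_total, 100 * x$fraction_selected))
  cat(sprintf("  thresholds: strict %.2f, relaxed %.2f; reference statistic: %s\n",
              x$strict_threshold, x$relaxed_threshold,
              x$reference_stat %||% "max"))
  if (length(x$first_fail_counts)) {
    cat("  first failing group:\n")
    for (g in names(x$first_fail_counts))
      cat(sprintf("    %s: %d\n", g, x$first_fail_counts[[g]]))
  }
  invisible(x)
}

#' Write screen results as tab-separated text
#'
#' @param results Data.frame from [screen_genes()].
#' @param path Output path.
#' @param selected_only Keep only selected genes.
#' @return `path`, invisibly.
#' @export
write_screen_results <- function(results, path, selected_only = FALSE) {
  out <- if (selected_only) results[results$selected, , drop = FALSE] else results
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
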