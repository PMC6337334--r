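#' Construct a validated expression matrix
#'
#' An `expression_matrix` is a dense numeric genes-by-samples matrix of RPKM
#' (reads per kilobase per million mapped reads) values. All cells must be
#' finite and non-negative; gene and sample identifiers must be unique.
#'
#' @param values Numeric matrix with gene IDs as rownames and sample IDs as
#'   colnames.
#' @return The matrix with class `expression_matrix` prepended.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix", call. = FALSE)
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("expression matrix needs gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression matrix contains non-finite values", call. = FALSE)
  if (any(values < 0))
    stop("expression matrix contains negative values", call. = FALSE)
  class(values) <- c("expression_matrix", class(values))
  values
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples\n", nrow(x), ncol(x)))
  cat("samples:", paste(utils::head(colnames(x), 8), collapse = ", "),
      if (ncol(x) > 8) "..." else "", "\n")
  invisible(x)
}

#' Read an RPKM table from tab-separated text
#'
#' Expects a header row of sample IDs and one gene per row, gene ID in the
#' first column. The first header cell may be empty or any label (e.g.
#' "Gene"); it is ignored. Cells must parse as non-negative numbers; blank
#' or `NA` cells are a hard error unless `fill_missing_zero = TRUE`, in
#' which case they become 0 (silent imputation would otherwise alter the
#' screen, so it is opt-in).
#'
#' @param path Path to a UTF-8 tab-separated file.
#' @param fill_missing_zero Replace blank/`NA` cells with 0 instead of
#'   raising an error.
#' @param quiet Suppress the row/column count message.
#' @return An [expression_matrix()].
#' @export
load_rpkm_table <- function(path, fill_missing_zero = FALSE, quiet = FALSE) {
  if (!file.exists(path)) stop("RPKM table not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE, na.strings = NULL,
                           fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop("RPKM table needs a gene column plus >= 1 sample column", call. = FALSE)
  gene_ids <- trimws(raw[[1]])
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene IDs in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "), call. = FALSE)
  cells <- as.matrix(raw[, -1, drop = FALSE])
  cells <- trimws(cells)
  missing <- cells == "" | toupper(cells) == "NA"
  if (any(missing)) {
    if (!fill_missing_zero) {
      idx <- which(missing, arr.ind = TRUE)[1, ]
      stop(sprintf("missing cell at gene '%s', sample '%s' (use fill_missing_zero = TRUE to coerce to 0)",
                   gene_ids[idx[1]], sample_ids[idx[2]]), call. = FALSE)
    }
    cells[missing] <- "0"
  }
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(values), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell '%s' at gene '%s', sample '%s'",
                 cells[bad[1, 1], bad[1, 2]], gene_ids[bad[1, 1]],
                 sample_ids[bad[1, 2]]), call. = FALSE)
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative RPKM %s at gene '%s', sample '%s'",
                 cells[idx[1], idx[2]], gene_ids[idx[1]], sample_ids[idx[2]]),
         call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  if (!quiet)
    message(sprintf("loaded %d genes x %d samples from %s",
                    nrow(values), ncol(values), path))
  expression_matrix(values)
}

#' Write an expression matrix as tab-separated text
#'
#' Uses the same dialect [load_rpkm_table()] reads, so a load/write cycle
#' round-trips finite decimal inputs exactly.
#'
#' @param mat An [expression_matrix()] (or plain named numeric matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rpkm_table <- function(mat, path) {
  df <- data.frame(Gene = rownames(mat),
                   apply(unclass(mat), 2, as.character),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Define a sample grouping scheme for the specificity screen
#'
#' Groups carry one of three roles. `reference` samples define the reference
#' expression level R per gene. Samples in `strict` groups must stay below
#' `strict_threshold * R` (default 0.20, "less than 20% that of P1 or P2");
#' samples in `relaxed` groups below `relaxed_threshold * R` (default 0.70,
#' used for the late-umbo stages LU1/LU2 immediately preceding settlement,
#' where pre-settlement transcription has already begun).
#'
#' @param groups Named list of character vectors of sample IDs.
#' @param roles Named character vector mapping each group name to one of
#'   `"reference"`, `"relaxed"`, `"strict"`.
#' @param strict_threshold,relaxed_threshold Fractions in (0, 1];
#'   `strict_threshold` must not exceed `relaxed_threshold`.
#' @return A `group_scheme` object.
#' @export
group_scheme <- function(groups, roles,
                         strict_threshold = 0.20, relaxed_threshold = 0.70) {
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list of sample ID vectors", call. = FALSE)
  roles <- unlist(roles)
  if (!setequal(names(roles), names(groups)))
    stop("roles must name exactly the declared groups", call. = FALSE)
  roles <- roles[names(groups)]
  ok_roles <- c("reference", "relaxed", "strict")
  if (!all(roles %in% ok_roles))
    stop("unknown role(s): ", paste(setdiff(roles, ok_roles), collapse = ", "),
         "; expected reference/relaxed/strict", call. = FALSE)
  if (!any(roles == "reference"))
    stop("scheme needs at least one reference group", call. = FALSE)
  groups <- lapply(groups, function(s) as.character(unlist(s)))
  all_samples <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_samples))
    stop("sample(s) assigned to more than one group: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "),
         call. = FALSE)
  for (th in c(strict_threshold = strict_threshold,
               relaxed_threshold = relaxed_threshold)) {
    if (!is.numeric(th) || length(th) != 1 || is.na(th) || th <= 0 || th > 1)
      stop("thresholds must be single numbers in (0, 1]", call. = FALSE)
  }
  if (strict_threshold > relaxed_threshold)
    stop("strict_threshold must not exceed relaxed_threshold ",
         "(the screen would be inconsistent)", call. = FALSE)
  structure(list(groups = groups, roles = roles,
                 strict_threshold = strict_threshold,
                 relaxed_threshold = relaxed_threshold),
            class = "group_scheme")
}

#' @export
print.group_scheme <- function(x, ...) {
  cat("<group_scheme>\n")
  for (g in names(x$groups))
    cat(sprintf("  %s [%s]: %d sample(s)\n", g, x$roles[[g]], length(x$groups[[g]])))
  cat(sprintf("  thresholds: strict %.2f, relaxed %.2f\n",
              x$strict_threshold, x$relaxed_threshold))
  invisible(x)
}

#' Read a group scheme from a YAML config file
#'
#' Layout:
#' ```yaml
#' thresholds: {strict: 0.20, relaxed: 0.70}   # optional; these defaults
#' groups:
#'   pediveliger: {role: reference, samples: [P1, P2]}
#'   late_umbo:   {role: relaxed,   samples: [LU1, LU2]}
#'   other:       {role: strict,    samples: [E, T1, Gil]}
#' ```
#'
#' Sample IDs absent from a particular matrix are reported at screen time,
#' not here, so one scheme file can serve several matrices.
#'
#' @param path Path to the YAML file.
#' @return A [group_scheme()].
#' @export
load_group_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$groups) || !length(cfg$groups))
    stop("scheme file declares no groups", call. = FALSE)
  groups <- lapply(cfg$groups, function(g) as.character(unlist(g$samples)))
  roles <- vapply(cfg$groups, function(g) {
    if (is.null(g$role)) stop("every group needs a role", call. = FALSE)
    as.character(g$role)
  }, character(1))
  group_scheme(groups, roles,
               strict_threshold = cfg$thresholds$strict %||% 0.20,
               relaxed_threshold = cfg$thresholds$relaxed %||% 0.70)
}

#' Write a group scheme to a YAML config file
#'
#' @param scheme A [group_scheme()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_group_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "group_scheme"))
  cfg <- list(
    thresholds = list(strict = scheme$strict_threshold,
                      relaxed = scheme$relaxed_threshold),
    groups = lapply(names(scheme$groups), function(g)
      list(role = unname(scheme$roles[[g]]), samples = scheme$groups[[g]]))
  )
  names(cfg$groups) <- names(scheme$groups)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
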