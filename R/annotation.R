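#' @name annotation
#' @title Candidate-table annotation utilities
#' @description
#' Tools for the Table-1-style candidate table: loading and writing it,
#' classifying hypothetical proteins, tallying subcellular localizations,
#' rule-based functional grouping, and parsing the tabular outputs of
#' external domain scanners (InterProScan-style TSV) and localization
#' predictors (DeepLoc-style TSV). The package never runs those predictors;
#' it only consumes their tables.
NULL

# Closed compartment vocabulary plus the spellings predictors and printed
# tables actually use ("Plast 0.39" vs footnote "Pla").
.compartments <- c("Ext", "Cyt", "Lys", "Mit", "Pla", "Mem", "ER", "Nuc")
.compartment_aliases <- c(
  ext = "Ext", extracellular = "Ext",
  cyt = "Cyt", cytoplasm = "Cyt",
  lys = "Lys", lysosome = "Lys", "lysosome/vacuole" = "Lys",
  mit = "Mit", mitochondria = "Mit", mitochondrion = "Mit",
  pla = "Pla", plast = "Pla", plastid = "Pla",
  mem = "Mem", membrane = "Mem", "cell membrane" = "Mem",
  er = "ER", "endoplasmic reticulum" = "ER", "endoplasmic_reticulum" = "ER",
  nuc = "Nuc", nucleus = "Nuc"
)

#' Normalize a compartment label to the closed vocabulary
#'
#' @param label Character vector of compartment names as printed by a
#'   predictor or table (e.g. "Extracellular", "Plast", "ER").
#' @return Character vector over Ext/Cyt/Lys/Mit/Pla/Mem/ER/Nuc.
#' @export
normalize_compartment <- function(label) {
  key <- tolower(trimws(label))
  out <- .compartment_aliases[key]
  if (any(is.na(out)))
    stop("unknown compartment label(s): ",
         paste(unique(label[is.na(out)]), collapse = ", "), call. = FALSE)
  unname(out)
}

#' Default functional-group vocabulary
#' @return Character vector of the controlled functional-group names.
#' @export
functional_groups <- function() {
  c("Hypothetical protein", "Enzyme", "Protease inhibitor",
    "Structural protein",
    "Calcification-related protein and calcium-binding protein")
}

#' Load a candidate table
#'
#' Reads a five-column tab-separated candidate table (functional_group,
#' gene_id, protein_id, product_name, localization). The localization cell
#' is `"<compartment> <score>"` (e.g. `"Mit 0.58"`) or empty for none; the
#' compartment is normalized via [normalize_compartment()] and the score
#' must lie in [0, 1]. The packaged fixture
#' `system.file("extdata", "pediveliger_candidates.tsv", package = "stagescreen")`
#' holds the 59 pediveliger-specific oyster candidates.
#'
#' @param path Path to the TSV.
#' @return Data.frame with columns `gene_id`, `protein_id`, `product_name`,
#'   `functional_group`, `compartment` (NA for none), `loc_score`.
#' @export
load_candidate_table <- function(path) {
  if (!file.exists(path)) stop("candidate table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          check.names = FALSE, na.strings = NULL,
                          fileEncoding = "UTF-8")
  need <- c("functional_group", "gene_id", "protein_id", "product_name",
            "localization")
  if (!all(need %in% colnames(df)))
    stop("candidate table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0)
    return(data.frame(gene_id = character(), protein_id = character(),
                      product_name = character(), functional_group = character(),
                      compartment = character(), loc_score = numeric(),
                      stringsAsFactors = FALSE))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene IDs in candidate table: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "),
         call. = FALSE)
  loc <- trimws(df$localization)
  compartment <- rep(NA_character_, nrow(df))
  score <- rep(NA_real_, nrow(df))
  has_loc <- loc != ""
  if (any(has_loc)) {
    parts <- strsplit(loc[has_loc], "\\s+")
    bad <- vapply(parts, length, integer(1)) != 2
    if (any(bad))
      stop("malformed localization cell(s): ",
           paste(loc[has_loc][bad], collapse = "; "),
           " (expected '<compartment> <score>')", call. = FALSE)
    compartment[has_loc] <- normalize_compartment(vapply(parts, `[`, "", 1))
    score[has_loc] <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
    if (any(is.na(score[has_loc])) ||
        any(score[has_loc] < 0) || any(score[has_loc] > 1))
      stop("localization scores must be numbers in [0, 1]", call. = FALSE)
  }
  data.frame(gene_id = df$gene_id, protein_id = df$protein_id,
             product_name = df$product_name,
             functional_group = df$functional_group,
             compartment = compartment, loc_score = score,
             stringsAsFactors = FALSE)
}

#' Write a candidate table
#'
#' Inverse of [load_candidate_table()]; a load/write cycle is lossless.
#'
#' @param records Data.frame as returned by [load_candidate_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(records, path) {
  loc <- ifelse(is.na(records$compartment), "",
                paste(records$compartment,
                      vapply(records$loc_score, format, "", trim = TRUE)))
  out <- data.frame(functional_group = records$functional_group,
                    gene_id = records$gene_id,
                    protein_id = records$protein_id,
                    product_name = records$product_name,
                    localization = loc, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Path to the packaged pediveliger candidate fixture
#' @return File path of the 59-row candidate table shipped with the package.
#' @export
pediveliger_candidates_path <- function() {
  system.file("extdata", "pediveliger_candidates.tsv",
              package = "stagescreen", mustWork = TRUE)
}

#' Is a product name a hypothetical protein?
#'
#' True iff the name begins with "hypothetical protein", case-insensitively,
#' after trimming — the convention used for predicted proteins with no
#' functional annotation in reference databases.
#'
#' @param product_name Character vector of product names.
#' @return Logical vector.
#' @export
classify_hypothetical <- function(product_name) {
  grepl("^hypothetical protein", trimws(product_name), ignore.case = TRUE)
}

#' Tally subcellular localizations
#'
#' @param records Candidate records ([load_candidate_table()]).
#' @param subset Optional logical vector or predicate over records (e.g.
#'   `function(r) classify_hypothetical(r$product_name)`) restricting the
#'   tally.
#' @return Named integer vector of counts per compartment; records without
#'   a localization are counted under `"none"`. Counts always sum to the
#'   number of (subsetted) records.
#' @export
tally_localizations <- function(records, subset = NULL) {
  if (!is.null(subset)) {
    keep <- if (is.function(subset)) subset(records) else subset
    records <- records[keep, , drop = FALSE]
  }
  if (nrow(records) == 0) return(integer(0))
  comp <- ifelse(is.na(records$compartment), "none", records$compartment)
  tab <- table(comp)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Default keyword rules for functional-group assignment
#'
#' The published grouping reflects expert judgment; the pipeline makes the
#' rule explicit as an ordered keyword list (first match wins, matched
#' case-insensitively against the product name) that callers can replace.
#'
#' @return Data.frame with columns `pattern` (regular expression) and
#'   `group`.
#' @export
default_group_rules <- function() {
  data.frame(
    pattern = c("^hypothetical protein",
                "inhibitor",
                "tyrosinase|peroxidase|anhydrase|hyaluron|peptidase|proteinase|protease",
                "collagen|tenascin|iggfc|hemicentin|egf",
                "perlucin|calmodulin|cadherin|aggrecan|lectin|receptor"),
    group = c("Hypothetical protein",
              "Protease inhibitor",
              "Enzyme",
              "Structural protein",
              "Calcification-related protein and calcium-binding protein"),
    stringsAsFactors = FALSE
  )
}

#' Assign functional groups from product names
#'
#' @param product_name Character vector.
#' @param rules Ordered rule table as from [default_group_rules()].
#' @param unmatched Group assigned when no rule matches.
#' @return Character vector of group names.
#' @export
assign_functional_group <- function(product_name, rules = default_group_rules(),
                                    unmatched = "other") {
  out <- rep(unmatched, length(product_name))
  undecided <- rep(TRUE, length(product_name))
  for (i in seq_len(nrow(rules))) {
    hit <- undecided & grepl(rules$pattern[i], product_name, ignore.case = TRUE)
    out[hit] <- rules$group[i]
    undecided[hit] <- FALSE
  }
  out
}

#' Parse domain-scanner output (InterProScan-style TSV)
#'
#' Accepts the scanner's headerless tab-separated format with 13 or more
#' columns (protein accession, sequence MD5, length, analysis, signature
#' accession, signature description, start, stop, ...). A minimal four-column
#' layout (protein, domain, start, end) is also accepted. Coordinates are
#' 1-based inclusive residue positions and are preserved verbatim.
#'
#' @param path Path to the TSV.
#' @return Data.frame of `protein_id`, `domain_name`, `start`, `end`.
#' @export
parse_domain_scan <- function(path) {
  if (!file.exists(path)) stop("domain scan file not found: ", path, call. = FALSE)
  empty <- data.frame(protein_id = character(), domain_name = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- vapply(fields, length, integer(1))
  if (any(ncols < 4))
    stop("domain scan rows need >= 4 tab-separated columns", call. = FALSE)
  pick <- function(f) {
    if (length(f) >= 13) f[c(1, 6, 7, 8)] else f[1:4]
  }
  m <- t(vapply(fields, pick, character(4)))
  start <- suppressWarnings(as.numeric(m[, 3]))
  end <- suppressWarnings(as.numeric(m[, 4]))
  bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad))
    stop("non-integer domain position(s) in row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  if (any(start < 1 | start > end))
    stop("invalid domain coordinates (need 1 <= start <= end) in row(s): ",
         paste(which(start < 1 | start > end), collapse = ", "), call. = FALSE)
  data.frame(protein_id = m[, 1], domain_name = m[, 2],
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Summarize domain architecture over a candidate set
#'
#' @param hits Data.frame from [parse_domain_scan()].
#' @param protein_ids Candidate protein IDs; proteins with no hit are
#'   reported with zero domains so the headline count is over the full set.
#' @return List with `n_hits` (named integer vector per protein) and
#'   `n_with_domain` (number of candidates with at least one hit).
#' @export
domain_architecture_summary <- function(hits, protein_ids) {
  protein_ids <- as.character(protein_ids)
  counts <- stats::setNames(integer(length(protein_ids)), protein_ids)
  if (nrow(hits)) {
    tab <- table(hits$protein_id[hits$protein_id %in% protein_ids])
    counts[names(tab)] <- as.integer(tab)
  }
  list(n_hits = counts, n_with_domain = sum(counts > 0))
}

#' Parse subcellular-localization predictor output (DeepLoc-style TSV)
#'
#' Accepts a header line with at least `ID` and `Location` columns. When
#' per-class score columns are present (named by compartment, in any of the
#' spellings [normalize_compartment()] accepts), the predicted class's score
#' is retained; a single `Score` column is also accepted. One prediction per
#' protein; duplicates are an error.
#'
#' @param path Path to the TSV.
#' @return Data.frame of `protein_id`, `compartment`, `score`.
#' @export
parse_localization_output <- function(path) {
  if (!file.exists(path)) stop("localization file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
  cols <- colnames(df)
  id_col <- which(tolower(cols) == "id")[1]
  loc_col <- which(tolower(cols) == "location")[1]
  if (is.na(id_col) || is.na(loc_col))
    stop("localization table needs 'ID' and 'Location' columns", call. = FALSE)
  if (nrow(df) == 0)
    return(data.frame(protein_id = character(), compartment = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  ids <- df[[id_col]]
  if (anyDuplicated(ids))
    stop("duplicate protein ID(s) in localization output: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  compartment <- normalize_compartment(df[[loc_col]])
  class_cols <- stats::setNames(rep(NA_integer_, length(.compartments)),
                                .compartments)
  for (j in seq_along(cols)[-c(id_col, loc_col)]) {
    key <- tolower(trimws(cols[j]))
    if (key %in% names(.compartment_aliases))
      class_cols[.compartment_aliases[[key]]] <- j
  }
  score_col <- which(tolower(cols) == "score")[1]
  score <- numeric(nrow(df))
  for (i in seq_len(nrow(df))) {
    j <- class_cols[[compartment[i]]]
    if (is.na(j)) j <- score_col
    if (is.na(j))
      stop("no score column found for predicted class '", compartment[i],
           "' (row ", i, ")", call. = FALSE)
    score[i] <- suppressWarnings(as.numeric(df[i, j]))
  }
  if (any(is.na(score)) || any(score < 0) || any(score > 1))
    stop("localization scores must be numbers in [0, 1]", call. = FALSE)
  data.frame(protein_id = ids, compartment = compartment, score = score,
             stringsAsFactors = FALSE)
}
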