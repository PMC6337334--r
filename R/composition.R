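.standard_aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.nonstandard_aa <- c("B", "J", "O", "U", "X", "Z", "*", "-")

#' Amino-acid composition of a protein sequence
#'
#' Fractions are computed over the standard 20-residue alphabet; ambiguity
#' codes and rare residues (B, J, O, U, X, Z) and the gap/stop symbols
#' (`-`, `*`) are counted separately and excluded from the denominator, the
#' convention under which published composition percentages are reported.
#' Input is case-insensitive; whitespace is stripped. Any other symbol
#' (digits, punctuation) is an error.
#'
#' @param sequence Amino-acid sequence as a single string.
#' @param protein_id Optional identifier carried into the profile.
#' @return A `composition_profile`: `protein_id`, `length_standard`,
#'   `fractions` (named over the 20 standard residues, summing to 1 when
#'   `length_standard > 0`), `n_nonstandard`.
#' @export
composition_profile <- function(sequence, protein_id = NA_character_) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  seq <- toupper(gsub("\\s+", "", sequence))
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(chars), c(.standard_aa, .nonstandard_aa))
  if (length(bad))
    stop("invalid symbol(s) in sequence: ", paste(bad, collapse = " "),
         call. = FALSE)
  counts <- table(factor(chars, levels = .standard_aa))
  n_std <- sum(counts)
  fractions <- stats::setNames(rep(0, length(.standard_aa)), .standard_aa)
  if (n_std > 0) fractions[] <- as.numeric(counts) / n_std
  structure(list(protein_id = protein_id,
                 length_standard = as.integer(n_std),
                 fractions = fractions,
                 n_nonstandard = length(chars) - as.integer(n_std)),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("<composition_profile> %s: %d standard residues (%d nonstandard)\n",
              x$protein_id %||% "?", x$length_standard, x$n_nonstandard))
  top <- sort(x$fractions, decreasing = TRUE)[1:5]
  cat("  top residues:",
      paste(sprintf("%s %.1f%%", names(top), 100 * top), collapse = ", "), "\n")
  invisible(x)
}

#' Default composition flag rules
#'
#' Thresholds sit near the levels at which collagen-like glycine/proline
#' enrichment and disulfide-capable cysteine richness are conventionally
#' called, and are plain data so callers can adjust them.
#'
#' @return Data.frame with columns `flag`, `residue`, `min_fraction`.
#' @export
default_composition_rules <- function() {
  data.frame(flag = c("collagen-like glycine", "collagen-like proline",
                      "cysteine-rich"),
             residue = c("G", "P", "C"),
             min_fraction = c(0.20, 0.10, 0.05),
             stringsAsFactors = FALSE)
}

#' Flag a composition profile against residue-enrichment rules
#'
#' A flag is raised when the residue's fraction is greater than or equal to
#' the rule's minimum.
#'
#' @param profile A [composition_profile()].
#' @param rules Rule table as from [default_composition_rules()].
#' @return Character vector of raised flag names (possibly empty).
#' @export
flag_composition <- function(profile, rules = default_composition_rules()) {
  stopifnot(inherits(profile, "composition_profile"))
  if (is.null(rules) || nrow(rules) == 0) return(character(0))
  raised <- profile$fractions[rules$residue] >= rules$min_fraction
  rules$flag[raised]
}

#' Composition profiles for every record of a protein FASTA
#'
#' Record IDs are the first whitespace-delimited token of each header;
#' duplicates are an error. Sequence case is irrelevant.
#'
#' @param fasta_path Path to a FASTA file of amino-acid sequences.
#' @return List of [composition_profile()]s, input order preserved.
#' @export
batch_composition <- function(fasta_path) {
  if (!file.exists(fasta_path))
    stop("FASTA file not found: ", fasta_path, call. = FALSE)
  seqs <- tryCatch(Biostrings::readAAStringSet(fasta_path),
                   error = function(e) stop("malformed FASTA: ",
                                            conditionMessage(e), call. = FALSE))
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1)
  if (anyDuplicated(ids))
    stop("duplicate FASTA record ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  mapply(composition_profile, as.character(seqs), ids,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Tabulate composition profiles
#'
#' @param profiles List of [composition_profile()]s.
#' @param rules Flag rules passed to [flag_composition()].
#' @return Data.frame: `protein_id`, `length_standard`, one column per
#'   standard residue (full-precision fraction), `n_nonstandard`, `flags`
#'   (comma-separated).
#' @export
composition_table <- function(profiles, rules = default_composition_rules()) {
  if (!length(profiles))
    return(data.frame(protein_id = character(), length_standard = integer(),
                      stringsAsFactors = FALSE))
  frac <- do.call(rbind, lapply(profiles, function(p) p$fractions))
  data.frame(
    protein_id = vapply(profiles, function(p) p$protein_id, ""),
    length_standard = vapply(profiles, function(p) p$length_standard, 0L),
    frac,
    n_nonstandard = vapply(profiles, function(p) p$n_nonstandard, 0L),
    flags = vapply(profiles, function(p)
      paste(flag_composition(p, rules), collapse = ","), ""),
    stringsAsFactors = FALSE, check.names = FALSE
  )
}

#' Format a fraction as a one-decimal percentage
#'
#' Reporting convention: percentages printed to one decimal; stored values
#' keep full precision.
#'
#' @param x Numeric fractions in [0, 1].
#' @return Character vector like `"25.7%"`.
#' @export
percent1 <- function(x) sprintf("%.1f%%", round(100 * x, 1))
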