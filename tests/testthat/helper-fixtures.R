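# Small in-code fixtures shared across test files.

# Minimal scheme: 2 reference, 2 relaxed, 4 strict samples.
tiny_scheme <- function(strict_threshold = 0.20, relaxed_threshold = 0.70) {
  group_scheme(
    groups = list(ped = c("P1", "P2"), lu = c("LU1", "LU2"),
                  rest = c("E", "U1", "Gil", "Mtl")),
    roles = c(ped = "reference", lu = "relaxed", rest = "strict"),
    strict_threshold = strict_threshold,
    relaxed_threshold = relaxed_threshold
  )
}

tiny_matrix <- function(rows) {
  samples <- c("P1", "P2", "LU1", "LU2", "E", "U1", "Gil", "Mtl")
  m <- do.call(rbind, rows)
  colnames(m) <- samples
  expression_matrix(m)
}

# Random non-negative matrix over the tiny scheme's samples.
random_tiny_matrix <- function(n_genes) {
  m <- matrix(round(stats::rexp(n_genes * 8, rate = 0.1), 3), n_genes, 8)
  rownames(m) <- sprintf("g%03d", seq_len(n_genes))
  colnames(m) <- c("P1", "P2", "LU1", "LU2", "E", "U1", "Gil", "Mtl")
  expression_matrix(m)
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Independent per-letter counting loop used as the composition oracle.
naive_composition <- function(seq) {
  seq <- toupper(gsub("\\s", "", seq))
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  counts <- stats::setNames(rep(0, 20), std)
  n_std <- 0
  for (i in seq_len(nchar(seq))) {
    ch <- substr(seq, i, i)
    if (ch %in% std) {
      counts[ch] <- counts[ch] + 1
      n_std <- n_std + 1
    }
  }
  counts / n_std
}
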