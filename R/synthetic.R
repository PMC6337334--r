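#' Default oyster-style sample layout and grouping
#'
#' Mirrors the shape of the developmental RPKM table the screen was built
#' around: 38 developmental sampling times (two of which are the reference
#' pediveliger samples P1/P2 and two the relaxed late-umbo samples LU1/LU2)
#' plus 11 adult-organ samples, all others strict. Sample labels are
#' invented but plausible stage/organ codes.
#'
#' @param strict_dev Number of strict developmental samples (default 34).
#' @param organs Number of adult-organ samples (default 11).
#' @param strict_threshold,relaxed_threshold Passed to [group_scheme()].
#' @return A [group_scheme()] with groups `pediveliger` (reference),
#'   `late_umbo` (relaxed), `early_stages` and `adult_organs` (strict).
#' @export
default_oyster_scheme <- function(strict_dev = 34, organs = 11,
                                  strict_threshold = 0.20,
                                  relaxed_threshold = 0.70) {
  dev_pool <- c("E", "M", "B", "G", "T1", "T2", paste0("D", 1:12),
                paste0("U", 1:6), paste0("EU", 1:8), "S", "J")
  organ_pool <- c("Gil", "Mtl", "Amu", "Dgl", "Lpa", "Hem", "Fgo", "Mgo",
                  "Msc", "Ngl", "Gon")
  if (strict_dev > length(dev_pool) || organs > length(organ_pool))
    stop("at most ", length(dev_pool), " developmental and ",
         length(organ_pool), " organ samples available", call. = FALSE)
  group_scheme(
    groups = list(pediveliger = c("P1", "P2"),
                  late_umbo = c("LU1", "LU2"),
                  early_stages = dev_pool[seq_len(strict_dev)],
                  adult_organs = organ_pool[seq_len(organs)]),
    roles = c(pediveliger = "reference", late_umbo = "relaxed",
              early_stages = "strict", adult_organs = "strict"),
    strict_threshold = strict_threshold,
    relaxed_threshold = relaxed_threshold
  )
}

#' Generate a synthetic RPKM matrix with planted stage-specific genes
#'
#' Background genes draw a per-gene log-normal baseline shared across all
#' samples with multiplicative log-normal noise, so their expression is
#' broad and they rarely pass the screen. Planted reference-specific genes
#' draw a reference level R >= 1 (one reference sample is set to R exactly)
#' and every non-reference sample uniformly in
#' `[0, threshold / margin * R)` for its group's threshold, so they pass
#' the screen by construction for any `margin > 1`. Near-miss genes use the
#' same construction but place exactly one strict sample at
#' `strict_threshold * R * margin`, violating exactly that one condition,
#' so they fail for any `margin > 1`.
#'
#' @param n_genes Total genes (background + planted).
#' @param n_specific Planted reference-specific genes.
#' @param n_near_miss Planted near-miss genes.
#' @param margin Margin factor m > 1 separating planted genes from the
#'   thresholds.
#' @param scheme Sampling layout; defaults to [default_oyster_scheme()].
#' @param log_mean,log_sd Log-normal parameters of the background baseline.
#' @param noise_sd Log-scale standard deviation of per-sample noise.
#' @param seed Integer seed; generation is reproducible given the seed.
#' @return List with `matrix` (an [expression_matrix()]), `truth` (a
#'   `synthetic_truth`: `planted_specific`, `planted_near_miss`, `params`),
#'   and `scheme`.
#' @export
generate_matrix <- function(n_genes = 1000, n_specific = 50, n_near_miss = 25,
                            margin = 10, scheme = default_oyster_scheme(),
                            log_mean = 1, log_sd = 1.5, noise_sd = 0.25,
                            seed = 1) {
  if (margin <= 1) stop("margin must exceed 1", call. = FALSE)
  if (n_specific + n_near_miss > n_genes)
    stop("planted genes exceed n_genes", call. = FALSE)
  ref_samples <- unlist(scheme$groups[scheme$roles == "reference"],
                        use.names = FALSE)
  if (length(ref_samples) < 1)
    stop("scheme needs at least one reference sample", call. = FALSE)
  set.seed(seed)
  samples <- unlist(scheme$groups, use.names = FALSE)
  thr_of <- stats::setNames(rep(NA_real_, length(samples)), samples)
  for (g in names(scheme$groups)) {
    thr_of[scheme$groups[[g]]] <- switch(scheme$roles[[g]],
      reference = NA_real_,
      strict = scheme$strict_threshold,
      relaxed = scheme$relaxed_threshold)
  }
  non_ref <- samples[!is.na(thr_of)]
  strict_samples <- samples[!is.na(thr_of) & thr_of == scheme$strict_threshold]

  n_bg <- n_genes - n_specific - n_near_miss
  gene_ids <- sprintf("SYN_%05d", seq_len(n_genes))
  spec_ids <- if (n_specific) gene_ids[seq_len(n_specific)] else character(0)
  miss_ids <- if (n_near_miss)
    gene_ids[n_specific + seq_len(n_near_miss)] else character(0)

  mat <- matrix(0, n_genes, length(samples),
                dimnames = list(gene_ids, samples))
  planted_row <- function(i) {
    R <- 1 + stats::rlnorm(1, meanlog = 3, sdlog = 1)
    row <- stats::setNames(numeric(length(samples)), samples)
    row[ref_samples] <- stats::runif(length(ref_samples), 0.5 * R, R)
    row[ref_samples[1]] <- R
    row[non_ref] <- stats::runif(length(non_ref)) * thr_of[non_ref] / margin * R
    row
  }
  for (i in seq_len(n_specific)) mat[spec_ids[i], ] <- planted_row(i)
  for (i in seq_len(n_near_miss)) {
    row <- planted_row(i)
    R <- row[ref_samples[1]]
    hot <- sample(strict_samples, 1)
    row[hot] <- scheme$strict_threshold * R * margin
    mat[miss_ids[i], ] <- row
  }
  if (n_bg > 0) {
    bg_ids <- gene_ids[(n_specific + n_near_miss + 1):n_genes]
    base <- stats::rlnorm(n_bg, meanlog = log_mean, sdlog = log_sd)
    noise <- matrix(stats::rlnorm(n_bg * length(samples), 0, noise_sd),
                    n_bg, length(samples))
    mat[bg_ids, ] <- base * noise
  }
  truth <- structure(list(planted_specific = spec_ids,
                          planted_near_miss = miss_ids,
                          params = list(n_genes = n_genes,
                                        n_specific = n_specific,
                                        n_near_miss = n_near_miss,
                                        margin = margin, log_mean = log_mean,
                                        log_sd = log_sd, noise_sd = noise_sd,
                                        seed = seed)),
                     class = "synthetic_truth")
  list(matrix = expression_matrix(mat), truth = truth, scheme = scheme)
}

#' Recovery metrics of a screen run against planted ground truth
#'
#' @param results Data.frame from [screen_genes()].
#' @param truth `synthetic_truth` from [generate_matrix()].
#' @return List: `sensitivity` (selected fraction of planted-specific
#'   genes; NaN when none were planted), `near_miss_false_positives`
#'   (selected near-miss count), `background_fpr` (selected fraction of
#'   background genes; NaN when there are none).
#' @export
recovery_metrics <- function(results, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  planted <- c(truth$planted_specific, truth$planted_near_miss)
  missing <- setdiff(planted, results$gene_id)
  if (length(missing))
    stop("truth gene(s) missing from results: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  sel <- stats::setNames(results$selected, results$gene_id)
  bg <- setdiff(results$gene_id, planted)
  list(
    sensitivity = if (length(truth$planted_specific))
      mean(sel[truth$planted_specific]) else NaN,
    near_miss_false_positives = if (length(truth$planted_near_miss))
      sum(sel[truth$planted_near_miss]) else 0L,
    background_fpr = if (length(bg)) mean(sel[bg]) else NaN
  )
}

#' Generate companion annotation files for a synthetic matrix
#'
#' Writes, for the planted-specific genes of a [generate_matrix()] run, a
#' consistent bundle the downstream stages can consume: a protein FASTA
#' (a configurable fraction of sequences built collagen-like — Gly-X-Y
#' triplets giving exactly 1/3 glycine and ~11% proline, so composition
#' flags fire by construction), a candidate annotation TSV, a domain-scan
#' TSV (collagen-like proteins get a triple-helix hit, others sporadic EGF
#' hits), and a localization TSV biased extracellular. All files parse
#' cleanly through the package's own parsers.
#'
#' @param truth `synthetic_truth` from [generate_matrix()].
#' @param dir Output directory (created if needed).
#' @param collagen_fraction Fraction of planted proteins built
#'   collagen-like.
#' @param seed Integer seed.
#' @return Named list of file paths: `fasta`, `annotations`, `domains`,
#'   `localization`.
#' @export
generate_companion_files <- function(truth, dir, collagen_fraction = 0.2,
                                     seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  genes <- truth$planted_specific
  n <- length(genes)
  prot <- sprintf("SYP%05d", seq_len(n))
  n_col <- ceiling(collagen_fraction * n)
  is_col <- seq_len(n) <= n_col
  other_aa <- setdiff(.standard_aa, c("G", "P"))

  collagen_seq <- function() {
    n_trip <- 100
    n_pro <- 33  # proline in the X position of 33/100 triplets: 11% overall
    x <- c(rep("P", n_pro),
           sample(other_aa, n_trip - n_pro, replace = TRUE))[sample(n_trip)]
    y <- sample(other_aa, n_trip, replace = TRUE)
    paste(rbind("G", x, y), collapse = "")
  }
  random_seq <- function()
    paste(sample(.standard_aa, sample(150:600, 1), replace = TRUE),
          collapse = "")
  seqs <- vapply(seq_len(n),
                 function(i) if (is_col[i]) collagen_seq() else random_seq(),
                 "")
  fasta <- file.path(dir, "proteins.faa")
  writeLines(paste0(">", prot, " synthetic\n", seqs), fasta)

  name <- ifelse(is_col, "Collagen-like protein",
                 paste("Hypothetical protein", genes))
  comp <- ifelse(stats::runif(n) < 0.7, "Ext",
                 sample(c("Cyt", "Mem", "Nuc"), n, replace = TRUE))
  score <- round(stats::runif(n, 0.3, 1), 2)
  ann <- file.path(dir, "annotations.tsv")
  utils::write.table(
    data.frame(functional_group = assign_functional_group(name),
               gene_id = genes, protein_id = prot, product_name = name,
               localization = paste(comp, score), stringsAsFactors = FALSE),
    ann, sep = "\t", quote = FALSE, row.names = FALSE)

  dom_rows <- character(0)
  for (i in seq_len(n)) {
    if (is_col[i]) {
      dom_rows <- c(dom_rows, paste(prot[i], "Collagen triple helix repeat",
                                    31, 270, sep = "\t"))
    } else if (stats::runif(1) < 0.5) {
      s <- sample(10:200, 1)
      dom_rows <- c(dom_rows, paste(prot[i], "EGF-like domain",
                                    s, s + 35, sep = "\t"))
    }
  }
  dom <- file.path(dir, "domains.tsv")
  writeLines(dom_rows, dom)

  loc <- file.path(dir, "localization.tsv")
  long <- c(Ext = "Extracellular", Cyt = "Cytoplasm", Mem = "Cell membrane",
            Nuc = "Nucleus")
  utils::write.table(
    data.frame(ID = prot, Location = unname(long[comp]), Score = score,
               stringsAsFactors = FALSE),
    loc, sep = "\t", quote = FALSE, row.names = FALSE)

  list(fasta = fasta, annotations = ann, domains = dom, localization = loc)
}

#' Write a full synthetic analysis bundle
#'
#' Convenience wrapper generating the matrix, its scheme file, and all
#' companion annotation files into one directory, ready for
#' [run_pipeline()].
#'
#' @inheritParams generate_matrix
#' @param dir Output directory.
#' @param ... Passed to [generate_matrix()].
#' @return Named list of paths plus the `truth` object.
#' @export
simulate_bundle <- function(dir, seed = 1, ...) {
  sim <- generate_matrix(seed = seed, ...)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  matrix_path <- file.path(dir, "rpkm.tsv")
  scheme_path <- file.path(dir, "scheme.yaml")
  write_rpkm_table(sim$matrix, matrix_path)
  write_group_scheme(sim$scheme, scheme_path)
  companions <- generate_companion_files(sim$truth, dir, seed = seed + 1)
  c(list(matrix = matrix_path, scheme = scheme_path, truth = sim$truth),
    companions)
}
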