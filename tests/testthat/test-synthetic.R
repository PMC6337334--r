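test_that("generation is deterministic given the seed", {
  a <- generate_matrix(n_genes = 200, n_specific = 20, n_near_miss = 10,
                       margin = 10, seed = 42)
  b <- generate_matrix(n_genes = 200, n_specific = 20, n_near_miss = 10,
                       margin = 10, seed = 42)
  expect_identical(unclass(a$matrix), unclass(b$matrix))
  expect_identical(a$truth$planted_specific, b$truth$planted_specific)
  c <- generate_matrix(n_genes = 200, n_specific = 20, n_near_miss = 10,
                       margin = 10, seed = 43)
  expect_false(identical(unclass(a$matrix), unclass(c$matrix)))
})

test_that("the default layout mirrors the oyster table shape", {
  sim <- generate_matrix(n_genes = 10, n_specific = 2, n_near_miss = 2,
                         seed = 1)
  expect_equal(ncol(sim$matrix), 49)  # 38 developmental + 11 organ samples
  expect_true(all(c("P1", "P2", "LU1", "LU2") %in% colnames(sim$matrix)))
  expect_true(all(unclass(sim$matrix) >= 0))
})

test_that("planted sets are disjoint and present in the matrix", {
  sim <- generate_matrix(n_genes = 300, n_specific = 30, n_near_miss = 15,
                         seed = 7)
  expect_length(intersect(sim$truth$planted_specific,
                          sim$truth$planted_near_miss), 0)
  expect_true(all(c(sim$truth$planted_specific,
                    sim$truth$planted_near_miss) %in% rownames(sim$matrix)))
})

test_that("degenerate generator parameters are rejected", {
  expect_error(generate_matrix(margin = 1, seed = 1), "margin")
  expect_error(generate_matrix(n_genes = 10, n_specific = 9, n_near_miss = 9,
                               seed = 1), "exceed")
})

test_that("planted-specific genes pass and near-misses fail at margin 10", {
  sim <- generate_matrix(n_genes = 500, n_specific = 40, n_near_miss = 20,
                         margin = 10, seed = 42)
  res <- screen_genes(sim$matrix, sim$scheme)
  met <- recovery_metrics(res, sim$truth)
  expect_equal(met$sensitivity, 1.0)
  expect_equal(met$near_miss_false_positives, 0)
  # planted genes pass under every reference statistic at this margin
  for (stat in c("min", "mean")) {
    met2 <- recovery_metrics(screen_genes(sim$matrix, sim$scheme, stat),
                             sim$truth)
    expect_equal(met2$sensitivity, 1.0)
  }
})

test_that("near-miss false positives stay zero for any margin above one", {
  for (m in c(1.01, 2, 5)) {
    sim <- generate_matrix(n_genes = 120, n_specific = 10, n_near_miss = 30,
                           margin = m, seed = 3)
    met <- recovery_metrics(screen_genes(sim$matrix, sim$scheme), sim$truth)
    expect_equal(met$near_miss_false_positives, 0)
    expect_equal(met$sensitivity, 1.0)
  }
})

test_that("raising thresholds toward 1 increases background selection", {
  sim <- generate_matrix(n_genes = 800, n_specific = 0, n_near_miss = 0,
                         log_sd = 1, noise_sd = 1, seed = 13)
  tight <- default_oyster_scheme(strict_threshold = 0.05,
                                 relaxed_threshold = 0.05)
  loose <- default_oyster_scheme(strict_threshold = 0.999,
                                 relaxed_threshold = 0.999)
  fpr_tight <- recovery_metrics(screen_genes(sim$matrix, tight),
                                sim$truth)$background_fpr
  fpr_loose <- recovery_metrics(screen_genes(sim$matrix, loose),
                                sim$truth)$background_fpr
  expect_gte(fpr_loose, fpr_tight)
  expect_gt(fpr_loose, 0)
})

test_that("recovery metrics handle inversions, gaps, and empty truth", {
  sim <- generate_matrix(n_genes = 100, n_specific = 10, n_near_miss = 5,
                         seed = 21)
  res <- screen_genes(sim$matrix, sim$scheme)
  inverted <- res
  inverted$selected <- !inverted$selected
  expect_equal(recovery_metrics(inverted, sim$truth)$sensitivity, 0.0)
  expect_error(recovery_metrics(res[-1, ], sim$truth), "missing from results")
  empty <- generate_matrix(n_genes = 50, n_specific = 0, n_near_miss = 0,
                           seed = 2)
  met <- recovery_metrics(screen_genes(empty$matrix, empty$scheme),
                          empty$truth)
  expect_true(is.nan(met$sensitivity))
})

test_that("companion files are consistent and parse through the package", {
  sim <- generate_matrix(n_genes = 100, n_specific = 20, n_near_miss = 5,
                         seed = 17)
  dir <- withr::local_tempdir()
  paths <- generate_companion_files(sim$truth, dir, collagen_fraction = 0.25,
                                    seed = 18)
  ann <- load_candidate_table(paths$annotations)
  expect_setequal(ann$gene_id, sim$truth$planted_specific)
  profiles <- batch_composition(paths$fasta)
  expect_length(profiles, 20)
  expect_setequal(vapply(profiles, function(p) p$protein_id, ""),
                  ann$protein_id)
  loc <- parse_localization_output(paths$localization)
  expect_setequal(loc$protein_id, ann$protein_id)
  hits <- parse_domain_scan(paths$domains)
  expect_true(all(hits$protein_id %in% ann$protein_id))

  # collagen-like sequences hit the composition flags by construction
  is_col <- ann$product_name == "Collagen-like protein"
  expect_equal(sum(is_col), 5)
  col_prof <- profiles[vapply(profiles, function(p) p$protein_id, "") %in%
                         ann$protein_id[is_col]]
  for (p in col_prof) {
    expect_gte(p$fractions[["G"]], 0.25)
    expect_true("collagen-like glycine" %in% flag_composition(p))
    expect_true("collagen-like proline" %in% flag_composition(p))
  }
})
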