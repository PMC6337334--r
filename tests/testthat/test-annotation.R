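test_that("the packaged candidate fixture loads with 59 validated records", {
  rec <- load_candidate_table(pediveliger_candidates_path())
  expect_equal(nrow(rec), 59)
  first <- rec[rec$gene_id == "CGI_10014580", ]
  expect_equal(first$protein_id, "EKC18206")
  expect_equal(first$compartment, "Mit")
  expect_equal(first$loc_score, 0.58)
  # printed "Plast" normalizes into the closed vocabulary
  expect_equal(rec$compartment[rec$gene_id == "CGI_10003099"], "Pla")
  expect_true(all(rec$compartment %in%
                    c("Ext", "Cyt", "Lys", "Mit", "Pla", "Mem", "ER", "Nuc")))
})

test_that("candidate tables round-trip losslessly and reject bad cells", {
  rec <- load_candidate_table(pediveliger_candidates_path())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_candidate_table(rec, path)
  expect_equal(load_candidate_table(path), rec)

  hdr <- "functional_group\tgene_id\tprotein_id\tproduct_name\tlocalization"
  expect_equal(nrow(load_candidate_table(write_tsv_fixture(hdr))), 0)
  bad_comp <- write_tsv_fixture(c(hdr, "Enzyme\tg1\tp1\tFoo\tMoon 0.5"))
  expect_error(load_candidate_table(bad_comp), "unknown compartment")
  bad_score <- write_tsv_fixture(c(hdr, "Enzyme\tg1\tp1\tFoo\tExt 1.5"))
  expect_error(load_candidate_table(bad_score), "\\[0, 1\\]")
})

test_that("hypothetical-protein classification is a case-insensitive prefix test", {
  expect_true(classify_hypothetical("Hypothetical protein CGI_10014580"))
  expect_true(classify_hypothetical("  hypothetical PROTEIN x"))
  expect_false(classify_hypothetical("Putative tyrosinase-like protein tyr 1"))
  expect_false(classify_hypothetical("Protein, hypothetical"))
  expect_false(classify_hypothetical(""))
  rec <- load_candidate_table(pediveliger_candidates_path())
  expect_identical(classify_hypothetical(rec$product_name),
                   rec$functional_group == "Hypothetical protein")
})

test_that("localization tallies reproduce the published counts and sum to n", {
  rec <- load_candidate_table(pediveliger_candidates_path())
  tal <- tally_localizations(rec)
  expect_equal(tal[["Ext"]], 42)
  expect_equal(sum(tal), nrow(rec))
  hyp <- tally_localizations(rec, function(r) classify_hypothetical(r$product_name))
  expect_equal(hyp[["Ext"]], 15)
  expect_equal(sum(hyp), 21)
  expect_equal(tally_localizations(rec[0, ]), integer(0))
})

test_that("records without localization land in the none bucket", {
  rec <- data.frame(gene_id = c("a", "b"), protein_id = c("pa", "pb"),
                    product_name = c("x", "y"), functional_group = c("other", "other"),
                    compartment = c("Ext", NA), loc_score = c(0.9, NA))
  tal <- tally_localizations(rec)
  expect_equal(tal[["none"]], 1)
  expect_equal(sum(tal), 2)
})

test_that("keyword rules reproduce the fixture's functional groups", {
  rec <- load_candidate_table(pediveliger_candidates_path())
  expect_identical(assign_functional_group(rec$product_name),
                   rec$functional_group)
  expect_equal(assign_functional_group("Unclassifiable widget"), "other")
})

test_that("domain-scan parsing keeps 1-based inclusive coordinates", {
  full <- paste(c("EKC19955", "md5", "500", "Pfam", "PF00008",
                  "EGF-like domain", "277", "312", "1e-9", "T",
                  "01-01-2020", "IPR000742", "EGF-like domain"),
                collapse = "\t")
  mini <- "EKC19955\tCUB domain\t320\t438"
  hits <- parse_domain_scan(write_tsv_fixture(c(full, mini)))
  expect_equal(hits$start, c(277L, 320L))
  expect_equal(hits$end, c(312L, 438L))
  expect_equal(hits$domain_name, c("EGF-like domain", "CUB domain"))
  expect_equal(nrow(parse_domain_scan(write_tsv_fixture(character(0)))), 0)
  expect_error(parse_domain_scan(write_tsv_fixture("p\td\t40\t30")),
               "start <= end")
  expect_error(parse_domain_scan(write_tsv_fixture("p\td\t1.5\t30")),
               "non-integer")
})

test_that("domain architecture summaries count zero-hit proteins", {
  hits <- parse_domain_scan(write_tsv_fixture(
    c("A\tEGF\t1\t30", "A\tEGF\t40\t70", "B\tCUB\t5\t90")))
  s <- domain_architecture_summary(hits, c("A", "B", "C"))
  expect_equal(s$n_hits, c(A = 2L, B = 1L, C = 0L))
  expect_equal(s$n_with_domain, 2)
  empty <- domain_architecture_summary(hits[0, ], c("A", "B"))
  expect_equal(empty$n_with_domain, 0)
})

test_that("localization predictor output parses with class-name normalization", {
  path <- write_tsv_fixture(c(
    "ID\tLocation\tExtracellular\tCytoplasm\tEndoplasmic reticulum",
    "p1\tExtracellular\t0.99\t0.01\t0.00",
    "p2\tEndoplasmic reticulum\t0.10\t0.30\t0.40"))
  loc <- parse_localization_output(path)
  expect_equal(loc$compartment, c("Ext", "ER"))
  expect_equal(loc$score, c(0.99, 0.40))

  simple <- parse_localization_output(write_tsv_fixture(
    c("ID\tLocation\tScore", "p1\tCell membrane\t0.77")))
  expect_equal(simple$compartment, "Mem")
  expect_equal(simple$score, 0.77)

  expect_error(parse_localization_output(write_tsv_fixture(
    c("ID\tLocation\tScore", "p1\tExtracellular\t0.9", "p1\tNucleus\t0.3"))),
    "duplicate")
  expect_error(parse_localization_output(write_tsv_fixture(
    c("ID\tLocation\tScore", "p1\tOuterSpace\t0.9"))),
    "OuterSpace")
})
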