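test_that("the database holds exactly the four tables with the input counts", {
  inp <- toy_store_inputs()
  db <- build_database(inp$snps, inp$genes, inp$links, inp$consequences)
  on.exit(close_database(db))
  expect_setequal(db_tables(db),
                  c("snp_info", "gene_info", "snp_region", "TFBS_results"))
  expect_equal(length(db_tables(db)), 4L)
  expect_equal(unname(db_counts(db)), c(3L, 2L, 4L, 2L))
})

test_that("integrity violations abort the build with the offending row named", {
  inp <- toy_store_inputs()
  dup <- rbind(inp$snps, inp$snps[1, ])
  expect_error(build_database(dup, inp$genes, inp$links, inp$consequences),
               "duplicate snp_id.*s1")
  bad_link <- inp$links
  bad_link$snp_id[1] <- "ghost"
  expect_error(build_database(inp$snps, inp$genes, bad_link, inp$consequences),
               "unknown snp_id.*ghost")
  bad_cons <- inp$consequences
  bad_cons$gene_strand[1] <- "-"  # s1 links only to + genes on that strand? s1 links gA(+) and gB(-)
  bad_cons$snp_id[1] <- "s2"      # s2 links only to gA (+): "-" has no join
  expect_error(build_database(inp$snps, inp$genes, inp$links, bad_cons),
               "joins to no snp_region")
})

test_that("no_change rows are excluded by default and kept on request", {
  inp <- toy_store_inputs()
  cons <- rbind(inp$consequences,
                within(inp$consequences[1, ], {
                  seq_offset <- 10L; consequence <- "no_change"
                  alt_core_score <- 0.95; alt_matrix_score <- 0.93
                  alt_site_seq <- "aaTATAAtt"
                }))
  db1 <- build_database(inp$snps, inp$genes, inp$links, cons)
  expect_equal(unname(db_counts(db1)["TFBS_results"]), 2L)
  close_database(db1)
  db2 <- build_database(inp$snps, inp$genes, inp$links, cons,
                        keep_no_change = TRUE)
  expect_equal(unname(db_counts(db2)["TFBS_results"]), 3L)
  close_database(db2)
})

test_that("rebuilding from identical inputs gives byte-identical exports", {
  inp <- toy_store_inputs()
  out <- character(2)
  for (i in 1:2) {
    db <- build_database(inp$snps, inp$genes, inp$links, inp$consequences)
    out[i] <- tempfile(fileext = ".tsv")
    export_results(db, out[i])
    close_database(db)
  }
  expect_identical(readLines(out[1]), readLines(out[2]))
  expect_gt(length(readLines(out[1])), 1)
})

test_that("query modes agree and multi-ID search is a union without duplicates", {
  inp <- toy_store_inputs()
  db <- build_database(inp$snps, inp$genes, inp$links, inp$consequences)
  on.exit(close_database(db))
  one <- query_database(db, "snp_ids", "s1")
  expect_equal(unique(one$snp_id), "s1")
  expect_equal(one$consequence, "loss")
  expect_true(all(c("ref_bound", "alt_bound") %in% names(one)))
  expect_equal(one$ref_bound, TRUE)
  expect_equal(one$alt_bound, FALSE)
  multi <- query_database(db, "snp_ids", "s1 s2 s2")
  expect_equal(multi, query_database(db, "snp_ids", c("s1", "s2")))
  expect_false(any(duplicated(multi[, c("snp_id", "gene_id", "pwm_id",
                                        "seq_offset", "orientation")])))
  pos <- query_database(db, "position", list("chr1", 1100))
  expect_equal(pos, one)
  expect_warning(empty <- query_database(db, "snp_ids", "nope"), "unknown")
  expect_equal(nrow(empty), 0L)
  expect_warning(query_database(db, "gene", "missing_gene"), "unknown gene")
})

test_that("queries re-filter by the user window and refuse wider-than-built ones", {
  inp <- toy_store_inputs()
  db <- build_database(inp$snps, inp$genes, inp$links, inp$consequences)
  on.exit(close_database(db))
  # s1 sits at -900 for gA: inside the default -1 kb, outside -500 bp
  expect_equal(nrow(query_database(db, "snp_ids", "s1")), 1L)
  expect_equal(nrow(query_database(db, "snp_ids", "s1", upstream_bp = 500)), 0L)
  expect_error(query_database(db, "snp_ids", "s1", upstream_bp = 8000),
               "exceeds")
})

test_that("a region query covering a chromosome equals its chromosome-wise export", {
  inp <- toy_store_inputs()
  db <- build_database(inp$snps, inp$genes, inp$links, inp$consequences)
  on.exit(close_database(db))
  reg <- query_database(db, "region", "chr1:1-99999",
                        upstream_bp = db$built_upstream_bp,
                        downstream_bp = db$built_downstream_bp)
  exp_path <- tempfile(fileext = ".tsv")
  export_results(db, exp_path, chrom = "chr1")
  exported <- read.delim(exp_path)
  expect_equal(nrow(reg), nrow(exported))
  expect_equal(reg$snp_id, exported$snp_id)
  expect_equal(reg$pwm_id, exported$pwm_id)
  # union of per-chromosome exports = full results table
  full_path <- tempfile(fileext = ".tsv")
  export_results(db, full_path)
  expect_equal(readLines(exp_path), readLines(full_path))  # single chromosome
})

test_that("the export marks the SNP base with brackets inside the site", {
  inp <- toy_store_inputs()
  db <- build_database(inp$snps, inp$genes, inp$links, inp$consequences)
  on.exit(close_database(db))
  path <- tempfile(fileext = ".tsv")
  export_results(db, path)
  tab <- read.delim(path)
  # s1's loss site: offset 24, width 9 -> SNP at string position 3
  row <- tab[tab$snp_id == "s1", ]
  expect_equal(row$ref_site_seq, "aa[T]ATAAtt")
})

test_that("gene queries return only that gene's rows, by id or name", {
  inp <- toy_store_inputs()
  db <- build_database(inp$snps, inp$genes, inp$links, inp$consequences)
  on.exit(close_database(db))
  by_id <- query_database(db, "gene", "gA")
  expect_true(all(by_id$gene_id == "gA"))
  expect_equal(nrow(by_id), 2L)  # s1 loss + s2 score_change within -1kb/+100
})

test_that("summary statistics follow their definitions", {
  inp <- toy_store_inputs()
  db <- build_database(inp$snps, inp$genes, inp$links, inp$consequences)
  on.exit(close_database(db))
  st <- summarize_database(db)
  # within -1 kb/+100 bp: links s1/gA (-900), s2/gA (-100), s3/gA (+50)
  expect_equal(st$n_snps, 3L)
  expect_equal(st$n_rsnps, 2L)          # s1 (loss), s2 (score_change)
  expect_equal(st$pct_rsnp, 100 * 2 / 3)
  expect_equal(st$n_genes, 2L)
  expect_equal(st$rsnps_per_promoter, 1.0)  # gA has 2, gB has 0 -> mean 1.0
  expect_equal(st$tfbs_per_rsnp, 1.0)
  # rSNP links in [-750, +250): only s2 at -100 (s1 sits at -900; s3 is no rSNP)
  expect_equal(sum(st$tss_histogram), 1L)
  expect_equal(unname(st$tss_histogram["[-100,-50)"]), 1L)  # left-closed bin
})

test_that("per-gene rSNP averages and the bin-edge convention are exact", {
  # 2 genes; gene A with 3 rSNPs, gene B with 0 -> 1.5 per promoter
  snps <- data.frame(snp_id = paste0("r", 1:3), chrom = "c1",
                     pos = c(9251L, 9500L, 9900L),
                     ref_allele = "A", alt_allele = "G", stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("gA", "gB"), name = c("gA", "gB"),
                      chrom = "c1", strand = "+", tss = c(10000L, 50000L),
                      start = c(10000L, 50000L), end = c(10100L, 50100L),
                      source_feature = "gene", stringsAsFactors = FALSE)
  links <- data.frame(snp_id = paste0("r", 1:3), gene_id = "gA",
                      distance_to_tss = c(-749L, -500L, -100L),
                      stringsAsFactors = FALSE)
  cons <- data.frame(snp_id = paste0("r", 1:3), gene_strand = "+",
                     pwm_id = "P$A_01", seq_offset = 24L,
                     orientation = "forward", consequence = "loss",
                     ref_core_score = 0.9, ref_matrix_score = 0.9,
                     alt_core_score = NA_real_, alt_matrix_score = NA_real_,
                     ref_site_seq = "aaTAAAtaa", alt_site_seq = NA_character_,
                     stringsAsFactors = FALSE)
  db <- build_database(snps, genes, links, cons)
  on.exit(close_database(db))
  st <- summarize_database(db)
  expect_equal(st$rsnps_per_promoter, 1.5)
  # distance -749 falls in the leftmost bin [-750, -700)
  expect_equal(unname(st$tss_histogram["[-750,-700)"]), 1L)
})

test_that("an empty database summarizes to all zeros and narrowing is monotone", {
  empty <- build_database(
    toy_store_inputs()$snps[0, ], toy_store_inputs()$genes[0, ],
    toy_store_inputs()$links[0, ], toy_store_inputs()$consequences[0, ])
  on.exit(close_database(empty), add = TRUE)
  st <- summarize_database(empty)
  expect_equal(st$n_snps, 0L)
  expect_equal(st$n_rsnps, 0L)
  expect_equal(st$pct_rsnp, 0)
  expect_equal(st$rsnps_per_promoter, 0)
  expect_equal(sum(st$tss_histogram), 0L)
  inp <- toy_store_inputs()
  db <- build_database(inp$snps, inp$genes, inp$links, inp$consequences)
  on.exit(close_database(db), add = TRUE)
  wide <- summarize_database(db, 1000, 100)
  narrow <- summarize_database(db, 200, 50)
  expect_lte(narrow$n_snps, wide$n_snps)
  expect_lte(narrow$n_rsnps, wide$n_rsnps)
  expect_true(all(narrow$tss_histogram <= wide$tss_histogram |
                    narrow$tss_histogram == 0))
})

test_that("a database file can be reopened and queried", {
  inp <- toy_store_inputs()
  path <- tempfile(fileext = ".sqlite")
  db <- build_database(inp$snps, inp$genes, inp$links, inp$consequences,
                       path = path)
  close_database(db)
  db2 <- open_database(path)
  on.exit(close_database(db2))
  expect_equal(unname(db_counts(db2)), c(3L, 2L, 4L, 2L))
  expect_equal(query_database(db2, "snp_ids", "s1")$consequence, "loss")
})
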