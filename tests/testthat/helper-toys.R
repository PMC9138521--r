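# Small builders for toy input files and in-memory objects, created fresh
# inside each test's tempdir.

write_toy_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(seqs), function(nm) c(paste0(">", nm), seqs[[nm]]))),
             path)
  path
}

write_toy_gff3 <- function(df, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3",
               sprintf("%s\ttoy\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                       df$chrom, df$feature %||% rep("gene", nrow(df)),
                       df$start, df$end, df$strand, df$gene_id,
                       df$name %||% df$gene_id)),
             path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_toy_vcf <- function(records, path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               records),
             path)
  path
}

# A consistent tiny store input set: 3 SNPs, 2 genes, 4 links, 2 consequences
toy_store_inputs <- function() {
  snps <- data.frame(
    snp_id = c("s1", "s2", "s3"), chrom = "chr1",
    pos = c(1100L, 1900L, 2050L),
    ref_allele = c("A", "C", "G"), alt_allele = c("G", "T", "A"),
    stringsAsFactors = FALSE)
  genes <- data.frame(
    gene_id = c("gA", "gB"), name = c("geneA", "geneB"), chrom = "chr1",
    strand = c("+", "-"), tss = c(2000L, 1500L),
    start = c(2000L, 800L), end = c(2600L, 1500L), source_feature = "gene",
    stringsAsFactors = FALSE)
  links <- data.frame(
    snp_id = c("s1", "s1", "s2", "s3"),
    gene_id = c("gA", "gB", "gA", "gA"),
    distance_to_tss = c(-900L, 400L, -100L, 50L),
    stringsAsFactors = FALSE)
  attr(links, "upstream_bp") <- 7500
  attr(links, "downstream_bp") <- 2500
  consequences <- data.frame(
    snp_id = c("s1", "s2"), gene_strand = c("+", "+"),
    pwm_id = c("P$TOY_01", "P$TOY_02"), seq_offset = c(24L, 22L),
    orientation = "forward",
    consequence = c("loss", "score_change"),
    ref_core_score = c(0.95, 0.90), ref_matrix_score = c(0.93, 0.91),
    alt_core_score = c(NA, 0.88), alt_matrix_score = c(NA, 0.87),
    ref_site_seq = c("aaTATAAtt", "ccGGCGCtt"),
    alt_site_seq = c(NA, "ccGGCGGtt"),
    stringsAsFactors = FALSE)
  list(snps = snps, genes = genes, links = links, consequences = consequences)
}
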