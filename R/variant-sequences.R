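## 51-bp reference / alternate search sequences per (SNP, gene-strand)
## context. The SNP sits at position 26 (1-based) of both sequences; 25 bp
## of flank on each side. Catalog alleles are taken on the genome plus
## strand (VCF/GVF convention) and complemented for minus-strand contexts.

FLANK_BP <- 25L
SEQ_LEN <- 51L
CENTER_POS <- 26L

SEQ_DISCARD_REASONS <- c("too_short", "contains_N", "ref_mismatch")

#' Build the 51-bp allele sequence pair for one SNP in one strand context
#'
#' Extracts 25 bp of genomic flank on each side of the SNP. For a plus-strand
#' gene context the reference sequence is the genomic slice itself; for a
#' minus-strand context it is the reverse complement, with the SNP still at
#' position 26 and the alleles complemented. The alternate sequence is the
#' reference sequence with the center base substituted.
#'
#' Discard rules, checked in order (the first failing rule is recorded):
#' `too_short` (SNP closer than 25 bp to a chromosome edge, so the full
#' 51-bp window does not exist), `contains_N` (any N in the window),
#' `ref_mismatch` (genome base at the SNP position differs from the catalog
#' reference allele — such catalog/assembly disagreements do occur and the
#' affected SNPs are excluded rather than annotated unreliably).
#'
#' @param snp One-row data.frame or list with `snp_id`, `chrom`, `pos`,
#'   `ref_allele`, `alt_allele`.
#' @param gene_strand `"+"` or `"-"`: strand of the gene whose promoter
#'   provides the context.
#' @param genome `DNAStringSet` from [read_genome()].
#' @return A list of class `AlleleSequencePair` with `snp_id`, `gene_strand`,
#'   `ref_seq`, `alt_seq`, `center_pos` — or a list of class `SeqDiscard`
#'   with `snp_id`, `gene_strand`, `chrom`, `reason`.
#' @export
extract_pair <- function(snp, gene_strand, genome) {
  stopifnot(gene_strand %in% c("+", "-"))
  discard <- function(reason) {
    structure(list(snp_id = snp$snp_id, gene_strand = gene_strand,
                   chrom = snp$chrom, reason = reason),
              class = "SeqDiscard")
  }
  len <- chrom_lengths(genome)[[snp$chrom]]
  if (snp$pos - FLANK_BP < 1L || snp$pos + FLANK_BP > len) {
    return(discard("too_short"))
  }
  slice <- genome_slice(genome, snp$chrom, snp$pos - FLANK_BP, snp$pos + FLANK_BP)
  if (grepl("N", slice, fixed = TRUE)) return(discard("contains_N"))
  if (substr(slice, CENTER_POS, CENTER_POS) != snp$ref_allele) {
    return(discard("ref_mismatch"))
  }
  if (gene_strand == "+") {
    ref_seq <- slice
    alt <- snp$alt_allele
  } else {
    ref_seq <- revcomp(slice)
    alt <- comp_base(snp$alt_allele)
  }
  alt_seq <- ref_seq
  substr(alt_seq, CENTER_POS, CENTER_POS) <- alt
  structure(list(snp_id = snp$snp_id, gene_strand = gene_strand,
                 ref_seq = ref_seq, alt_seq = alt_seq,
                 center_pos = CENTER_POS),
            class = "AlleleSequencePair")
}

#' Build all allele sequence pairs needed by a set of SNP-promoter links
#'
#' One pair per distinct (SNP, gene strand) combination occurring in the
#' links: pairs are deduplicated across genes that share a strand, because
#' the scan result depends only on the sequence, which depends only on the
#' strand. Consequences are joined back to every gene through the links.
#'
#' @param snps SNP data.frame (see [read_snp_catalog()]).
#' @param links data.frame from [assign_snps()].
#' @param genes Gene data.frame (provides each gene's strand).
#' @param genome `DNAStringSet`.
#' @return List with `pairs` (data.frame: `snp_id`, `gene_strand`,
#'   `ref_seq`, `alt_seq`), `discards` (data.frame: `snp_id`, `gene_strand`,
#'   `chrom`, `reason`) and `filter_log` (named counts over the three
#'   discard reasons). `nrow(pairs) + nrow(discards)` equals the number of
#'   attempted (SNP, strand) contexts.
#' @export
extract_pairs <- function(snps, links, genes, genome) {
  strand_of <- setNames(genes$strand, genes$gene_id)
  ctx <- unique(data.frame(snp_id = links$snp_id,
                           gene_strand = unname(strand_of[links$gene_id]),
                           stringsAsFactors = FALSE))
  snp_idx <- match(ctx$snp_id, snps$snp_id)
  if (anyNA(snp_idx)) {
    stop_rsnpdb("links reference SNP ids absent from the catalog")
  }
  pair_rows <- list(); disc_rows <- list()
  for (i in seq_len(nrow(ctx))) {
    res <- extract_pair(snps[snp_idx[i], ], ctx$gene_strand[i], genome)
    if (inherits(res, "SeqDiscard")) {
      disc_rows[[length(disc_rows) + 1L]] <- as.data.frame(unclass(res))
    } else {
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        snp_id = res$snp_id, gene_strand = res$gene_strand,
        ref_seq = res$ref_seq, alt_seq = res$alt_seq,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(snp_id = character(0), gene_strand = character(0),
               ref_seq = character(0), alt_seq = character(0),
               stringsAsFactors = FALSE)
  discards <- if (length(disc_rows)) do.call(rbind, disc_rows) else
    data.frame(snp_id = character(0), gene_strand = character(0),
               chrom = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  log <- vapply(SEQ_DISCARD_REASONS,
                function(r) sum(discards$reason == r), integer(1))
  ord <- order(pairs$snp_id, pairs$gene_strand)
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, discards = discards, filter_log = log)
}

#' Export search sequences as FASTA
#'
#' Two records per pair, with ids `<snp_id>|<strand>|ref` and
#' `<snp_id>|<strand>|alt`, for external inspection.
#'
#' @param pairs data.frame from [extract_pairs()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
export_pairs_fasta <- function(pairs, path) {
  out <- character(0)
  for (i in seq_len(nrow(pairs))) {
    out <- c(out,
             sprintf(">%s|%s|ref", pairs$snp_id[i], pairs$gene_strand[i]),
             pairs$ref_seq[i],
             sprintf(">%s|%s|alt", pairs$snp_id[i], pairs$gene_strand[i]),
             pairs$alt_seq[i])
  }
  writeLines(out, path)
  invisible(path)
}
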