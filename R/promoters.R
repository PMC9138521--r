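## Promoter windows around the TSS and SNP-to-promoter assignment.
## All genomic coordinates are 1-based inclusive; windows are clipped to the
## chromosome, never negative. Distances to the TSS are signed in gene
## orientation: negative = upstream, 0 = at the TSS base, positive =
## downstream.

#' Build promoter windows around gene TSSs
#'
#' For a plus-strand gene the window spans `tss - upstream_bp` to
#' `tss + downstream_bp` on the genome; for a minus-strand gene it is
#' mirrored (`tss - downstream_bp` to `tss + upstream_bp`). Both bounds are
#' inclusive, so the unclipped window covers `upstream_bp + downstream_bp + 1`
#' bases including the TSS base itself. Windows are clipped at chromosome
#' edges.
#'
#' @param genes data.frame from [read_gene_annotations()].
#' @param upstream_bp,downstream_bp Window extent in bases relative to the
#'   TSS in gene orientation. Defaults 7500 / 2500, the extent at which the
#'   promoter scan is built.
#' @param chrom_lengths Named integer vector of chromosome lengths (see
#'   [chrom_lengths()]).
#' @return data.frame: gene columns plus `win_start`, `win_end`,
#'   `upstream_bp`, `downstream_bp`.
#' @export
build_windows <- function(genes, upstream_bp = 7500, downstream_bp = 2500,
                          chrom_lengths) {
  stopifnot(upstream_bp >= 0, downstream_bp >= 0)
  missing_chr <- setdiff(unique(genes$chrom), names(chrom_lengths))
  if (length(missing_chr)) {
    stop_rsnpdb("gene chromosome(s) absent from genome: ",
                paste(missing_chr, collapse = ", "))
  }
  len <- unname(chrom_lengths[genes$chrom])
  plus <- genes$strand == "+"
  win_start <- ifelse(plus, genes$tss - upstream_bp, genes$tss - downstream_bp)
  win_end <- ifelse(plus, genes$tss + downstream_bp, genes$tss + upstream_bp)
  out <- genes
  out$win_start <- pmax(1L, as.integer(win_start))
  out$win_end <- pmin(len, as.integer(win_end))
  out$upstream_bp <- upstream_bp
  out$downstream_bp <- downstream_bp
  out
}

#' Assign SNPs to promoter windows
#'
#' Every containment of a SNP position in a promoter window produces one
#' link; a SNP inside two overlapping promoters is linked to both genes and
#' annotated independently per gene. Window bounds are inclusive at both
#' ends. The signed distance to the TSS is `pos - tss` for plus-strand genes
#' and `tss - pos` for minus-strand genes.
#'
#' @param snps data.frame of SNP records (`snp_id`, `chrom`, `pos`, ...).
#' @param windows data.frame from [build_windows()].
#' @return data.frame of links: `snp_id`, `gene_id`, `distance_to_tss`,
#'   sorted by (chrom, pos, gene_id). The build window extents are attached
#'   as attributes `upstream_bp` / `downstream_bp` and checked by
#'   [filter_links_by_window()].
#' @export
assign_snps <- function(snps, windows) {
  if (nrow(snps) == 0 || nrow(windows) == 0) {
    links <- data.frame(snp_id = character(0), gene_id = character(0),
                        distance_to_tss = integer(0), stringsAsFactors = FALSE)
  } else {
    chroms <- unique(c(snps$chrom, windows$chrom))
    snp_gr <- GenomicRanges::GRanges(
      factor(snps$chrom, chroms), IRanges::IRanges(snps$pos, snps$pos))
    win_gr <- GenomicRanges::GRanges(
      factor(windows$chrom, chroms),
      IRanges::IRanges(windows$win_start, windows$win_end))
    hits <- GenomicRanges::findOverlaps(snp_gr, win_gr)
    si <- S4Vectors::queryHits(hits)
    wi <- S4Vectors::subjectHits(hits)
    d <- ifelse(windows$strand[wi] == "+",
                snps$pos[si] - windows$tss[wi],
                windows$tss[wi] - snps$pos[si])
    links <- data.frame(snp_id = snps$snp_id[si],
                        gene_id = windows$gene_id[wi],
                        distance_to_tss = as.integer(d),
                        stringsAsFactors = FALSE)
    ord <- order(snps$chrom[si], snps$pos[si], windows$gene_id[wi])
    links <- links[ord, , drop = FALSE]
    rownames(links) <- NULL
  }
  attr(links, "upstream_bp") <- windows$upstream_bp[1] %||% NA_integer_
  attr(links, "downstream_bp") <- windows$downstream_bp[1] %||% NA_integer_
  links
}

#' Re-filter SNP-promoter links to a narrower window
#'
#' Pure re-filter on the stored distances (no re-scan): keeps links with
#' `-upstream_bp <= distance_to_tss <= downstream_bp`, bounds inclusive. The
#' TSS base (distance 0) counts as the downstream side. Requesting a window
#' wider than the one the links were built with is an error, because the
#' result would be incomplete.
#'
#' @param links data.frame from [assign_snps()].
#' @param upstream_bp,downstream_bp Query window; defaults 1000 / 100, the
#'   default query extent.
#' @param built_upstream_bp,built_downstream_bp Extent the links were built
#'   with; taken from the attributes of `links` when present.
#' @return Filtered links (attributes preserved).
#' @export
filter_links_by_window <- function(links, upstream_bp = 1000, downstream_bp = 100,
                                   built_upstream_bp = attr(links, "upstream_bp"),
                                   built_downstream_bp = attr(links, "downstream_bp")) {
  if (!is.null(built_upstream_bp) && !is.na(built_upstream_bp) &&
      (upstream_bp > built_upstream_bp || downstream_bp > built_downstream_bp)) {
    stop_rsnpdb(sprintf(
      "requested window (-%d/+%d) exceeds the built window (-%d/+%d); results would be incomplete",
      upstream_bp, downstream_bp, built_upstream_bp, built_downstream_bp))
  }
  keep <- links$distance_to_tss >= -upstream_bp &
    links$distance_to_tss <= downstream_bp
  out <- links[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "upstream_bp") <- built_upstream_bp
  attr(out, "downstream_bp") <- built_downstream_bp
  out
}
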