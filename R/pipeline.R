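## End-to-end driver: files in, classified consequences and database out.

#' Run the full rSNP annotation pipeline
#'
#' Executes the five pipeline stages in order: (1) build promoter windows
#' and assign catalog SNPs to them, (2) extract the 51-bp reference search
#' sequences, (3) create the alternate-allele copies, (4) scan both alleles
#' of every sequence pair with the PWM library using MATCH-style core and
#' matrix similarity scoring, (5) classify each site's consequence and flag
#' rSNPs.
#'
#' @param genome `DNAStringSet` from [read_genome()].
#' @param genes Gene data.frame from [read_gene_annotations()].
#' @param snps SNP data.frame (the `snps` element of [read_snp_catalog()]).
#' @param pwms Named list of [Pwm] objects from [read_pwm_library()].
#' @param upstream_bp,downstream_bp Promoter build window (defaults
#'   7500 / 2500).
#' @param pseudocount PWM regularization pseudocount (default 0.8).
#' @param orientations Orientations to scan; both by default.
#' @param score_digits Score-comparison precision for the consequence
#'   classification (default 3 decimals).
#' @return List with `windows`, `links`, `pairs`, `seq_filter_log`,
#'   `seq_discards`, `consequences`, `flags`.
#' @export
run_pipeline <- function(genome, genes, snps, pwms,
                         upstream_bp = 7500, downstream_bp = 2500,
                         pseudocount = 0.8,
                         orientations = c("forward", "reverse"),
                         score_digits = 3) {
  windows <- build_windows(genes, upstream_bp, downstream_bp,
                           chrom_lengths(genome))
  links <- assign_snps(snps, windows)
  seqs <- extract_pairs(snps, links, genes, genome)
  spwms <- prepare_library(pwms, pseudocount = pseudocount)
  consequences <- annotate_consequences(seqs$pairs, spwms,
                                        orientations = orientations,
                                        score_digits = score_digits)
  flags <- flag_rsnps(consequences, snp_ids = snps$snp_id)
  list(windows = windows, links = links, pairs = seqs$pairs,
       seq_filter_log = seqs$filter_log, seq_discards = seqs$discards,
       consequences = consequences, flags = flags)
}

#' Run the pipeline from input files and build the database
#'
#' @param genome_path,gff3_path,snps_path,pwms_path Input files (FASTA,
#'   GFF3, VCF/GVF, TRANSFAC-dialect PWM flat file).
#' @param db_path Output SQLite path.
#' @param feature GFF3 feature type defining genes/TSS (default `"gene"`).
#' @param default_core_cutoff,default_matrix_cutoff Cutoffs for PWMs
#'   without their own.
#' @param keep_no_change Store `no_change` rows (default `FALSE`).
#' @inheritParams run_pipeline
#' @return The `RsnpDatabase` handle (invisible); the pipeline intermediates
#'   are attached as attribute `"run"`.
#' @export
build_from_files <- function(genome_path, gff3_path, snps_path, pwms_path,
                             db_path = ":memory:", feature = "gene",
                             upstream_bp = 7500, downstream_bp = 2500,
                             default_core_cutoff = 0.75,
                             default_matrix_cutoff = 0.85,
                             pseudocount = 0.8,
                             orientations = c("forward", "reverse"),
                             keep_no_change = FALSE) {
  genome <- read_genome(genome_path)
  genes <- read_gene_annotations(gff3_path, feature = feature)
  catalog <- read_snp_catalog(snps_path)
  pwms <- read_pwm_library(pwms_path,
                           default_core_cutoff = default_core_cutoff,
                           default_matrix_cutoff = default_matrix_cutoff)
  run <- run_pipeline(genome, genes, catalog$snps, pwms,
                      upstream_bp = upstream_bp,
                      downstream_bp = downstream_bp,
                      pseudocount = pseudocount,
                      orientations = orientations)
  db <- build_database(catalog$snps, genes, run$links, run$consequences,
                       path = db_path, keep_no_change = keep_no_change)
  attr(db, "run") <- run
  invisible(db)
}
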