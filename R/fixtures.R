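## Deterministic synthetic fixtures: a toy genome, gene annotation, SNP
## catalog and PWM library with *planted*, ground-truth binding-site
## effects, so every pipeline stage is testable without downloads. The
## background sequence is i.i.d. nucleotides at a configurable GC content;
## planted ref/alt constructions are verified at generation time by running
## the scanner itself, so the emitted truth table is guaranteed, never a
## silent wrong label.

PLANT_MOTIF_WIDTH <- 6L
PLANT_SNP_COL <- 3L      # PWM column placed on the SNP
PLANT_SEQ_OFFSET <- 24L  # resulting footprint start in the 51-bp sequence

#' Specify a synthetic fixture
#'
#' @param seed Integer seed; the whole fixture is a deterministic function
#'   of the spec including the seed.
#' @param n_chroms,chrom_length Number and length of chromosomes.
#' @param n_genes Genes, assigned round-robin to chromosomes with
#'   alternating strand and evenly spaced TSSs.
#' @param planted data.frame with columns `pwm_id`, `gene_id`,
#'   `distance_to_tss`, `allele_effect` (one of `gain`, `loss`,
#'   `score_change`, `none`); one SNP is planted per row at the stated
#'   distance from the gene's TSS, engineered to produce exactly the stated
#'   consequence (or none) for the named PWM at the configured cutoffs.
#' @param n_background_snps Additional unengineered SNPs placed at random
#'   positions inside promoter windows (their reference allele always
#'   matches the genome; their consequences are whatever the scan finds).
#' @param gc_content Background GC fraction in `[0, 1]`.
#' @param core_cutoff,matrix_cutoff,pseudocount Scan configuration the
#'   plants are engineered against (defaults 0.75 / 0.85 / 0.8).
#' @return List of class `FixtureSpec`.
#' @export
fixture_spec <- function(seed = 1L, n_chroms = 1L, chrom_length = 30000L,
                         n_genes = 2L, planted = NULL,
                         n_background_snps = 0L, gc_content = 0.4,
                         core_cutoff = 0.75, matrix_cutoff = 0.85,
                         pseudocount = 0.8) {
  if (is.null(planted)) {
    planted <- data.frame(pwm_id = "P$FIX1_01", gene_id = "g1",
                          distance_to_tss = -200L, allele_effect = "loss",
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(planted$allele_effect %in% c("gain", "loss", "score_change", "none")),
            gc_content >= 0, gc_content <= 1, n_genes >= 1, n_chroms >= 1)
  gene_ids <- paste0("g", seq_len(n_genes))
  bad <- setdiff(planted$gene_id, gene_ids)
  if (length(bad)) stop_rsnpdb("planted gene id(s) not in fixture: ",
                               paste(bad, collapse = ", "))
  if (any(planted$distance_to_tss < -7500 | planted$distance_to_tss > 2500)) {
    stop_rsnpdb("planted distance outside the built promoter window")
  }
  ## a PWM carrying a score_change plant needs a mixed SNP column, which is
  ## incompatible with the sharp column a gain/loss plant relies on
  eff_by_pwm <- split(planted$allele_effect, planted$pwm_id)
  for (id in names(eff_by_pwm)) {
    e <- unique(eff_by_pwm[[id]])
    if ("score_change" %in% e && any(c("gain", "loss") %in% e)) {
      stop_rsnpdb("PWM '", id, "': score_change and gain/loss plants cannot ",
                  "share a matrix (incompatible SNP-column shapes)")
    }
  }
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 n_genes = as.integer(n_genes), planted = planted,
                 n_background_snps = as.integer(n_background_snps),
                 gc_content = gc_content, core_cutoff = core_cutoff,
                 matrix_cutoff = matrix_cutoff, pseudocount = pseudocount),
            class = "FixtureSpec")
}

## Internal: counts for one planted PWM. Sharp columns are 97/1/1/1 on the
## consensus; a score_change SNP column is 60/36/2/2 over (major, minor,
## rest), which keeps both alleles above cutoff with distinct scores.
plant_pwm_counts <- function(consensus, score_change, minor_base = NULL) {
  w <- length(consensus)
  counts <- matrix(1, w, 4, dimnames = list(NULL, DNA_BASES))
  for (i in seq_len(w)) counts[i, consensus[i]] <- 97
  if (score_change) {
    i <- PLANT_SNP_COL
    counts[i, ] <- 2
    counts[i, consensus[i]] <- 60
    counts[i, minor_base] <- 36
  }
  counts
}

#' Generate fixture files from a spec
#'
#' Writes `genome.fa`, `genes.gff3`, `snps.vcf`, `pwms.txt` and `truth.tsv`
#' into `outdir`. Deterministic: the same spec yields byte-identical files.
#' Every planted effect is verified at generation time by extracting the
#' 51-bp pair and scanning it with the generated library; if a plant cannot
#' be realized (e.g. chance background matches keep interfering after
#' bounded resampling) generation fails rather than emit a wrong truth
#' table.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory (created if needed).
#' @return Invisible list with the five file paths plus the in-memory
#'   `truth_table`, `gene_table`, `snp_table` and `pwm_list` objects.
#' @export
generate_fixtures <- function(spec, outdir) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  chroms <- paste0("chr", seq_len(spec$n_chroms))
  p_base <- c((1 - spec$gc_content) / 2, spec$gc_content / 2,
              spec$gc_content / 2, (1 - spec$gc_content) / 2)

  ## genes: round-robin chromosome, alternating strand, evenly spaced TSS
  n <- spec$n_genes
  gene_chrom <- chroms[((seq_len(n) - 1L) %% spec$n_chroms) + 1L]
  per_chrom_rank <- stats::ave(seq_len(n), gene_chrom, FUN = seq_along)
  per_chrom_n <- stats::ave(seq_len(n), gene_chrom, FUN = length)
  tss <- as.integer(round(per_chrom_rank * spec$chrom_length / (per_chrom_n + 1)))
  strand <- rep(c("+", "-"), length.out = n)
  if (any(tss < 26L | tss > spec$chrom_length - 26L)) {
    stop_rsnpdb("chromosome too short for the requested gene count")
  }
  genes <- data.frame(gene_id = paste0("g", seq_len(n)),
                      name = paste0("gene", seq_len(n)),
                      chrom = gene_chrom, strand = strand, tss = tss,
                      stringsAsFactors = FALSE)
  genes$start <- ifelse(strand == "+", tss, pmax(1L, tss - 999L))
  genes$end <- ifelse(strand == "+", pmin(spec$chrom_length, tss + 999L), tss)

  ## background genome as per-chromosome character vectors
  genome_chars <- lapply(chroms, function(ch) {
    sample(DNA_BASES, spec$chrom_length, replace = TRUE, prob = p_base)
  })
  names(genome_chars) <- chroms

  ## PWM library: one matrix per distinct planted pwm_id. Consensi are
  ## rejection-sampled so that every pair of consensus words (including
  ## each word against its own reverse complement) differs in at least two
  ## positions: a single-base allele substitution then can never turn one
  ## planted footprint into a full-score site of another matrix, keeping
  ## every planted classification realizable.
  planted <- spec$planted
  if (nrow(planted) == 0) stop_rsnpdb("fixture needs at least one planted row")
  pwm_ids <- unique(planted$pwm_id)
  hamming <- function(a, b) sum(a != b)
  rc_chars <- function(x) rev(comp_base(x))
  pwms <- list()
  pwm_meta <- list()  # consensus + minor base per pwm
  chosen <- list()
  for (id in pwm_ids) {
    ok <- FALSE
    for (try in 1:200) {
      consensus <- sample(DNA_BASES, PLANT_MOTIF_WIDTH, replace = TRUE)
      ok <- hamming(consensus, rc_chars(consensus)) >= 2 &&
        all(vapply(chosen, function(pr) {
          hamming(consensus, pr) >= 2 && hamming(consensus, rc_chars(pr)) >= 2
        }, logical(1)))
      if (ok) break
    }
    if (!ok) stop_rsnpdb("could not sample a usable consensus for ", id)
    chosen[[id]] <- consensus
    sc <- "score_change" %in% planted$allele_effect[planted$pwm_id == id]
    minor <- sample(setdiff(DNA_BASES, consensus[PLANT_SNP_COL]), 1)
    pwms[[id]] <- Pwm(id, plant_pwm_counts(consensus, sc, minor),
                      core_cutoff = spec$core_cutoff,
                      matrix_cutoff = spec$matrix_cutoff)
    pwm_meta[[id]] <- list(consensus = consensus, minor = minor,
                           score_change = sc)
  }

  ## planted SNP placement (genomic); enforce non-interacting 51-bp windows
  gene_ix <- match(planted$gene_id, genes$gene_id)
  plant_pos <- ifelse(genes$strand[gene_ix] == "+",
                      genes$tss[gene_ix] + planted$distance_to_tss,
                      genes$tss[gene_ix] - planted$distance_to_tss)
  plant_chrom <- genes$chrom[gene_ix]
  if (any(plant_pos < 26L | plant_pos > spec$chrom_length - 25L)) {
    stop_rsnpdb("planted SNP too close to a chromosome edge")
  }
  for (ch in unique(plant_chrom)) {
    p <- sort(plant_pos[plant_chrom == ch])
    if (length(p) > 1 && any(diff(p) < 60L)) {
      stop_rsnpdb("planted SNPs closer than 60 bp on ", ch,
                  ": their 51-bp windows would interact")
    }
  }

  ## write the motifs / pick alleles, in gene-strand space
  minb <- function(id) {
    ## lowest-count base at the SNP column (deterministic: alphabetical)
    cnt <- pwms[[id]]$counts[PLANT_SNP_COL, ]
    DNA_BASES[which.min(cnt)]
  }
  write_on_strand <- function(ch, strand, center, motif) {
    w <- length(motif)
    if (strand == "+") {
      at <- (center - PLANT_SNP_COL + 1L):(center - PLANT_SNP_COL + w)
      genome_chars[[ch]][at] <<- motif
    } else {
      at <- (center - (w - PLANT_SNP_COL)):(center + PLANT_SNP_COL - 1L)
      genome_chars[[ch]][at] <<- rev(comp_base(motif))
    }
  }
  snp_rows <- list()
  for (k in seq_len(nrow(planted))) {
    id <- planted$pwm_id[k]
    eff <- planted$allele_effect[k]
    meta <- pwm_meta[[id]]
    g_strand <- genes$strand[gene_ix[k]]
    ch <- plant_chrom[k]
    pos <- plant_pos[k]
    cons_b <- meta$consensus[PLANT_SNP_COL]
    alleles <- switch(eff,  # (ref, alt) in gene-strand space
      loss = c(cons_b, minb(id)),
      gain = c(minb(id), cons_b),
      score_change = c(cons_b, meta$minor),
      none = {
        ref_gs <- if (g_strand == "+") genome_chars[[ch]][pos]
                  else comp_base(genome_chars[[ch]][pos])
        c(ref_gs, sample(setdiff(DNA_BASES, ref_gs), 1))
      })
    if (eff != "none") {
      motif <- meta$consensus
      motif[PLANT_SNP_COL] <- alleles[1]
      write_on_strand(ch, g_strand, pos, motif)
    }
    ## catalog alleles are on the genome plus strand
    to_plus <- function(b) if (g_strand == "+") b else comp_base(b)
    snp_rows[[k]] <- data.frame(
      snp_id = sprintf("snp%03d", k), chrom = ch, pos = pos,
      ref_allele = to_plus(alleles[1]), alt_allele = to_plus(alleles[2]),
      gene_id = planted$gene_id[k], gene_strand = g_strand,
      distance_to_tss = planted$distance_to_tss[k],
      pwm_id = id, expected_consequence = eff,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, snp_rows)

  ## generation-time verification of every plant, with bounded local
  ## background resampling when chance matches interfere
  spwms <- prepare_library(pwms, pseudocount = spec$pseudocount)
  widths <- setNames(vapply(spwms, function(s) s$width, integer(1)),
                     vapply(spwms, function(s) s$pwm$pwm_id, character(1)))
  for (k in seq_len(nrow(truth))) {
    tr <- truth[k, ]
    footprint <- if (tr$expected_consequence == "none") integer(0) else {
      if (tr$gene_strand == "+") {
        (tr$pos - PLANT_SNP_COL + 1L):(tr$pos - PLANT_SNP_COL + PLANT_MOTIF_WIDTH)
      } else {
        (tr$pos - (PLANT_MOTIF_WIDTH - PLANT_SNP_COL)):(tr$pos + PLANT_SNP_COL - 1L)
      }
    }
    resample_at <- setdiff((tr$pos - 25L):(tr$pos + 25L), c(footprint, tr$pos))
    ok <- FALSE
    for (try in 1:50) {
      genome_dss <- Biostrings::DNAStringSet(
        setNames(vapply(genome_chars, paste, character(1), collapse = ""),
                 names(genome_chars)))
      pair <- extract_pair(tr, tr$gene_strand, genome_dss)
      if (!inherits(pair, "SeqDiscard")) {
        rec <- classify_matches(
          scan_library(spwms, pair$ref_seq),
          scan_library(spwms, pair$alt_seq))
        rec <- restrict_to_snp_overlap(rec, widths)
        eff_rec <- rec[rec$consequence != "no_change", , drop = FALSE]
        ok <- if (tr$expected_consequence == "none") nrow(eff_rec) == 0 else {
          nrow(eff_rec) == 1 &&
            eff_rec$consequence == tr$expected_consequence &&
            eff_rec$pwm_id == tr$pwm_id &&
            eff_rec$seq_offset == PLANT_SEQ_OFFSET &&
            eff_rec$orientation == "forward"
        }
      }
      if (ok) break
      genome_chars[[tr$chrom]][resample_at] <-
        sample(DNA_BASES, length(resample_at), replace = TRUE, prob = p_base)
    }
    if (!ok) {
      stop_rsnpdb("unrealizable plant for ", tr$snp_id, " (", tr$pwm_id, ", ",
                  tr$expected_consequence, "): verification failed")
    }
  }

  ## background SNPs inside promoter windows, clear of planted windows
  bg_rows <- list()
  if (spec$n_background_snps > 0) {
    win <- build_windows(genes, 7500, 2500,
                         setNames(rep(spec$chrom_length, spec$n_chroms), chroms))
    for (b in seq_len(spec$n_background_snps)) {
      for (try in 1:100) {
        gi <- sample(nrow(win), 1)
        pos <- sample(max(26L, win$win_start[gi]):
                        min(spec$chrom_length - 25L, win$win_end[gi]), 1)
        ch <- win$chrom[gi]
        clear <- all(abs(pos - plant_pos[plant_chrom == ch]) > 55L) &&
          !any(vapply(bg_rows, function(r) r$chrom == ch && r$pos == pos,
                      logical(1)))
        if (clear) break
      }
      ref <- genome_chars[[ch]][pos]
      bg_rows[[b]] <- data.frame(
        snp_id = sprintf("bg%03d", b), chrom = ch, pos = pos,
        ref_allele = ref, alt_allele = sample(setdiff(DNA_BASES, ref), 1),
        stringsAsFactors = FALSE)
    }
  }
  snps <- rbind(truth[, c("snp_id", "chrom", "pos", "ref_allele", "alt_allele")],
                if (length(bg_rows)) do.call(rbind, bg_rows))
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  rownames(snps) <- NULL

  ## ---- write files ----
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    gff3 = file.path(outdir, "genes.gff3"),
    vcf = file.path(outdir, "snps.vcf"),
    pwms = file.path(outdir, "pwms.txt"),
    truth = file.path(outdir, "truth.tsv"))
  fa <- character(0)
  for (ch in chroms) {
    s <- paste(genome_chars[[ch]], collapse = "")
    fa <- c(fa, paste0(">", ch),
            substring(s, seq(1, nchar(s), 70), pmin(nchar(s), seq(70, nchar(s) + 69, 70))))
  }
  writeLines(fa, paths$genome)
  gff <- c("##gff-version 3",
           sprintf("%s\trsnpdb\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                   genes$chrom, genes$start, genes$end, genes$strand,
                   genes$gene_id, genes$name))
  writeLines(gff, paths$gff3)
  vcf <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", chroms, spec$chrom_length),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.",
                   snps$chrom, snps$pos, snps$snp_id, snps$ref_allele,
                   snps$alt_allele))
  writeLines(vcf, paths$vcf)
  write_pwm_library(pwms, paths$pwms)
  write_tsv_det(truth, paths$truth)
  invisible(c(paths, list(truth_table = truth, gene_table = genes,
                          snp_table = snps, pwm_list = pwms)))
}

#' Generate edge-case fixtures exercising the three sequence discard rules
#'
#' Builds a two-contig genome with one gene per contig and three SNPs that
#' trigger exactly `too_short` (SNP 10 bp from a contig end), `contains_N`
#' (an N inside the 51-bp window) and `ref_mismatch` (catalog reference
#' allele absent from the genome), plus one clean SNP that passes.
#'
#' @param outdir Output directory.
#' @return Invisible list of paths plus `expected_log`, the discard counts
#'   the sequence-extraction stage must report.
#' @export
generate_edge_fixtures <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(424242L)
  e1 <- sample(DNA_BASES, 60, replace = TRUE)
  e1[40] <- "N"
  e2 <- sample(DNA_BASES, 160, replace = TRUE)
  writeLines(c(">e1", paste(e1, collapse = ""),
               ">e2", paste(e2, collapse = "")),
             file.path(outdir, "genome.fa"))
  writeLines(c("##gff-version 3",
               "e1\trsnpdb\tgene\t30\t60\t.\t+\t.\tID=ge1;Name=ge1",
               "e2\trsnpdb\tgene\t60\t160\t.\t+\t.\tID=ge2;Name=ge2"),
             file.path(outdir, "genes.gff3"))
  mism <- setdiff(DNA_BASES, e2[60])[1]
  clean_ref <- e2[110]
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=e1,length=60>",
               "##contig=<ID=e2,length=160>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               sprintf("e1\t10\ts_short\t%s\t%s\t.\tPASS\t.",
                       e1[10], setdiff(DNA_BASES, e1[10])[1]),
               sprintf("e1\t30\ts_n\t%s\t%s\t.\tPASS\t.",
                       e1[30], setdiff(DNA_BASES, e1[30])[1]),
               sprintf("e2\t60\ts_mis\t%s\t%s\t.\tPASS\t.",
                       mism, setdiff(DNA_BASES, mism)[1]),
               sprintf("e2\t110\ts_ok\t%s\t%s\t.\tPASS\t.",
                       clean_ref, setdiff(DNA_BASES, clean_ref)[1])),
             file.path(outdir, "snps.vcf"))
  invisible(list(genome = file.path(outdir, "genome.fa"),
                 gff3 = file.path(outdir, "genes.gff3"),
                 vcf = file.path(outdir, "snps.vcf"),
                 expected_log = c(too_short = 1L, contains_N = 1L,
                                  ref_mismatch = 1L)))
}
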