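## Readers and writers for every external format the pipeline touches:
## FASTA genome, GFF3 gene annotation, VCF/GVF SNP catalog, TRANSFAC-dialect
## PWM flat file. All records are normalized into plain data.frames (and a
## DNAStringSet for the genome) at this boundary; downstream modules never
## see file formats.

#' Read a reference genome from FASTA
#'
#' @param path Path to a FASTA file. Sequence names are truncated at the
#'   first whitespace, as is conventional for genome FASTA headers.
#' @return A [Biostrings::DNAStringSet] with one element per chromosome,
#'   uppercased. Use [genome_slice()] for clipped random access.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop_rsnpdb("genome FASTA not found: ", path)
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  dup <- unique(names(genome)[duplicated(names(genome))])
  if (length(dup)) {
    stop_rsnpdb("duplicate chromosome names in FASTA: ",
                paste(dup, collapse = ", "))
  }
  genome
}

#' Extract a clipped slice of a chromosome
#'
#' Coordinates are 1-based inclusive. Requests extending beyond either end of
#' the chromosome are truncated to the available sequence (never an error),
#' so the returned string may be shorter than `end - start + 1`.
#'
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive coordinates.
#' @return Uppercase character string (possibly empty).
#' @export
genome_slice <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    stop_rsnpdb("chromosome not in genome: ", chrom)
  }
  len <- Biostrings::width(genome[chrom])
  start <- max(1L, as.integer(start))
  end <- min(len, as.integer(end))
  if (start > end) return("")
  toupper(as.character(Biostrings::subseq(genome[[chrom]], start, end)))
}

#' Chromosome lengths of a genome
#'
#' @param genome A `DNAStringSet` from [read_genome()].
#' @return Named integer vector of sequence lengths.
#' @export
chrom_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

#' Read gene annotations from GFF3 and derive one TSS per gene
#'
#' One record per feature of the selected type is returned; the transcription
#' start site is the feature start for plus-strand genes and the feature end
#' for minus-strand genes (GFF3 coordinates are 1-based inclusive). Features
#' with unknown strand (`.` or `?`) are skipped with a warning, since no
#' promoter orientation can be defined for them.
#'
#' @param path Path to a GFF3 file.
#' @param feature Feature type (column 3) that defines a gene; default
#'   `"gene"`. One TSS per gene; per-transcript promoters are out of scope.
#' @return data.frame with columns `gene_id`, `name`, `chrom`, `strand`,
#'   `tss`, `start`, `end`, `source_feature`.
#' @export
read_gene_annotations <- function(path, feature = "gene") {
  if (!file.exists(path)) stop_rsnpdb("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature]
  if (length(gr) == 0) {
    stop_rsnpdb("no '", feature, "' features in ", path)
  }
  strand <- as.character(BiocGenerics::strand(gr))
  unknown <- !strand %in% c("+", "-")
  if (any(unknown)) {
    warning(sum(unknown), " '", feature,
            "' feature(s) with unknown strand skipped", call. = FALSE)
    gr <- gr[!unknown]
    strand <- strand[!unknown]
  }
  ids <- as.character(S4Vectors::mcols(gr)$ID %||% rep(NA_character_, length(gr)))
  nm <- S4Vectors::mcols(gr)$Name %||% rep(NA_character_, length(gr))
  nm <- as.character(nm)
  ids <- ifelse(is.na(ids) | ids == "", nm, ids)
  if (anyNA(ids) || any(ids == "")) {
    stop_rsnpdb("gene feature without ID or Name attribute in ", path)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop_rsnpdb("duplicate gene id(s) in annotation: ",
                paste(dup, collapse = ", "))
  }
  st <- BiocGenerics::start(gr)
  en <- BiocGenerics::end(gr)
  data.frame(
    gene_id = ids,
    name = nm,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    strand = strand,
    tss = ifelse(strand == "+", st, en),
    start = st,
    end = en,
    source_feature = feature,
    stringsAsFactors = FALSE
  )
}

## ---- SNP catalog ----------------------------------------------------------

new_filter_log <- function() {
  c(multiallelic = 0L, indel = 0L, non_acgt = 0L, unparseable = 0L)
}

## Classify one raw (ref, alts) allele pair; alts is a character vector of
## alternate alleles already excluding the reference. Returns a reason string
## or "" for a clean biallelic SNV. Reason precedence: multiallelic before
## indel before non_acgt, so a record is counted once.
snv_filter_reason <- function(ref, alts) {
  if (length(alts) != 1) return("multiallelic")
  alt <- alts[[1]]
  if (is.na(ref) || is.na(alt) || alt == "." || alt == "" || ref == "") {
    return("non_acgt")
  }
  if (nchar(ref) != 1 || nchar(alt) != 1 || ref == "-" || alt == "-") {
    return("indel")
  }
  if (!ref %in% DNA_BASES || !alt %in% DNA_BASES) return("non_acgt")
  if (ref == alt) return("non_acgt")
  ""
}

#' Read and filter a SNP catalog (VCF or GVF)
#'
#' Only biallelic single-nucleotide variants with A/C/G/T alleles are
#' retained; insertions, deletions, multiallelic records and records with
#' degenerate alleles are removed and counted by reason, never silently
#' dropped. Records without an identifier are assigned the synthetic id
#' `chrom-pos-ref-alt` (e.g. `A01-1093-A-G`).
#'
#' For GVF input the `Variant_seq` attribute may list the reference allele
#' among the variant alleles; it is removed before deciding whether the
#' record is biallelic, so `Reference_seq=A; Variant_seq=G,A` is retained as
#' the SNV A/G.
#'
#' @param path Path to a VCF or GVF file.
#' @param format `"auto"` (sniffed from extension, then content), `"vcf"` or
#'   `"gvf"`.
#' @return A list with `snps` (data.frame: `snp_id`, `chrom`, `pos`,
#'   `ref_allele`, `alt_allele`) and `filter_log` (named integer vector with
#'   counts for `multiallelic`, `indel`, `non_acgt`, `unparseable`).
#'   `nrow(snps) + sum(filter_log)` equals the number of input records.
#' @export
read_snp_catalog <- function(path, format = c("auto", "vcf", "gvf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_rsnpdb("SNP catalog not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "gvf") "gvf"
      else if (ext == "vcf") "vcf"
      else {
        head_lines <- readLines(path, n = 50L)
        if (any(grepl("##gvf-version|Variant_seq", head_lines))) "gvf" else "vcf"
      }
  }
  if (format == "vcf") read_snp_catalog_vcf(path) else read_snp_catalog_gvf(path)
}

read_snp_catalog_vcf <- function(path) {
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  log <- new_filter_log()
  if (nrow(fix) == 0) {
    return(list(snps = empty_snp_frame(), filter_log = log))
  }
  ref <- toupper(fix[, "REF"])
  alt_raw <- fix[, "ALT"]
  keep <- logical(nrow(fix))
  reasons <- character(nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- if (is.na(alt_raw[i])) "." else toupper(strsplit(alt_raw[i], ",", fixed = TRUE)[[1]])
    reasons[i] <- snv_filter_reason(ref[i], alts)
    keep[i] <- reasons[i] == ""
  }
  for (r in names(log)) log[r] <- sum(reasons == r)
  pos <- suppressWarnings(as.integer(fix[keep, "POS"]))
  bad <- is.na(pos)
  if (any(bad)) {
    log["unparseable"] <- log["unparseable"] + sum(bad)
  }
  snps <- data.frame(
    snp_id = fix[keep, "ID"][!bad],
    chrom = fix[keep, "CHROM"][!bad],
    pos = pos[!bad],
    ref_allele = ref[keep][!bad],
    alt_allele = toupper(alt_raw[keep][!bad]),
    stringsAsFactors = FALSE
  )
  finalize_snp_catalog(snps, log)
}

read_snp_catalog_gvf <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  log <- new_filter_log()
  n <- length(gr)
  if (n == 0) return(list(snps = empty_snp_frame(), filter_log = log))
  mc <- S4Vectors::mcols(gr)
  get_attr <- function(field) {
    v <- mc[[field]]
    if (is.null(v)) return(replicate(n, character(0), simplify = FALSE))
    if (is(v, "List") || is.list(v)) as.list(v) else as.list(as.character(v))
  }
  ref_l <- get_attr("Reference_seq")
  var_l <- get_attr("Variant_seq")
  ids <- as.character(mc$ID %||% rep(NA_character_, n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ref <- toupper(unlist(ref_l[[i]], use.names = FALSE))
    alts <- toupper(unlist(var_l[[i]], use.names = FALSE))
    ## GVF attributes may pack alleles as "G,A" when not comma-split upstream
    alts <- unlist(strsplit(alts, ",", fixed = TRUE), use.names = FALSE)
    if (length(ref) != 1 || length(alts) == 0) {
      log["unparseable"] <- log["unparseable"] + 1L
      next
    }
    alts <- setdiff(alts, ref)  # Variant_seq may repeat the reference allele
    if (length(alts) == 0) {
      log["unparseable"] <- log["unparseable"] + 1L
      next
    }
    reason <- snv_filter_reason(ref, alts)
    if (reason != "") {
      log[reason] <- log[reason] + 1L
      next
    }
    rows[[i]] <- data.frame(
      snp_id = ids[i],
      chrom = as.character(GenomeInfoDb::seqnames(gr))[i],
      pos = BiocGenerics::start(gr)[i],
      ref_allele = ref,
      alt_allele = alts[[1]],
      stringsAsFactors = FALSE
    )
  }
  snps <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(snps)) snps <- empty_snp_frame()
  finalize_snp_catalog(snps, log)
}

empty_snp_frame <- function() {
  data.frame(snp_id = character(0), chrom = character(0), pos = integer(0),
             ref_allele = character(0), alt_allele = character(0),
             stringsAsFactors = FALSE)
}

finalize_snp_catalog <- function(snps, log) {
  missing_id <- is.na(snps$snp_id) | snps$snp_id %in% c("", ".")
  snps$snp_id[missing_id] <- synthesize_snp_ids(snps[missing_id, , drop = FALSE])
  snps <- snps[order(snps$chrom, snps$pos, snps$snp_id), , drop = FALSE]
  rownames(snps) <- NULL
  list(snps = snps, filter_log = log)
}

#' Synthesize SNP identifiers as chrom-pos-ref-alt
#'
#' Catalogs without stable identifiers get ids of the form
#' `chrom-pos-ref-alt`, e.g. `A01-1093-A-G`.
#'
#' @param snps data.frame with `chrom`, `pos`, `ref_allele`, `alt_allele`.
#' @return Character vector of ids.
#' @export
synthesize_snp_ids <- function(snps) {
  if (nrow(snps) == 0) return(character(0))
  paste(snps$chrom, snps$pos, snps$ref_allele, snps$alt_allele, sep = "-")
}

## ---- PWM library ----------------------------------------------------------

#' Construct a position weight matrix object
#'
#' @param pwm_id Matrix identifier, conventionally TRANSFAC-style
#'   `P$NAME_version` for plant factors.
#' @param counts Numeric matrix, width x 4, nonnegative, columns A, C, G, T
#'   in that order (column names optional).
#' @param core_cutoff,matrix_cutoff Score cutoffs in `[0, 1]` used by the
#'   scanner; sites must reach both.
#' @param core_start Optional annotated 1-based start of the 5-position core.
#'   When `NULL` (default) the core is computed as the maximum-information
#'   5-window at scan time.
#' @return An object of class `Pwm`.
#' @export
Pwm <- function(pwm_id, counts, core_cutoff = 0.75, matrix_cutoff = 0.85,
                core_start = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4) {
    stop_rsnpdb("PWM '", pwm_id, "': counts must have 4 columns (A,C,G,T)")
  }
  if (nrow(counts) < 5) {
    stop_rsnpdb("PWM '", pwm_id, "' rejected: width ", nrow(counts),
                " < 5, no 5-position core definable")
  }
  if (any(counts < 0) || anyNA(counts)) {
    stop_rsnpdb("PWM '", pwm_id, "' rejected: negative or missing count")
  }
  for (cut in c(core_cutoff, matrix_cutoff)) {
    if (!is.numeric(cut) || cut < 0 || cut > 1) {
      stop_rsnpdb("PWM '", pwm_id, "': cutoffs must lie in [0, 1]")
    }
  }
  if (!is.null(core_start)) {
    core_start <- as.integer(core_start)
    if (core_start < 1 || core_start > nrow(counts) - 4L) {
      stop_rsnpdb("PWM '", pwm_id, "': annotated core start out of range")
    }
  }
  dimnames(counts) <- list(NULL, DNA_BASES)
  structure(
    list(pwm_id = pwm_id, width = nrow(counts), counts = counts,
         core_cutoff = core_cutoff, matrix_cutoff = matrix_cutoff,
         core_start = core_start),
    class = "Pwm"
  )
}

#' @export
print.Pwm <- function(x, ...) {
  cat("Pwm", x$pwm_id, "width", x$width,
      sprintf("cutoffs core=%.3f matrix=%.3f\n", x$core_cutoff, x$matrix_cutoff))
  invisible(x)
}

#' Read a PWM library from a TRANSFAC-dialect flat file
#'
#' The expected dialect is blocks separated by `//`, each with an `ID` line,
#' a `P0` header naming the base order, numbered count rows
#' (`01  12  0  3  5  <consensus>`; a trailing consensus letter is ignored),
#' and an optional `CO <core_cutoff> <matrix_cutoff>` line. Blocks without a
#' `CO` line receive the default cutoffs. Matrices of width below 5 or with
#' negative counts are rejected with the matrix id named.
#'
#' @param path Path to the flat file.
#' @param default_core_cutoff,default_matrix_cutoff Cutoffs attached to
#'   matrices that do not carry their own.
#' @return Named list of [Pwm] objects, keyed by `pwm_id`.
#' @export
read_pwm_library <- function(path, default_core_cutoff = 0.75,
                             default_matrix_cutoff = 0.85) {
  if (!file.exists(path)) stop_rsnpdb("PWM library not found: ", path)
  lines <- readLines(path)
  pwms <- list()
  id <- NULL; base_order <- DNA_BASES; rows <- list(); cutoffs <- NULL
  flush_block <- function() {
    if (is.null(id)) return()
    if (length(rows) == 0) {
      stop_rsnpdb("PWM '", id, "': block has no count rows")
    }
    counts <- do.call(rbind, rows)
    ## reorder columns into A,C,G,T regardless of the P0 header order
    counts <- counts[, match(DNA_BASES, base_order), drop = FALSE]
    cc <- if (is.null(cutoffs)) default_core_cutoff else cutoffs[1]
    mc <- if (is.null(cutoffs)) default_matrix_cutoff else cutoffs[2]
    if (!is.null(pwms[[id]])) stop_rsnpdb("duplicate PWM id in library: ", id)
    pwms[[id]] <<- Pwm(id, counts, core_cutoff = cc, matrix_cutoff = mc)
    id <<- NULL; base_order <<- DNA_BASES; rows <<- list(); cutoffs <<- NULL
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, "XX") || startsWith(ln, "CC") ||
        startsWith(ln, "BF") || startsWith(ln, "NA")) next
    if (startsWith(ln, "//")) { flush_block(); next }
    tok <- strsplit(ln, "\\s+")[[1]]
    tag <- tok[1]
    if (tag == "ID") {
      flush_block()
      if (length(tok) < 2) stop_rsnpdb("ID line without identifier")
      id <- tok[2]
    } else if (tag == "P0" || tag == "PO") {
      base_order <- toupper(tok[2:5])
      if (!setequal(base_order, DNA_BASES)) {
        stop_rsnpdb("PWM '", id %||% "?", "': P0 header must name A, C, G, T")
      }
    } else if (tag == "CO") {
      cutoffs <- as.numeric(tok[2:3])
      if (anyNA(cutoffs)) stop_rsnpdb("PWM '", id %||% "?", "': bad CO line")
    } else if (grepl("^[0-9]+$", tag)) {
      if (is.null(id)) stop_rsnpdb("count row before any ID line")
      vals <- suppressWarnings(as.numeric(tok[2:5]))
      if (anyNA(vals)) stop_rsnpdb("PWM '", id, "': unparseable count row: ", ln)
      rows[[length(rows) + 1L]] <- vals
    }
    ## other tags are ignored (TRANSFAC carries many annotation fields)
  }
  flush_block()
  if (length(pwms) == 0) stop_rsnpdb("no PWM blocks found in ", path)
  pwms
}

#' Write a PWM library in the TRANSFAC dialect read by [read_pwm_library()]
#'
#' Writing then re-reading reproduces counts and cutoffs exactly (counts are
#' written with full precision).
#'
#' @param pwms Named list of [Pwm] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm_library <- function(pwms, path) {
  out <- character(0)
  for (pwm in pwms) {
    out <- c(out, paste("ID", pwm$pwm_id),
             paste("P0", paste(DNA_BASES, collapse = "  ")))
    for (i in seq_len(pwm$width)) {
      out <- c(out, paste(sprintf("%02d", i),
                          paste(format(pwm$counts[i, ], trim = TRUE, digits = 15),
                                collapse = "  ")))
    }
    out <- c(out, sprintf("CO %.6g %.6g", pwm$core_cutoff, pwm$matrix_cutoff),
             "//")
  }
  writeLines(out, path)
  invisible(path)
}
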