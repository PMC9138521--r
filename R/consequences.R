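## Allele comparison: pair the reference-allele and alternate-allele match
## sets of one search-sequence pair and classify each binding site as a
## gain, loss, score-change or no-change; flag rSNPs.

CONSEQUENCE_LEVELS <- c("gain", "loss", "score_change", "no_change")

#' Classify binding-site consequences between two allele match sets
#'
#' Sites are paired across alleles by positional identity
#' `(pwm_id, seq_offset, orientation)` — for a single-base substitution this
#' is the only pairing under which gain and loss are well defined. A key
#' present only in the alternate-allele set is a `gain`; only in the
#' reference set, a `loss`; present in both, a `score_change` when the
#' matrix similarity scores differ after rounding to `score_digits` decimals
#' (binding-affinity difference operationalized on the matrix score at its
#' reported precision), else `no_change`.
#'
#' @param ref_matches,alt_matches Match data.frames from [scan_sequence()] /
#'   [scan_library()] over the reference and alternate sequence of one
#'   [extract_pair()] result.
#' @param score_digits Scores are compared after rounding to this many
#'   decimals (default 3, the precision at which similarity scores are
#'   reported); equal-rounded scores are `no_change`, avoiding spurious
#'   score-changes from floating-point noise.
#' @return data.frame: `pwm_id`, `seq_offset`, `orientation`, `consequence`,
#'   `ref_core_score`, `ref_matrix_score`, `alt_core_score`,
#'   `alt_matrix_score`, `ref_site_seq`, `alt_site_seq` (absent-allele
#'   fields are `NA`), ordered by (pwm_id, offset, orientation).
#' @export
classify_matches <- function(ref_matches, alt_matches, score_digits = 3) {
  key <- function(m) paste(m$pwm_id, m$seq_offset, m$orientation, sep = "\r")
  rk <- key(ref_matches); ak <- key(alt_matches)
  if (anyDuplicated(rk) || anyDuplicated(ak)) {
    stop_rsnpdb("duplicate (pwm, offset, orientation) within one allele's ",
                "match list: scanner contract violated")
  }
  all_keys <- union(rk, ak)
  ri <- match(all_keys, rk); ai <- match(all_keys, ak)
  take <- function(m, i, col) {
    v <- m[[col]][i]
    v
  }
  base <- ifelse(is.na(ri),
                 "gain",
                 ifelse(is.na(ai), "loss", NA_character_))
  ref_ms <- take(ref_matches, ri, "matrix_score")
  alt_ms <- take(alt_matches, ai, "matrix_score")
  both <- is.na(base)
  base[both] <- ifelse(
    round(ref_ms[both], score_digits) != round(alt_ms[both], score_digits),
    "score_change", "no_change")
  src <- ifelse(is.na(ri), ai, ri)
  from <- ifelse(is.na(ri), "alt", "ref")
  out <- data.frame(
    pwm_id = ifelse(from == "ref", take(ref_matches, ri, "pwm_id"),
                    take(alt_matches, ai, "pwm_id")),
    seq_offset = as.integer(ifelse(from == "ref",
                                   take(ref_matches, ri, "seq_offset"),
                                   take(alt_matches, ai, "seq_offset"))),
    orientation = ifelse(from == "ref", take(ref_matches, ri, "orientation"),
                         take(alt_matches, ai, "orientation")),
    consequence = base,
    ref_core_score = take(ref_matches, ri, "core_score"),
    ref_matrix_score = ref_ms,
    alt_core_score = take(alt_matches, ai, "core_score"),
    alt_matrix_score = alt_ms,
    ref_site_seq = take(ref_matches, ri, "site_seq"),
    alt_site_seq = take(alt_matches, ai, "site_seq"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$pwm_id, out$seq_offset, out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict consequence records to footprints overlapping the SNP
#'
#' Keeps records whose footprint `[seq_offset, seq_offset + width - 1]`
#' contains the center position 26. Footprints not covering the SNP are
#' identical strings in both alleles, so this can only remove `no_change`
#' records; it guarantees every stored record is attributable to the SNP.
#'
#' @param records data.frame from [classify_matches()].
#' @param pwm_widths Named integer vector: width per `pwm_id`.
#' @param center_pos SNP position within the search sequence (1-based;
#'   default 26).
#' @return Filtered records.
#' @export
restrict_to_snp_overlap <- function(records, pwm_widths, center_pos = CENTER_POS) {
  if (nrow(records) == 0) return(records)
  w <- unname(pwm_widths[records$pwm_id])
  if (anyNA(w)) stop_rsnpdb("pwm_widths missing entries for some records")
  keep <- records$seq_offset <= center_pos &
    records$seq_offset + w - 1L >= center_pos
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag regulatory SNPs
#'
#' An rSNP is a SNP causing a gain, loss or score-change for at least one
#' binding site. `n_affected_tfbs` counts distinct affected sites per SNP,
#' identified by `(pwm_id, seq_offset, orientation, gene_strand)`.
#'
#' @param records Consequence data.frame carrying `snp_id` and `gene_strand`
#'   columns (see [annotate_consequences()]).
#' @param snp_ids Optional character vector of all SNP ids to report; SNPs
#'   without affected sites get `is_rsnp = FALSE`.
#' @return data.frame: `snp_id`, `is_rsnp`, `n_affected_tfbs`.
#' @export
flag_rsnps <- function(records, snp_ids = NULL) {
  affected <- records[records$consequence %in% c("gain", "loss", "score_change"), ,
                      drop = FALSE]
  if (nrow(affected)) {
    site_key <- paste(affected$pwm_id, affected$seq_offset,
                      affected$orientation, affected$gene_strand)
    dedup <- !duplicated(paste(affected$snp_id, site_key))
    counts <- table(affected$snp_id[dedup])
  } else {
    counts <- table(character(0))
  }
  ids <- snp_ids %||% sort(unique(records$snp_id))
  n <- as.integer(counts[match(ids, names(counts))])
  n[is.na(n)] <- 0L
  data.frame(snp_id = ids, is_rsnp = n >= 1L, n_affected_tfbs = n,
             stringsAsFactors = FALSE)
}

#' Scan and classify every allele sequence pair
#'
#' For each (SNP, gene-strand) search-sequence pair, scans both alleles with
#' the whole PWM library, classifies consequences, and restricts records to
#' footprints overlapping the SNP.
#'
#' @param pairs data.frame from [extract_pairs()].
#' @param spwms Named list of `ScoredPwm` objects ([prepare_library()]).
#' @param orientations Orientations to scan; both by default.
#' @param score_digits See [classify_matches()].
#' @param keep_no_change Keep `no_change` records (default `TRUE` here; the
#'   database build drops them by default, see [build_database()]).
#' @return Consequence data.frame with `snp_id` and `gene_strand` prepended.
#' @export
annotate_consequences <- function(pairs, spwms,
                                  orientations = c("forward", "reverse"),
                                  score_digits = 3, keep_no_change = TRUE) {
  widths <- vapply(spwms, function(s) s$width, integer(1))
  names(widths) <- vapply(spwms, function(s) s$pwm$pwm_id, character(1))
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ref_m <- scan_library(spwms, pairs$ref_seq[i], orientations)
    alt_m <- scan_library(spwms, pairs$alt_seq[i], orientations)
    rec <- classify_matches(ref_m, alt_m, score_digits = score_digits)
    rec <- restrict_to_snp_overlap(rec, widths)
    if (!keep_no_change) {
      rec <- rec[rec$consequence != "no_change", , drop = FALSE]
    }
    if (nrow(rec)) {
      rows[[i]] <- cbind(data.frame(snp_id = pairs$snp_id[i],
                                    gene_strand = pairs$gene_strand[i],
                                    stringsAsFactors = FALSE),
                         rec)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- empty_consequence_frame()
  }
  ord <- order(out$snp_id, out$gene_strand, out$pwm_id, out$seq_offset,
               out$orientation)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_consequence_frame <- function() {
  data.frame(snp_id = character(0), gene_strand = character(0),
             pwm_id = character(0), seq_offset = integer(0),
             orientation = character(0), consequence = character(0),
             ref_core_score = numeric(0), ref_matrix_score = numeric(0),
             alt_core_score = numeric(0), alt_matrix_score = numeric(0),
             ref_site_seq = character(0), alt_site_seq = character(0),
             stringsAsFactors = FALSE)
}
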