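## MATCH-style PWM scoring: pseudocount-regularized frequencies, a
## per-position information vector, and min-max normalized core / matrix
## similarity scores in [0, 1]. The core is the 5-position window of maximal
## summed information (leftmost on ties) unless the library annotates one.

#' Prepare a PWM for scanning
#'
#' Converts counts to row-stochastic frequencies with a pseudocount
#' (`freq(i,b) = (count(i,b) + p) / (sum_b count(i,b) + 4p)`), computes the
#' information vector `I(i) = sum_b freq(i,b) * ln(4 * freq(i,b))` (0 for a
#' uniform position, approaching `ln 4` for a fully conserved one), and
#' locates the 5-position core as the consecutive window maximizing
#' `sum I(i)`, taking the leftmost window on ties. An annotated
#' `core_start` on the Pwm overrides the computed core.
#'
#' @param pwm A [Pwm] object.
#' @param pseudocount Pseudocount added per base; default 0.8. May be 0 only
#'   if every position has a positive count sum.
#' @return An object of class `ScoredPwm` with elements `pwm`, `width`,
#'   `freqs`, `info`, `core_start`, and precomputed per-position weighted
#'   minima / maxima used for normalization.
#' @export
prepare_pwm <- function(pwm, pseudocount = 0.8) {
  stopifnot(inherits(pwm, "Pwm"))
  if (pseudocount < 0) stop_rsnpdb("pseudocount must be nonnegative")
  counts <- pwm$counts
  rs <- rowSums(counts)
  if (pseudocount == 0 && any(rs == 0)) {
    stop_rsnpdb("PWM '", pwm$pwm_id,
                "': all-zero count row requires a positive pseudocount")
  }
  freqs <- (counts + pseudocount) / (rs + 4 * pseudocount)
  lg <- freqs * log(4 * freqs)
  lg[freqs == 0] <- 0  # lim f->0 of f*ln(4f) is 0
  info <- rowSums(lg)
  w <- pwm$width
  if (!is.null(pwm$core_start)) {
    core_start <- pwm$core_start
  } else {
    cs <- cumsum(c(0, info))
    win_sums <- cs[6:(w + 1)] - cs[1:(w - 4)]
    core_start <- which.max(win_sums)  # which.max is leftmost on exact ties
  }
  wfreq <- freqs * info
  structure(
    list(pwm = pwm, width = w, freqs = freqs, info = info,
         core_start = as.integer(core_start),
         wfreq = wfreq,
         wmin = info * apply(freqs, 1, min),
         wmax = info * apply(freqs, 1, max)),
    class = "ScoredPwm"
  )
}

#' @export
print.ScoredPwm <- function(x, ...) {
  cat("ScoredPwm", x$pwm$pwm_id, "width", x$width,
      "core", x$core_start, "-", x$core_start + 4L, "\n")
  invisible(x)
}

## Internal: core and matrix similarity for every offset of seq (in the
## orientation given). Returns data.frame(offset, core_score, matrix_score)
## with offset the 1-based start within seq. Vectorized over offsets.
score_all_offsets <- function(spwm, seq) {
  w <- spwm$width
  idx <- seq_to_index(seq)
  if (anyNA(idx)) stop_rsnpdb("sequence contains letters outside A/C/G/T")
  L <- length(idx)
  noff <- L - w + 1L
  if (noff < 1L) {
    return(data.frame(offset = integer(0), core_score = numeric(0),
                      matrix_score = numeric(0)))
  }
  ## M[o, i] = base index at window offset o, PWM position i
  M <- vapply(seq_len(w), function(i) idx[seq_len(noff) + i - 1L],
              integer(noff))
  if (noff == 1L) M <- matrix(M, nrow = 1L)
  cur <- matrix(spwm$wfreq[cbind(rep(seq_len(w), each = noff), as.vector(M))],
                nrow = noff)
  core_cols <- spwm$core_start:(spwm$core_start + 4L)
  minmax_score <- function(current, wmin, wmax) {
    denom <- sum(wmax) - sum(wmin)
    if (denom <= 0) return(rep(1, length(current)))  # uninformative matrix
    (current - sum(wmin)) / denom
  }
  data.frame(
    offset = seq_len(noff),
    core_score = minmax_score(rowSums(cur[, core_cols, drop = FALSE]),
                              spwm$wmin[core_cols], spwm$wmax[core_cols]),
    matrix_score = minmax_score(rowSums(cur), spwm$wmin, spwm$wmax)
  )
}

#' Score a single window against a prepared PWM
#'
#' The matrix similarity score is `(Current - Min) / (Max - Min)` where
#' `Current = sum_i I(i) * freq(i, window_i)` and `Min` / `Max` substitute
#' the per-position minimum / maximum frequency; the core similarity score
#' is the same expression restricted to the 5 core positions. Both lie in
#' `[0, 1]`; a fully uninformative matrix (`Max = Min`) scores 1 by
#' definition.
#'
#' @param spwm A `ScoredPwm` from [prepare_pwm()].
#' @param window Character string over A/C/G/T of exactly the PWM width.
#' @return Named numeric vector `c(core_score, matrix_score)`.
#' @export
score_window <- function(spwm, window) {
  if (nchar(window) != spwm$width) {
    stop_rsnpdb("window length ", nchar(window), " != PWM width ", spwm$width)
  }
  sc <- score_all_offsets(spwm, window)
  c(core_score = sc$core_score[1], matrix_score = sc$matrix_score[1])
}

## Internal: site_seq formatting — core positions uppercase, flanks
## lowercase, in the orientation that matched the PWM.
format_site <- function(site, core_start) {
  s <- tolower(site)
  core <- toupper(substr(s, core_start, core_start + 4L))
  substr(s, core_start, core_start + 4L) <- core
  s
}

#' Scan a sequence for PWM matches in one or both orientations
#'
#' Every offset of the sequence is scored in each requested orientation; a
#' match is emitted when both the core and the matrix similarity scores reach
#' their cutoffs. For reverse-orientation matches the window's reverse
#' complement is scored and the reported offset is still the window start in
#' the scanned sequence's own coordinates; `site_seq` is given in PWM
#' orientation with the 5 core positions uppercased.
#'
#' @param spwm `ScoredPwm` from [prepare_pwm()].
#' @param seq Sequence to scan (typically a 51-bp search sequence).
#' @param orientations Subset of `c("forward", "reverse")`; both by default,
#'   since a binding site can reside on either strand of double-stranded
#'   DNA.
#' @param core_cutoff,matrix_cutoff Overrides; default to the cutoffs stored
#'   on the PWM.
#' @return data.frame of matches: `pwm_id`, `seq_offset` (1-based start of
#'   the footprint), `orientation`, `core_score`, `matrix_score`,
#'   `site_seq`; ordered by offset then orientation.
#' @export
scan_sequence <- function(spwm, seq,
                          orientations = c("forward", "reverse"),
                          core_cutoff = NULL, matrix_cutoff = NULL) {
  orientations <- match.arg(orientations, several.ok = TRUE)
  core_cutoff <- core_cutoff %||% spwm$pwm$core_cutoff
  matrix_cutoff <- matrix_cutoff %||% spwm$pwm$matrix_cutoff
  w <- spwm$width
  L <- nchar(seq)
  res <- list()
  for (ori in orientations) {
    s <- if (ori == "forward") seq else revcomp(seq)
    sc <- score_all_offsets(spwm, s)
    keep <- sc$core_score >= core_cutoff & sc$matrix_score >= matrix_cutoff
    sc <- sc[keep, , drop = FALSE]
    if (nrow(sc) == 0) next
    site <- substr(rep(s, nrow(sc)), sc$offset, sc$offset + w - 1L)
    offset <- if (ori == "forward") sc$offset else L - w - sc$offset + 2L
    res[[ori]] <- data.frame(
      pwm_id = spwm$pwm$pwm_id,
      seq_offset = as.integer(offset),
      orientation = ori,
      core_score = sc$core_score,
      matrix_score = sc$matrix_score,
      site_seq = vapply(site, format_site, character(1),
                        core_start = spwm$core_start, USE.NAMES = FALSE),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(pwm_id = character(0), seq_offset = integer(0),
               orientation = character(0), core_score = numeric(0),
               matrix_score = numeric(0), site_seq = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$seq_offset, out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a sequence against a whole PWM library
#'
#' @param spwms Named list of `ScoredPwm` objects (see [prepare_library()]).
#' @param seq Sequence to scan.
#' @inheritParams scan_sequence
#' @return Row-bound matches from [scan_sequence()] over all PWMs, ordered
#'   by (pwm_id, offset, orientation).
#' @export
scan_library <- function(spwms, seq, orientations = c("forward", "reverse")) {
  res <- lapply(spwms, scan_sequence, seq = seq, orientations = orientations)
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(pwm_id = character(0), seq_offset = integer(0),
                      orientation = character(0), core_score = numeric(0),
                      matrix_score = numeric(0), site_seq = character(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$pwm_id, out$seq_offset, out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prepare every PWM of a library for scanning
#'
#' @param pwms Named list of [Pwm] objects from [read_pwm_library()].
#' @param pseudocount Passed to [prepare_pwm()].
#' @return Named list of `ScoredPwm` objects.
#' @export
prepare_library <- function(pwms, pseudocount = 0.8) {
  lapply(pwms, prepare_pwm, pseudocount = pseudocount)
}
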