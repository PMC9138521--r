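# Independent brute-force implementation of the MATCH-style scoring scheme,
# written straight from the formulas with explicit loops. It shares no code
# with the package scanner and serves as the oracle the scanner is checked
# against.

oracle_freqs <- function(counts, pseudocount) {
  w <- nrow(counts)
  f <- matrix(0, w, 4)
  for (i in seq_len(w)) {
    tot <- sum(counts[i, ]) + 4 * pseudocount
    for (b in 1:4) f[i, b] <- (counts[i, b] + pseudocount) / tot
  }
  f
}

oracle_info <- function(f) {
  I <- numeric(nrow(f))
  for (i in seq_len(nrow(f))) {
    for (b in 1:4) {
      if (f[i, b] > 0) I[i] <- I[i] + f[i, b] * log(4 * f[i, b])
    }
  }
  I
}

oracle_core_start <- function(I) {
  best <- -Inf; best_i <- 1L
  for (i in seq_len(length(I) - 4L)) {
    s <- 0
    for (j in i:(i + 4L)) s <- s + I[j]
    if (s > best) { best <- s; best_i <- i }
  }
  best_i
}

# Core and matrix similarity of one window given precomputed frequencies,
# information vector and core start.
oracle_score_given <- function(f, I, cs, window) {
  idx <- match(strsplit(window, "")[[1]], c("A", "C", "G", "T"))
  score_over <- function(pos) {
    cur <- mn <- mx <- 0
    for (i in pos) {
      cur <- cur + I[i] * f[i, idx[i]]
      mn <- mn + I[i] * min(f[i, ])
      mx <- mx + I[i] * max(f[i, ])
    }
    if (mx - mn <= 0) return(1)
    (cur - mn) / (mx - mn)
  }
  c(core = score_over(cs:(cs + 4L)),
    matrix = score_over(seq_len(nrow(f))))
}

oracle_score <- function(counts, pseudocount, window) {
  f <- oracle_freqs(counts, pseudocount)
  I <- oracle_info(f)
  oracle_score_given(f, I, oracle_core_start(I), window)
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Exhaustive enumeration of all offsets x orientations of seq.
oracle_scan <- function(counts, pseudocount, seq) {
  w <- nrow(counts)
  L <- nchar(seq)
  f <- oracle_freqs(counts, pseudocount)
  I <- oracle_info(f)
  cs <- oracle_core_start(I)
  rows <- list()
  for (ori in c("forward", "reverse")) {
    for (off in seq_len(L - w + 1L)) {
      win <- substr(seq, off, off + w - 1L)
      if (ori == "reverse") win <- oracle_revcomp(win)
      sc <- oracle_score_given(f, I, cs, win)
      rows[[length(rows) + 1L]] <- data.frame(
        seq_offset = off, orientation = ori,
        core_score = unname(sc["core"]), matrix_score = unname(sc["matrix"]))
    }
  }
  do.call(rbind, rows)
}

random_pwm_counts <- function(width) {
  matrix(sample(0:60, width * 4, replace = TRUE), width, 4,
         dimnames = list(NULL, c("A", "C", "G", "T")))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
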