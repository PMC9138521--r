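sharp_pwm <- function(consensus, id = "P$TOY_01", core = 0.75, mat = 0.85) {
  bases <- strsplit(consensus, "")[[1]]
  counts <- matrix(1, length(bases), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(bases)) counts[i, bases[i]] <- 97
  Pwm(id, counts, core_cutoff = core, matrix_cutoff = mat)
}

test_that("information vector: uniform position is 0, conserved approaches ln 4", {
  uni <- Pwm("P$UNI_01", matrix(1, 6, 4))
  s <- prepare_pwm(uni)
  expect_equal(s$info, rep(0, 6))
  # near-degenerate column with vanishing pseudocount -> I -> ln 4
  deg <- matrix(0, 5, 4); deg[, 1] <- 1000
  s2 <- prepare_pwm(Pwm("P$DEG_01", deg), pseudocount = 1e-9)
  expect_equal(s2$info, rep(log(4), 5), tolerance = 1e-6)
  expect_error(prepare_pwm(Pwm("P$Z_01", matrix(0, 5, 4)), pseudocount = 0),
               "pseudocount")
})

test_that("frequencies are row-stochastic and the core is the max-info 5-window", {
  set.seed(42)
  for (rep in 1:25) {
    w <- sample(5:12, 1)
    counts <- random_pwm_counts(w)
    s <- prepare_pwm(Pwm("P$R_01", counts), pseudocount = 0.8)
    expect_equal(rowSums(s$freqs), rep(1, w), tolerance = 1e-12)
    expect_true(all(s$info >= 0))
    expect_equal(s$core_start,
                 oracle_core_start(oracle_info(oracle_freqs(counts, 0.8))))
  }
})

test_that("an asymmetric information profile places the core off-center", {
  # positions 2..6 carry nearly all information; window sums peak at start 2
  counts <- rbind(c(30, 25, 25, 20),
                  c(97, 1, 1, 1), c(1, 97, 1, 1), c(97, 1, 1, 1),
                  c(1, 1, 97, 1), c(1, 1, 1, 97))
  s <- prepare_pwm(Pwm("P$OFF_01", counts))
  expect_equal(s$core_start, 2L)
  # ties break leftmost: a fully uniform matrix has all-zero window sums
  expect_equal(prepare_pwm(Pwm("P$UNI_01", matrix(1, 8, 4)))$core_start, 1L)
})

test_that("consensus scores 1, anti-consensus scores 0, annotated core honored", {
  counts <- random_pwm_counts(7)
  set.seed(9)
  s <- prepare_pwm(Pwm("P$LIM_01", counts))
  consensus <- paste(c("A", "C", "G", "T")[apply(s$freqs, 1, which.max)],
                     collapse = "")
  anti <- paste(c("A", "C", "G", "T")[apply(s$freqs, 1, which.min)],
                collapse = "")
  expect_equal(unname(score_window(s, consensus)["matrix_score"]), 1)
  expect_equal(unname(score_window(s, anti)["matrix_score"]), 0)
  expect_equal(unname(score_window(s, consensus)["core_score"]), 1)
  # uninformative matrix: Max = Min -> score defined as 1
  su <- prepare_pwm(Pwm("P$UNI_01", matrix(1, 6, 4)))
  expect_equal(unname(score_window(su, "ACGTAC")["matrix_score"]), 1)
  # an annotated core overrides the computed window
  sa <- prepare_pwm(Pwm("P$ANN_01", counts, core_start = 3))
  expect_equal(sa$core_start, 3L)
  expect_error(score_window(s, "ACGT"), "width")
})

test_that("window scores equal the brute-force oracle to 1e-12", {
  set.seed(123)
  for (rep in 1:50) {
    counts <- random_pwm_counts(8)
    s <- prepare_pwm(Pwm("P$OR_01", counts))
    win <- random_dna(8)
    got <- score_window(s, win)
    want <- oracle_score(counts, 0.8, win)
    expect_equal(unname(got["core_score"]), unname(want["core"]),
                 tolerance = 1e-12)
    expect_equal(unname(got["matrix_score"]), unname(want["matrix"]),
                 tolerance = 1e-12)
  }
})

test_that("a planted consensus is found exactly once, score 1, right offset", {
  set.seed(55)
  pwm <- sharp_pwm("TATAAA")
  s <- prepare_pwm(pwm)
  repeat {  # background guaranteed free of TATAAA by construction
    bg <- random_dna(51)
    if (!grepl("TATAAA", bg, fixed = TRUE) &&
        !grepl("TATAAA", oracle_revcomp(bg), fixed = TRUE)) break
  }
  seq <- paste0(substr(bg, 1, 20), "TATAAA", substr(bg, 27, 51))
  hits <- scan_sequence(s, seq)
  fwd <- hits[hits$orientation == "forward" & hits$matrix_score == 1, ]
  expect_equal(fwd$seq_offset, 21L)
  expect_equal(unlist(gregexpr("TATAAA", seq, fixed = TRUE)), 21L)
  # cutoffs (1, 1) against background without the consensus -> empty
  expect_equal(nrow(scan_sequence(s, bg, core_cutoff = 1, matrix_cutoff = 1)), 0L)
})

test_that("scanning is strand-symmetric", {
  set.seed(66)
  for (rep in 1:10) {
    counts <- random_pwm_counts(sample(5:10, 1))
    s <- prepare_pwm(Pwm("P$SYM_01", counts, core_cutoff = 0, matrix_cutoff = 0))
    seq <- random_dna(51)
    a <- scan_sequence(s, seq)
    b <- scan_sequence(s, oracle_revcomp(seq))
    # a forward match at offset o maps to a reverse match at L - w - o + 2
    w <- nrow(counts)
    map <- function(d, ori) {
      d <- d[d$orientation == ori, ]
      d[order(d$seq_offset), c("seq_offset", "core_score", "matrix_score")]
    }
    af <- map(a, "forward"); br <- map(b, "reverse")
    br$seq_offset <- sort(51 - w - br$seq_offset + 2)
    expect_equal(af$seq_offset, br$seq_offset)
    expect_equal(sort(af$matrix_score), sort(br$matrix_score), tolerance = 1e-12)
    ar <- map(a, "reverse"); bf <- map(b, "forward")
    expect_equal(sort(ar$matrix_score), sort(bf$matrix_score), tolerance = 1e-12)
  }
})

test_that("raising either cutoff only ever shrinks the match set", {
  set.seed(88)
  counts <- random_pwm_counts(6)
  seq <- random_dna(51)
  key <- function(m) paste(m$seq_offset, m$orientation)
  prev <- NULL
  for (cut in c(0, 0.25, 0.5, 0.75, 0.9, 1)) {
    s <- prepare_pwm(Pwm("P$MONO_01", counts, core_cutoff = cut / 2,
                         matrix_cutoff = cut))
    cur <- scan_sequence(s, seq)
    if (!is.null(prev)) expect_true(all(key(cur) %in% key(prev)))
    prev <- cur
  }
})

test_that("emitted matches respect cutoffs and the [0,1] score range", {
  set.seed(99)
  s <- prepare_pwm(Pwm("P$RANGE_01", random_pwm_counts(7),
                       core_cutoff = 0.6, matrix_cutoff = 0.7))
  hits <- scan_sequence(s, random_dna(51))
  if (nrow(hits)) {
    expect_true(all(hits$core_score >= 0.6 & hits$core_score <= 1))
    expect_true(all(hits$matrix_score >= 0.7 & hits$matrix_score <= 1))
    expect_true(all(hits$seq_offset + 7 - 1 <= 51))
    # site_seq: 5 core positions uppercase, flanks lowercase
    core_part <- substr(hits$site_seq, s$core_start, s$core_start + 4)
    expect_true(all(core_part == toupper(core_part)))
    flank <- paste0(substr(hits$site_seq, 1, s$core_start - 1),
                    substr(hits$site_seq, s$core_start + 5, 7))
    expect_true(all(flank == tolower(flank)))
  }
})
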