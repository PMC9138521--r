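#' @importFrom methods is
#' @importFrom stats setNames
#' @importFrom utils write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of character sequences
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences over A/C/G/T/N.
#' @return Character vector of the same length.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Complement of single bases, preserving vectorization.
comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

## Split a sequence string into an integer vector over A=1,C=2,G=3,T=4.
## Unknown letters map to NA.
seq_to_index <- function(s) {
  match(strsplit(toupper(s), "", fixed = TRUE)[[1]], DNA_BASES)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_rsnpdb <- function(...) stop(..., call. = FALSE)

## Deterministic TSV writer used by every export: fixed column order,
## no quoting, "." for NA, literal tab separation.
write_tsv_det <- function(df, path) {
  df[] <- lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) {
      ifelse(is.na(col), ".", sprintf("%.6f", col))
    } else {
      col <- as.character(col)
      ifelse(is.na(col), ".", col)
    }
  })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = ".")
  invisible(path)
}
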