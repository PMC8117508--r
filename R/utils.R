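# Internal sequence and validation helpers. Alphabet is DNA internally;
# U on input is mapped to T at entry points.

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
dna_norm <- function(x) {
  chartr("uU", "TT", toupper(x))
}

#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
rand_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Seed of a mature miRNA: nucleotides 2-8 from the 5' end (7 nt).
#' @noRd
seed_of <- function(sequence) {
  substr(dna_norm(sequence), 2L, 8L)
}

#' @noRd
stopifnot_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, min, max),
         call. = FALSE)
  }
  invisible(x)
}

# Hamming distance between equal-length strings; Inf if lengths differ.
#' @noRd
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
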