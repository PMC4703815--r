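# Internal string helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Reverse complement of plain character vectors (N maps to N).
revcomp <- function(x) {
  stopifnot(is.character(x))
  flipped <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# All rotations of a motif, in phase order starting at the motif itself.
motif_rotations <- function(motif) {
  p <- nchar(motif)
  vapply(seq_len(p) - 1L, function(i) {
    paste0(substr(motif, i + 1L, p), substr(motif, 1L, i))
  }, character(1))
}

# A motif is primitive when it is not a whole-number repetition of a shorter
# motif (e.g. "ATAT" is not primitive, "AT" is).
motif_is_primitive <- function(motif) {
  p <- nchar(motif)
  for (d in seq_len(p - 1L)) {
    if (p %% d == 0L &&
        motif == strrep(substr(motif, 1L, d), p %/% d)) {
      return(FALSE)
    }
  }
  TRUE
}

# Uniform random DNA string(s), used by the simulator and tests.
random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
  }, character(1))
}

as_dna_set <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x)) {
    if (is.null(names(x))) stop("character sequences must be named by seq_id")
    return(Biostrings::DNAStringSet(x))
  }
  if (is.data.frame(x)) {
    return(Biostrings::DNAStringSet(setNames(x$residues, x$seq_id)))
  }
  stop("cannot interpret sequences of class ", paste(class(x), collapse = "/"))
}

#' @importFrom methods is
NULL
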