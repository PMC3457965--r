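#' Validate and normalize a DNA sequence
#'
#' Sequences are handled as plain uppercase character strings restricted to
#' the unambiguous alphabet A, C, G, T. IUPAC ambiguity codes are rejected:
#' the thermodynamic parameter tables are defined for unambiguous bases only
#' and a silent expansion would mis-parameterize the duplex.
#'
#' @param x character scalar, the sequence (case-insensitive).
#' @param min_len minimum accepted length.
#' @param what label used in error messages.
#' @return the normalized (uppercase) sequence string.
#' @keywords internal
normalize_dna <- function(x, min_len = 1L, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  x <- toupper(x)
  if (nchar(x) < min_len) {
    stop(what, " must have at least ", min_len, " bases", call. = FALSE)
  }
  if (grepl("[^ACGT]", x)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", x), "")[[1]])
    stop(what, " contains non-ACGT characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}

#' G/C content of a DNA sequence
#'
#' Fraction of G and C bases, expressed as a percentage. The exact value is
#' returned; rounding to whole percent (as printed in probe tables) is left
#' to the caller.
#'
#' @param sequence character vector of DNA sequences (A/C/G/T only).
#' @return numeric vector, `100 * (#G + #C) / length`.
#' @examples
#' gc_content("GAGTGTGACATCTTC")      # 46.67
#' round(gc_content("GGGG"))          # 100
#' @export
gc_content <- function(sequence) {
  vapply(sequence, function(s) {
    s <- normalize_dna(s)
    n <- nchar(s)
    100 * (n - nchar(gsub("[GC]", "", s))) / n
  }, numeric(1), USE.NAMES = FALSE)
}

#' Complement and reverse-complement of a plain sequence string
#'
#' `complement_seq()` returns the base-wise complement (same orientation in
#' the string, i.e. the opposing strand written 3'->5' when the input is
#' written 5'->3'). `reverse_complement()` returns the opposing strand
#' written 5'->3'.
#'
#' @param sequence character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
complement_seq <- function(sequence) {
  chartr("ACGT", "TGCA", toupper(sequence))
}

#' @rdname complement_seq
#' @export
reverse_complement <- function(sequence) {
  vapply(complement_seq(sequence), function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Reverse a string.
str_rev <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

# TRUE when base b (probe) and base t (target, opposing strand) form a
# Watson-Crick pair.
is_wc_pair <- function(b, t) {
  chartr("ACGT", "TGCA", b) == t
}
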