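#' Screen flanking sequence for probe binding sites
#'
#' Slides a probe over both strands of the sequence flanking its extraction
#' locus and reports every site with at most `max_mismatches` mismatches. A
#' hit is flagged `three_prime_matched` (extendable by the polymerase, and
#' therefore a specificity risk) when the `anchor_len` bases at the probe 3'
#' end are all matched. The design site itself is reported and labelled as
#' the intended site. Probes containing runs of three or more consecutive
#' guanosines trigger a promiscuous-hybridization warning.
#'
#' Candidate sites are located with [Biostrings::matchPattern()] and every
#' hit is re-verified base-by-base against the sequence.
#'
#' @param probe a [probe_spec()] object or a plain probe sequence (5'->3').
#' @param flank_seq forward-strand sequence of the scan window.
#' @param locus_pos 1-based position within `flank_seq` of the probe 3'
#'   terminus at the intended design site (on the strand given by
#'   `strand_of_design`).
#' @param max_mismatches maximum mismatches for a reported hit.
#' @param three_prime_anchor_len number of 3'-terminal probe bases that must
#'   all match for a hit to be flagged extendable.
#' @param window_kb half-width of the intended scan window in kb; hits
#'   farther than this from `locus_pos` are retained but flagged, so an
#'   over-wide input window is visible rather than silently truncated.
#' @param strand_of_design strand on which the probe text occurs at the
#'   design site: `"+"` when `flank_seq` contains the probe sequence
#'   verbatim.
#' @return an object of class `hit_report`: list with `set_name`, `hits`
#'   (data.frame: `start`, `end`, `strand`, `mismatch_count`,
#'   `three_prime_matched`, `distance_kb`, `intended_site`) and `summary`
#'   (named counts).
#' @export
scan_binding_sites <- function(probe, flank_seq, locus_pos,
                               max_mismatches = 2L,
                               three_prime_anchor_len = 3L,
                               window_kb = 50,
                               strand_of_design = "+") {
  if (inherits(probe, "probe_spec")) {
    set_name <- probe$set_name
    pseq <- probe$sequence
  } else {
    set_name <- "probe"
    pseq <- normalize_dna(probe, min_len = 6L, what = "probe")
  }
  flank_seq <- normalize_dna(flank_seq, min_len = nchar(pseq),
                             what = "flank_seq")
  L <- nchar(pseq)
  if (three_prime_anchor_len > L) {
    stop("three_prime_anchor_len exceeds the probe length", call. = FALSE)
  }
  if (nchar(flank_seq) < L) stop("scan window shorter than the probe", call. = FALSE)
  if (grepl("GGG", pseq, fixed = TRUE)) {
    warning("probe ", set_name, " contains a run of >= 3 guanosines and may ",
            "hybridize promiscuously", call. = FALSE)
  }

  subject <- Biostrings::DNAString(flank_seq)
  one_strand <- function(pattern, strand) {
    m <- Biostrings::matchPattern(pattern, subject,
                                  max.mismatch = max_mismatches)
    if (length(m) == 0L) return(NULL)
    starts <- BiocGenerics::start(m)
    ends <- BiocGenerics::end(m)
    keep <- ends - starts + 1L == L  # no indels
    starts <- starts[keep]; ends <- ends[keep]
    if (length(starts) == 0L) return(NULL)
    site <- substring(flank_seq, starts, ends)
    # re-verify every hit base-by-base against the stored sequence
    mmcount <- mapply(function(s) {
      sum(strsplit(s, "")[[1]] != strsplit(pattern, "")[[1]])
    }, site)
    keep <- mmcount <= max_mismatches
    data.frame(start = starts, end = ends, strand = strand,
               mismatch_count = as.integer(mmcount),
               site = site)[keep, , drop = FALSE]
  }

  fwd <- one_strand(pseq, "+")
  rev <- one_strand(reverse_complement(pseq), "-")
  hits <- rbind(fwd, rev)
  if (is.null(hits) || nrow(hits) == 0L) {
    hits <- data.frame(start = integer(), end = integer(),
                       strand = character(), mismatch_count = integer(),
                       site = character())
  }

  # 3' anchor: for '+' hits the probe 3' end lies at `end`; for '-' hits the
  # matched text is the reverse complement, so the 3' end lies at `start`.
  anchor_ok <- logical(nrow(hits))
  p_anchor <- substr(pseq, L - three_prime_anchor_len + 1L, L)
  rc_anchor <- substr(reverse_complement(pseq), 1L, three_prime_anchor_len)
  for (i in seq_len(nrow(hits))) {
    anchor_ok[i] <- if (hits$strand[i] == "+") {
      substr(hits$site[i], L - three_prime_anchor_len + 1L, L) == p_anchor
    } else {
      substr(hits$site[i], 1L, three_prime_anchor_len) == rc_anchor
    }
  }
  hits$three_prime_matched <- anchor_ok

  three_prime_pos <- ifelse(hits$strand == "+", hits$end, hits$start)
  hits$distance_kb <- abs(three_prime_pos - locus_pos) / 1000
  hits$intended_site <- hits$strand == strand_of_design &
    three_prime_pos == locus_pos & hits$mismatch_count == 0L
  hits$beyond_window <- hits$distance_kb > window_kb
  hits$site <- NULL
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL

  structure(
    list(set_name = set_name, hits = hits,
         summary = c(n_hits = nrow(hits),
                     n_three_prime_matched = sum(hits$three_prime_matched),
                     n_offtarget = sum(!hits$intended_site),
                     n_offtarget_extendable = sum(!hits$intended_site &
                                                    hits$three_prime_matched))),
    class = "hit_report"
  )
}

#' @export
print.hit_report <- function(x, ...) {
  cat("Binding-site scan for", x$set_name, "\n")
  cat(sprintf("  %d hit(s); %d with matched 3' end; %d off-target (%d extendable)\n",
              x$summary[["n_hits"]], x$summary[["n_three_prime_matched"]],
              x$summary[["n_offtarget"]], x$summary[["n_offtarget_extendable"]]))
  if (nrow(x$hits)) print(x$hits, row.names = FALSE)
  invisible(x)
}
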