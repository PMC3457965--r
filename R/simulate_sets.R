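#' Simulate the delta-con curve of a catalogued probe set
#'
#' Looks a probe set up in the packaged catalogue ([hse_probes()]), builds
#' its 5'-truncation length series and computes the [delta_con_curve()] at
#' the given conditions. For the two worked-example sets (P224FC, P30RC)
#' the per-length profile table carries a longer 5' extension of the design
#' than the catalogue; its longest sequence is used so the series can cover
#' the full published length range.
#'
#' @param set_name a `set_name` from [hse_probes()].
#' @param lengths lengths to simulate; default 8 nt up to the full design.
#' @param params an [nn_params()] parameter set.
#' @param conditions a [duplex_params()] object.
#' @param ... passed on to [delta_con_curve()].
#' @return a [delta_con_curve()] object.
#' @examples
#' \donttest{
#' simulate_probe_set("P224FC")
#' }
#' @export
simulate_probe_set <- function(set_name, lengths = NULL,
                               params = nn_params(),
                               conditions = duplex_params(), ...) {
  cat <- hse_probes()
  row <- cat[cat$set_name == set_name, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("unknown probe set: ", set_name, call. = FALSE)
  }
  seq_full <- row$sequence
  prof <- hse_length_profiles()
  prof <- prof[prof$set_name == set_name, , drop = FALSE]
  if (nrow(prof) && max(nchar(prof$sequence)) > nchar(seq_full)) {
    seq_full <- prof$sequence[which.max(nchar(prof$sequence))]
  }
  offset <- if (grepl("-1$", set_name)) 1L else 0L
  # set names end in <F|R><allele base> (optionally "-1"): P224FC, P30RC-1
  stem <- sub("-1$", "", set_name)
  ori_chr <- substr(stem, nchar(stem) - 1L, nchar(stem) - 1L)
  orientation <- if (identical(ori_chr, "R")) "reverse" else "forward"
  if (is.null(lengths)) lengths <- seq.int(8L, nchar(seq_full))
  probes <- probe_series(seq_full, lengths = lengths,
                         mismatch = row$mismatch,
                         discriminator_offset = offset,
                         orientation = orientation,
                         set_name = set_name)
  delta_con_curve(probes, params = params, conditions = conditions, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The six core probe sets spanning the G/C range
#'
#' A fixed panel of six terminal-discriminator probe sets whose mean G/C
#' content spans roughly 25-85%, used to examine how the optimum of the
#' delta-con curve shifts with G/C content: higher G/C moves the optimal
#' probe length shorter.
#'
#' @return character vector of six set names, ordered from highest to
#'   lowest mean G/C content.
#' @export
core_probe_sets <- function() {
  c("P38FC", "P244RC", "P224RG", "P224FC", "P30FG", "P30RC")
}

#' Delta-con optimum versus G/C content across the core sets
#'
#' Simulates every core probe set and tabulates the mean G/C content over
#' the simulated length series together with the delta-con-optimal length.
#'
#' @inheritParams simulate_probe_set
#' @param sets probe set names, default [core_probe_sets()].
#' @return data.frame with columns `set_name`, `mean_gc_pct`,
#'   `best_length`, `max_delta_con`, sorted by increasing `mean_gc_pct`.
#' @export
gc_shift_table <- function(sets = core_probe_sets(),
                           params = nn_params(),
                           conditions = duplex_params(), ...) {
  rows <- lapply(sets, function(s) {
    cv <- simulate_probe_set(s, params = params, conditions = conditions, ...)
    data.frame(set_name = s,
               mean_gc_pct = mean(cv$gc_pct),
               best_length = attr(cv, "best_length"),
               max_delta_con = max(cv$delta_con))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mean_gc_pct), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Experimental best-probe points for the G/C-length regression
#'
#' Extracts from the packaged set summary the probes marked (by asterisk)
#' as experimentally most specific, and computes for each best length the
#' G/C content of the actual probe of that length (the 5'-truncation of the
#' catalogued design). These are the experimental points used to fit the
#' G/C-content-versus-optimal-length line.
#'
#' @return data.frame with columns `set_name`, `best_length`, `gc_pct`.
#' @export
best_probe_points <- function() {
  summ <- hse_set_summary()
  cat <- hse_probes()
  starred <- summ[grepl("\\*", summ$best_tested_length), , drop = FALSE]
  rows <- lapply(seq_len(nrow(starred)), function(i) {
    lens <- parse_best_lengths(starred$best_tested_length[i])[[1]]
    seq_full <- cat$sequence[cat$set_name == starred$set_name[i]]
    if (length(seq_full) != 1L) {
      stop("set ", starred$set_name[i], " not found in the probe catalogue",
           call. = FALSE)
    }
    n <- nchar(seq_full)
    data.frame(set_name = starred$set_name[i], best_length = lens,
               gc_pct = gc_content(substring(seq_full, n - lens + 1L, n)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
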