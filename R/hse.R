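#' Curated experimental probe tables
#'
#' Three tables transcribed from a published haplotype-specific extraction
#' (HSE) probe study accompany the package and drive the concordance
#' analyses:
#'
#' * `hse_probes()` -- the tested probe catalogue: 41 probe sets with the
#'   full-length design sequence, the probe-target mismatch label, and the
#'   tested-length tokens (singletons and ranges such as `"17, 19-22"`),
#'   kept verbatim.
#' * `hse_set_summary()` -- the per-set experimental summary: mean G/C
#'   content, off-target hit listing, best HSE enrichment (%), best tested
#'   probe length(s) (asterisks mark the most specific probes), the
#'   match/mismatch free-energy difference ddG(M-MM) in kcal/mol, the
#'   simulated best length(s), and the printed prediction-concordance label
#'   (`r` = right, `w` = wrong).
#' * `hse_length_profiles()` -- the per-length profiles of the two
#'   worked-example sets (P224FC, P30RC): sequence, G/C%, Tm, dG, HSE
#'   enrichment with sd and replicate count, and simulated match/mismatch
#'   duplex concentrations (in 1e-17 M units).
#'
#' Transcription notes: decimal commas in the source are normalized to
#' decimal points; en-dash length ranges to ASCII hyphens. Known
#' inconsistencies of the source tables are preserved verbatim rather than
#' corrected (for example the P240FT row lists mismatch `C-A` although the
#' set name implies a T discriminator, and the set summary lists the Tat
#' locus with FG/FG-1 designs where the probe catalogue carries them under
#' rs13304202). Printed per-length `delta_con` values are consistent with
#' `con_M - con_MM` only to +/-1 in the last printed digit because each
#' column was rounded independently.
#'
#' @return a data.frame (see Details for columns).
#' @export
hse_probes <- function() {
  read_fixture("probe_sets.tsv")
}

#' @rdname hse_probes
#' @export
hse_set_summary <- function() {
  read_fixture("set_summary.tsv")
}

#' @rdname hse_probes
#' @export
hse_length_profiles <- function() {
  read_fixture("length_profiles.tsv")
}

read_fixture <- function(name) {
  f <- system.file("extdata", "tables", name, package = "hseprobe",
                   mustWork = TRUE)
  utils::read.delim(f, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Parse tested-length tokens
#'
#' Length lists in the probe catalogue mix singletons and ranges, e.g.
#' `"17, 19-22"` denotes lengths 17, 19, 20, 21, 22.
#'
#' @param tokens character vector of length-list strings.
#' @return list of integer vectors.
#' @export
parse_length_tokens <- function(tokens) {
  lapply(tokens, function(tok) {
    if (is.na(tok) || !nzchar(trimws(tok))) return(integer())
    parts <- trimws(strsplit(tok, ",", fixed = TRUE)[[1]])
    out <- lapply(parts, function(p) {
      if (grepl("^[0-9]+$", p)) return(as.integer(p))
      m <- regmatches(p, regexec("^([0-9]+)\\s*-\\s*([0-9]+)$", p))[[1]]
      if (length(m) != 3L) stop("malformed length token: '", p, "'",
                                call. = FALSE)
      seq.int(as.integer(m[2]), as.integer(m[3]))
    })
    sort(unique(unlist(out)))
  })
}

#' Count probe sets and distinct probes in the catalogue
#'
#' @param probes the probe catalogue, default [hse_probes()].
#' @return list with `n_sets` (distinct probe set names) and `n_probes`
#'   (distinct set/length combinations).
#' @examples
#' count_probes()   # 41 sets, 137 probes
#' @export
count_probes <- function(probes = hse_probes()) {
  lens <- parse_length_tokens(probes$tested_lengths)
  list(n_sets = length(unique(probes$set_name)),
       n_probes = sum(lengths(lens)))
}

#' HSE enrichment of one contributor
#'
#' Share of the total STR signal attributable to the dominant contributor,
#' `100 * max(s1, s2) / (s1 + s2)`. The published efficiency equation is
#' available only as a figure; this surrogate is used because it is
#' symmetric in contributor labelling and reproduces the reported behaviour
#' (50% for an unseparated mixture, approaching 100% for complete
#' separation).
#'
#' @param signal_1,signal_2 non-negative peak signals of the two
#'   contributors at one STR marker (vectorized).
#' @return enrichment percentage in `[50, 100]`.
#' @examples
#' hse_enrichment(700, 300)  # 70
#' hse_enrichment(500, 500)  # 50
#' @export
hse_enrichment <- function(signal_1, signal_2) {
  if (any(signal_1 < 0) || any(signal_2 < 0)) {
    stop("peak signals must be non-negative", call. = FALSE)
  }
  tot <- signal_1 + signal_2
  if (any(tot == 0)) stop("both peak signals are zero", call. = FALSE)
  100 * pmax(signal_1, signal_2) / tot
}

#' Classify HSE separation success
#'
#' Categorizes an enrichment percentage using the published thresholds:
#' complete separation above 89%, significant separation from 61%, no
#' separation at or below 60%. The three categories partition `[0, 100]`.
#'
#' @param enrichment_pct numeric vector in `[0, 100]`.
#' @return factor with levels `none`, `significant`, `complete`.
#' @examples
#' classify_separation(c(90, 61, 60))
#' @export
classify_separation <- function(enrichment_pct) {
  if (any(enrichment_pct < 0 | enrichment_pct > 100)) {
    stop("enrichment must lie in [0, 100]", call. = FALSE)
  }
  cut(enrichment_pct, breaks = c(-Inf, 60, 89, Inf),
      labels = c("none", "significant", "complete"))
}

# Strip asterisks / whitespace from a printed best-length token and parse
# numeric lengths; "n.s." and "no" give integer(0).
parse_best_lengths <- function(tok) {
  parse_length_tokens(gsub("\\*", "", ifelse(grepl("n\\.s\\.|^no$", tok),
                                             "", tok)))
}

#' Concordance between predicted and experimental optimal probe lengths
#'
#' Summarizes the printed per-set concordance labels (`r` = the simulated
#' delta-con optimum matched the experimentally best probe, `w` = it did
#' not), and, separately, recomputes a rule-based concordance from the
#' printed best lengths: a set counts as concordant when some experimentally
#' best length lies within `k` nt of some simulated best length. The two
#' counts are reported side by side; the printed labels are the primary
#' figure, the rule-based recount makes the labelling criterion explicit.
#'
#' @param summary_tab the set summary table, default [hse_set_summary()].
#' @param k half-width (nt) of the rule-based concordance window.
#' @return list with `n_sets`, `n_concordant`, `n_discordant`,
#'   `pct_concordant` (printed labels), and `rule_based` (list with `k`,
#'   `n_evaluable`, `n_concordant`, `pct_concordant`).
#' @examples
#' concordance_summary()   # 41 sets, 36 concordant (88%)
#' @export
concordance_summary <- function(summary_tab = hse_set_summary(), k = 1L) {
  lab <- summary_tab$concordance
  if (any(is.na(lab) | !lab %in% c("r", "w"))) {
    stop("concordance labels must all be 'r' or 'w'", call. = FALSE)
  }
  n <- nrow(summary_tab)
  if (n == 0L) stop("empty probe-set summary", call. = FALSE)
  n_r <- sum(lab == "r")

  best_exp <- parse_best_lengths(summary_tab$best_tested_length)
  best_sim <- parse_best_lengths(summary_tab$sim_best_length)
  evaluable <- lengths(best_exp) > 0L & lengths(best_sim) > 0L
  agree <- mapply(function(e, s) {
    if (length(e) == 0L || length(s) == 0L) return(NA)
    min(abs(outer(e, s, "-"))) <= k
  }, best_exp, best_sim)

  list(n_sets = n,
       n_concordant = n_r,
       n_discordant = n - n_r,
       pct_concordant = 100 * n_r / n,
       rule_based = list(k = k,
                         n_evaluable = sum(evaluable),
                         n_concordant = sum(agree[evaluable]),
                         pct_concordant = 100 * sum(agree[evaluable]) /
                           sum(evaluable)))
}

#' Effect of moving the discriminator to the penultimate position
#'
#' Pairs each terminal-discriminator probe set with its `-1` variant and
#' tabulates the change in best HSE enrichment. Pairs whose enrichment
#' improves by more than 10 percentage points at the penultimate position
#' are flagged.
#'
#' @param summary_tab the set summary table, default [hse_set_summary()].
#' @param improve_threshold flag threshold in percentage points.
#' @return data.frame with one row per pair: `set_name`,
#'   `success_terminal`, `success_penultimate`, `delta` (penultimate minus
#'   terminal) and `improved` (`delta > improve_threshold`).
#' @examples
#' s <- mismatch_position_summary()
#' sum(s$improved)   # 3 pairs improve by > 10 points
#' @export
mismatch_position_summary <- function(summary_tab = hse_set_summary(),
                                      improve_threshold = 10) {
  is_pen <- grepl("-1$", summary_tab$set_name)
  base <- sub("-1$", "", summary_tab$set_name[is_pen])
  missing <- setdiff(base, summary_tab$set_name[!is_pen])
  if (length(missing)) {
    stop("penultimate design(s) without a terminal partner: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  idx_t <- match(base, summary_tab$set_name)
  idx_p <- which(is_pen)
  out <- data.frame(
    set_name = base,
    success_terminal = summary_tab$success_pct[idx_t],
    success_penultimate = summary_tab$success_pct[idx_p]
  )
  out$delta <- out$success_penultimate - out$success_terminal
  out$improved <- out$delta > improve_threshold
  out[order(out$set_name), , drop = FALSE]
}

#' Transcription consistency of the per-length profile table
#'
#' Checks, for every row of [hse_length_profiles()], that the printed
#' `delta_con` equals `con_M - con_MM` to within one unit in the last
#' printed digit (the three columns were rounded independently at the
#' source; a strict equality does not hold in the printed table itself) and
#' compares the printed G/C content against the value recomputed from the
#' sequence. G/C rows that disagree by more than one percentage point are
#' reported as flagged transcription anomalies of the source table -- the
#' 6-mer row of the P224FC profile prints 43% where its sequence gives 33%
#' -- rather than treated as errors in the fixture.
#'
#' @param profiles the profile table, default [hse_length_profiles()].
#' @return invisibly, a list with `delta_con_ok` (logical) and `gc_flagged`
#'   (data.frame of rows whose printed G/C deviates by more than 1 point
#'   from the sequence-derived value). Stops if any `delta_con` row is
#'   inconsistent beyond rounding.
#' @export
check_profile_consistency <- function(profiles = hse_length_profiles()) {
  resid <- abs(profiles$delta_con_1e17 -
                 (profiles$con_m_1e17 - profiles$con_mm_1e17))
  bad <- which(resid > 1)
  if (length(bad)) {
    stop("delta_con inconsistent with con_M - con_MM in rows: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  gc_new <- round(gc_content(profiles$sequence))
  gc_bad <- which(abs(gc_new - profiles$gc_pct) > 1)
  invisible(list(
    delta_con_ok = TRUE,
    gc_flagged = data.frame(
      set_name = profiles$set_name[gc_bad],
      length = profiles$length[gc_bad],
      gc_printed = profiles$gc_pct[gc_bad],
      gc_computed = gc_new[gc_bad]
    )
  ))
}
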