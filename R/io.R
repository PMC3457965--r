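#' Read sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that returns
#' uppercase plain character strings (multi-record files give a named
#' vector), the representation used throughout the package.
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#'
#' @param sequences named character vector of sequences.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a delta-con curve as TSV
#'
#' Concentrations are reported in units of 1e-17 M (the convention of the
#' published per-length profile tables); the column names carry the unit.
#' A `flags` column marks the selected best length, the optimum plateau and
#' a no-discrimination curve.
#'
#' @param curve a [delta_con_curve()] object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_curve_tsv <- function(curve, path) {
  stopifnot(inherits(curve, "delta_con_curve"))
  df <- as.data.frame(curve)
  out <- data.frame(
    set_name = attr(curve, "set_name"),
    length = df$length,
    sequence = df$sequence,
    gc_pct = round(df$gc_pct),
    tm_c = round(df$tm_c, 1),
    dg_kcal = round(df$dg_kcal, 2),
    con_M_1e17 = df$con_m * 1e17,
    con_MM_1e17 = df$con_mm * 1e17,
    delta_con_1e17 = df$delta_con * 1e17
  )
  flags <- character(nrow(df))
  flags[df$length %in% attr(curve, "plateau")] <- "plateau"
  flags[df$length == attr(curve, "best_length")] <- "best"
  if (attr(curve, "no_discrimination")) {
    flags <- paste0(flags, ifelse(nzchar(flags), ";", ""), "no-discrimination")
  }
  out$flags <- flags
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a delta-con TSV
#'
#' @param path path written by [write_curve_tsv()].
#' @return data.frame.
#' @export
read_curve_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Evaluation report over the packaged experimental tables
#'
#' Collects the probe counts, the concordance summary, the separation
#' classification of each probe set's best enrichment and the
#' mismatch-position comparison into one list, optionally writing a
#' human-readable report file.
#'
#' @param path optional output path for a plain-text report.
#' @param k rule-based concordance window (nt), see [concordance_summary()].
#' @return invisibly (or visibly when `path` is `NULL`), a list with
#'   `counts`, `concordance`, `classification` (table of
#'   [classify_separation()] over the per-set best enrichments) and
#'   `mismatch_position`.
#' @export
write_report <- function(path = NULL, k = 1L) {
  counts <- count_probes()
  conc <- concordance_summary(k = k)
  summ <- hse_set_summary()
  cls <- table(classify_separation(summ$success_pct))
  mm <- mismatch_position_summary()
  res <- list(counts = counts, concordance = conc,
              classification = cls, mismatch_position = mm)
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    w <- function(...) writeLines(sprintf(...), con)
    w("HSE probe evaluation report")
    w("===========================")
    w("Probe sets: %d; distinct probes: %d", counts$n_sets, counts$n_probes)
    w("Prediction concordance (printed labels): %d/%d sets (%.0f%%)",
      conc$n_concordant, conc$n_sets, conc$pct_concordant)
    w("Rule-based concordance (+/- %d nt): %d/%d evaluable sets (%.0f%%)",
      conc$rule_based$k, conc$rule_based$n_concordant,
      conc$rule_based$n_evaluable, conc$rule_based$pct_concordant)
    w("Separation of best probes: complete %d, significant %d, none %d",
      cls[["complete"]], cls[["significant"]], cls[["none"]])
    w("")
    w("Penultimate vs terminal discriminator (delta = best enrichment change):")
    utils::write.table(format(mm, digits = 3), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(res))
  }
  res
}

#' Run configuration files
#'
#' A run configuration bundles assay conditions, the probe length range,
#' the curve and screening thresholds, and the random seed into a plain
#' YAML file. Unknown keys are rejected so that typos do not silently fall
#' back to defaults.
#'
#' @param path path to a YAML configuration file.
#' @param config list as returned by `default_run_config()`.
#' @return `read_run_config()`/`default_run_config()`: a named list;
#'   `write_run_config()`: invisibly, `path`.
#' @export
default_run_config <- function() {
  list(
    temperature_c = 64, probe_conc = 5e-6, target_conc = 3e-15,
    monovalent = 0.05, magnesium = 1.5e-3,
    min_length = 9L, max_length = 25L,
    plateau_tol = 0.10, floor_frac = 0.01,
    max_mismatches = 2L, three_prime_anchor_len = 3L, window_kb = 50,
    seed = 1L, out_dir = "."
  )
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(default_run_config())
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(default_run_config(), cfg)
}

#' @rdname default_run_config
#' @export
write_run_config <- function(config, path) {
  known <- names(default_run_config())
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Conditions object from a run configuration
#'
#' @param config a run-configuration list.
#' @return a [duplex_params()] object.
#' @export
config_conditions <- function(config) {
  duplex_params(temperature_c = config$temperature_c,
                probe_conc = config$probe_conc,
                target_conc = config$target_conc,
                monovalent = config$monovalent,
                magnesium = config$magnesium)
}
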