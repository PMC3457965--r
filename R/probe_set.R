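#' Allele-specific extension probe specification
#'
#' One oligonucleotide probe within a probe set (a 5'-truncation length
#' series sharing a locus, orientation, allele and discriminator position).
#' The discriminating base sits at the probe 3' terminus
#' (`discriminator_offset = 0`) or one base inward
#' (`discriminator_offset = 1`, the "-1" designs).
#'
#' @param set_name probe set name, e.g. `"P224FC"`; `"-1"` suffixed names
#'   denote penultimate-discriminator designs.
#' @param sequence probe sequence, 5'->3'.
#' @param orientation `"forward"` or `"reverse"` with respect to the
#'   reference strand of the locus.
#' @param discriminator_offset 0 (3' terminus) or 1 (penultimate).
#' @param mismatch_target_base the target base faced by the discriminator in
#'   the mismatched allele (the second letter of a probe-target mismatch
#'   label such as `"C-A"`).
#' @return an object of class `probe_spec`.
#' @examples
#' probe_spec("P224FC", "TCAGAAATGAGTGTGACATCTTC",
#'            mismatch_target_base = "A")
#' @export
probe_spec <- function(set_name, sequence, orientation = "forward",
                       discriminator_offset = 0L,
                       mismatch_target_base = NULL) {
  sequence <- normalize_dna(sequence, min_len = 6L, what = "probe sequence")
  orientation <- match.arg(orientation, c("forward", "reverse"))
  discriminator_offset <- as.integer(discriminator_offset)
  if (!discriminator_offset %in% c(0L, 1L)) {
    stop("discriminator_offset must be 0 (3' terminus) or 1 (penultimate)",
         call. = FALSE)
  }
  n <- nchar(sequence)
  disc <- substr(sequence, n - discriminator_offset, n - discriminator_offset)
  if (!is.null(mismatch_target_base)) {
    mismatch_target_base <- normalize_dna(mismatch_target_base,
                                          what = "mismatch_target_base")
    if (is_wc_pair(disc, mismatch_target_base)) {
      stop("mismatch_target_base ", mismatch_target_base,
           " is the Watson-Crick partner of the discriminating base ", disc,
           "; it must create a mismatch", call. = FALSE)
    }
  }
  structure(
    list(set_name = set_name, sequence = sequence, orientation = orientation,
         discriminator_offset = discriminator_offset,
         matched_allele = disc, length = n,
         mismatch_target_base = mismatch_target_base),
    class = "probe_spec"
  )
}

#' @export
print.probe_spec <- function(x, ...) {
  cat(sprintf("<probe %s> %d nt %s, discriminator %s at %s\n",
              x$set_name, x$length, x$sequence, x$matched_allele,
              if (x$discriminator_offset == 0) "3' terminus" else "-1 position"))
  invisible(x)
}

#' Enumerate a 5'-trimmed probe-length series at a SNP locus
#'
#' Builds the probe set for one design variant: orientation, discriminator
#' position and a range of lengths, each probe obtained from the longest by
#' stepwise 5' truncation. Probes end 3' at the SNP
#' (`discriminator_offset = 0`) or one base past it
#' (`discriminator_offset = 1`). Reverse-orientation probes are built on the
#' reverse-complement strand. Coordinates are 1-based positions on the
#' forward reference strand.
#'
#' @param locus_seq reference (forward strand) sequence containing the SNP.
#' @param snp_pos 1-based SNP position within `locus_seq`.
#' @param allele the designed-for SNP allele on the forward strand; the
#'   probe carries this base (forward designs) or its complement (reverse
#'   designs) at the discriminator position.
#' @param orientation `"forward"` or `"reverse"`.
#' @param discriminator_offset 0 or 1, see [probe_spec()].
#' @param lengths integer vector of probe lengths (6-40 nt).
#' @param other_allele optional second SNP allele on the forward strand,
#'   used to annotate each probe with its mismatch target base.
#' @param set_name name for the probe set.
#' @return list of [probe_spec()] objects, ordered as `lengths`.
#' @export
enumerate_probes <- function(locus_seq, snp_pos, allele,
                             orientation = c("forward", "reverse"),
                             discriminator_offset = 0L,
                             lengths,
                             other_allele = NULL,
                             set_name = "probe") {
  locus_seq <- normalize_dna(locus_seq, min_len = 6L, what = "locus_seq")
  orientation <- match.arg(orientation)
  allele <- normalize_dna(allele, what = "allele")
  discriminator_offset <- as.integer(discriminator_offset)
  lengths <- sort(unique(as.integer(lengths)))
  if (any(lengths < 6L | lengths > 40L)) {
    stop("probe lengths must lie in [6, 40]", call. = FALSE)
  }
  n <- nchar(locus_seq)
  if (snp_pos < 1L || snp_pos > n) stop("snp_pos outside locus_seq", call. = FALSE)

  # forward-strand window of the longest design, discriminator included
  lmax <- max(lengths)
  if (orientation == "forward") {
    # probe = forward strand, 3' end at snp_pos (+ offset bases past it)
    start <- snp_pos - lmax + 1L + discriminator_offset
    end <- snp_pos + discriminator_offset
    if (start < 1L || end > n) {
      stop("SNP too close to the sequence end for a ", lmax, " nt probe",
           call. = FALSE)
    }
    full <- substr(locus_seq, start, end)
    disc_idx <- lmax - discriminator_offset
    substr(full, disc_idx, disc_idx) <- allele
  } else {
    # probe = reverse-complement strand, 3' end at snp_pos (- offset)
    start <- snp_pos - discriminator_offset
    end <- snp_pos + lmax - 1L - discriminator_offset
    if (start < 1L || end > n) {
      stop("SNP too close to the sequence end for a ", lmax, " nt probe",
           call. = FALSE)
    }
    full <- reverse_complement(substr(locus_seq, start, end))
    disc_idx <- lmax - discriminator_offset
    substr(full, disc_idx, disc_idx) <- complement_seq(allele)
  }

  mm_base <- NULL
  if (!is.null(other_allele)) {
    other_allele <- normalize_dna(other_allele, what = "other_allele")
    if (other_allele == allele) {
      stop("other_allele must differ from the design allele", call. = FALSE)
    }
    # the template strand base of the other allele: forward probes anneal to
    # the reverse strand, reverse probes to the forward strand
    mm_base <- if (orientation == "forward") complement_seq(other_allele) else other_allele
  }

  lapply(lengths, function(l) {
    probe_spec(set_name, substr(full, lmax - l + 1L, lmax),
               orientation = orientation,
               discriminator_offset = discriminator_offset,
               mismatch_target_base = mm_base)
  })
}

#' Build a probe-length series directly from a full-length probe sequence
#'
#' Probe sets are 5'-truncation series, so the whole series is determined by
#' its longest member. This constructor builds the series from a designed
#' full-length probe (e.g. a row of a published probe table) without needing
#' the locus sequence.
#'
#' @param sequence the full-length probe, 5'->3'.
#' @param lengths lengths to generate (each `<= nchar(sequence)`).
#' @param mismatch the probe-target mismatch label, e.g. `"C-A"` meaning
#'   probe base C faces target base A in the mismatched allele; the probe
#'   base must equal the discriminating base of `sequence`.
#' @inheritParams probe_spec
#' @return list of [probe_spec()] objects, shortest first.
#' @examples
#' probe_series("TCAGAAATGAGTGTGACATCTTC", lengths = c(19, 23),
#'              mismatch = "C-A", set_name = "P224FC")
#' @export
probe_series <- function(sequence, lengths, mismatch,
                         discriminator_offset = 0L,
                         orientation = "forward",
                         set_name = "probe") {
  sequence <- normalize_dna(sequence, min_len = 6L, what = "sequence")
  lengths <- sort(unique(as.integer(lengths)))
  if (any(lengths > nchar(sequence))) {
    stop("requested length exceeds the full-length design", call. = FALSE)
  }
  parts <- strsplit(mismatch, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop("mismatch must be of the form '<probe base>-<target base>'",
         call. = FALSE)
  }
  n <- nchar(sequence)
  disc <- substr(sequence, n - discriminator_offset, n - discriminator_offset)
  if (parts[1] != disc) {
    warning("mismatch label ", mismatch, " names probe base ", parts[1],
            " but the discriminating base of the sequence is ", disc,
            call. = FALSE)
  }
  lapply(lengths, function(l) {
    probe_spec(set_name, substr(sequence, n - l + 1L, n),
               orientation = orientation,
               discriminator_offset = discriminator_offset,
               mismatch_target_base = parts[2])
  })
}

#' Target site of the mismatched allele for one probe
#'
#' Returns the target strand faced by the probe under the mismatched allele:
#' identical to the perfect complement of the probe except at the
#' discriminator position, where the target carries
#' `probe$mismatch_target_base`. The string is written 3'->5', aligned
#' base-for-base with the probe, ready for [duplex_energy()].
#'
#' @param probe a [probe_spec()] with a `mismatch_target_base`.
#' @param other_allele optional override of the mismatching target base.
#' @return target site string, 3'->5'.
#' @export
build_mismatch_target <- function(probe, other_allele = NULL) {
  stopifnot(inherits(probe, "probe_spec"))
  base <- if (!is.null(other_allele)) {
    normalize_dna(other_allele, what = "other_allele")
  } else {
    probe$mismatch_target_base
  }
  if (is.null(base)) {
    stop("probe has no mismatch_target_base and none was supplied",
         call. = FALSE)
  }
  if (is_wc_pair(probe$matched_allele, base)) {
    stop("base ", base, " matches the discriminating base ",
         probe$matched_allele, "; no mismatch to build", call. = FALSE)
  }
  target <- complement_seq(probe$sequence)
  pos <- probe$length - probe$discriminator_offset
  substr(target, pos, pos) <- base
  target
}

#' Match-minus-mismatch duplex concentration curve for a probe set
#'
#' For every probe length in a 5'-trimmed series, simulates the equilibrium
#' duplex concentration of the probe against its matched target (`con_M`)
#' and against the single-mismatch target (`con_MM`) at the assay
#' conditions, and tabulates the difference `delta_con = con_M - con_MM` --
#' the predictor of allele-specific extension success. The optimal probe
#' length is the maximum of the delta-con curve; near-ties within
#' `plateau_tol` of the maximum are reported as a plateau.
#'
#' @param probes list of [probe_spec()] objects from one set (at least 3
#'   lengths), each carrying a `mismatch_target_base`.
#' @param params an [nn_params()] parameter set.
#' @param conditions a [duplex_params()] object.
#' @param plateau_tol fractional tolerance defining the optimum plateau
#'   (lengths with `delta_con >= (1 - plateau_tol) * max`).
#' @param floor_frac no-discrimination floor: when the maximum `delta_con`
#'   is below `floor_frac * target_conc` the curve is flagged as giving no
#'   confident optimum.
#' @return an object of class `delta_con_curve`: a data.frame with columns
#'   `length`, `sequence`, `gc_pct`, `tm_c`, `dg_kcal`, `con_m`, `con_mm`,
#'   `delta_con` (concentrations in mol/L), plus attributes `set_name`,
#'   `best_length`, `plateau`, `no_discrimination` and `conditions`.
#' @examples
#' pr <- probe_series("TCAGAAATGAGTGTGACATCTTC", 15:23, "C-A",
#'                    set_name = "P224FC")
#' delta_con_curve(pr)
#' @export
delta_con_curve <- function(probes, params = nn_params(),
                            conditions = duplex_params(),
                            plateau_tol = 0.10, floor_frac = 0.01) {
  if (length(probes) < 3L) {
    stop("a delta-con curve needs at least 3 probe lengths", call. = FALSE)
  }
  sets <- unique(vapply(probes, `[[`, character(1), "set_name"))
  if (length(sets) != 1L) {
    stop("all probes must come from one set; got: ",
         paste(sets, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(probes, function(p) {
    res <- tryCatch({
      m <- duplex_thermo(p$sequence, params = params, conditions = conditions)
      mm <- duplex_thermo(p$sequence, build_mismatch_target(p),
                          params = params, conditions = conditions)
      list(m = m, mm = mm)
    }, error = function(e) {
      stop("length ", p$length, ": ", conditionMessage(e), call. = FALSE)
    })
    data.frame(length = p$length, sequence = p$sequence,
               gc_pct = gc_content(p$sequence),
               tm_c = res$m$tm_c, dg_kcal = res$m$dg_at_t,
               con_m = res$m$duplex_conc, con_mm = res$mm$duplex_conc,
               delta_con = res$m$duplex_conc - res$mm$duplex_conc)
  })
  curve <- do.call(rbind, rows)
  curve <- curve[order(curve$length), , drop = FALSE]
  rownames(curve) <- NULL

  sel <- select_optimum(curve$length, curve$delta_con,
                        plateau_tol = plateau_tol,
                        floor = floor_frac * conditions$target_conc)
  best <- sel$best_length
  plateau <- sel$plateau
  no_disc <- sel$no_discrimination
  structure(curve,
            class = c("delta_con_curve", "data.frame"),
            set_name = sets, best_length = best,
            plateau = plateau, no_discrimination = no_disc,
            plateau_tol = plateau_tol, conditions = conditions)
}

#' @export
print.delta_con_curve <- function(x, ...) {
  cat("Delta-con curve for probe set", attr(x, "set_name"), "\n")
  df <- as.data.frame(x)
  df$con_m <- df$con_m * 1e17
  df$con_mm <- df$con_mm * 1e17
  df$delta_con <- df$delta_con * 1e17
  names(df)[names(df) %in% c("con_m", "con_mm", "delta_con")] <-
    c("con_M_1e17", "con_MM_1e17", "delta_con_1e17")
  print.data.frame(df, digits = 3, row.names = FALSE)
  if (attr(x, "no_discrimination")) {
    cat("No confident optimum: maximum delta-con is below the discrimination floor\n")
  } else {
    cat(sprintf("Best length: %d nt (plateau: %s)\n", attr(x, "best_length"),
                paste(attr(x, "plateau"), collapse = ", ")))
  }
  invisible(x)
}

#' Optimum selection rule for a delta-con curve
#'
#' The optimal probe length is the argmax of `delta_con`; exact ties are
#' broken toward the shorter probe (shorter probes are preferred until
#' non-specific binding dominates, and a deterministic rule is required).
#' Lengths whose `delta_con` lies within `plateau_tol` of the maximum form
#' the reported plateau. A curve whose maximum falls below `floor` carries
#' no usable discrimination signal and is flagged.
#'
#' @param lengths integer vector of probe lengths.
#' @param delta_con numeric vector of match-minus-mismatch duplex
#'   concentrations (mol/L), parallel to `lengths`.
#' @param plateau_tol fractional plateau tolerance.
#' @param floor absolute no-discrimination floor (mol/L).
#' @return list with `best_length`, `plateau` and `no_discrimination`.
#' @export
select_optimum <- function(lengths, delta_con, plateau_tol = 0.10,
                           floor = 0) {
  stopifnot(length(lengths) == length(delta_con), length(lengths) > 0L)
  ord <- order(lengths)
  lengths <- lengths[ord]
  delta_con <- delta_con[ord]
  dmax <- max(delta_con)
  list(
    best_length = lengths[which.max(delta_con)],  # first index = shortest
    plateau = lengths[dmax > 0 & delta_con >= (1 - plateau_tol) * dmax],
    no_discrimination = dmax < floor
  )
}

#' Optimal probe length from a delta-con curve
#'
#' Returns the argmax of the delta-con curve, with ties broken toward the
#' shorter probe, the plateau of near-optimal lengths, and a note flagging
#' curves whose maximum is below the discrimination floor.
#'
#' @param curve a [delta_con_curve()] object.
#' @return list with `best_length`, `plateau` and `note` (`"ok"` or
#'   `"no-discrimination"`).
#' @export
predict_best_length <- function(curve) {
  stopifnot(inherits(curve, "delta_con_curve"))
  list(best_length = attr(curve, "best_length"),
       plateau = attr(curve, "plateau"),
       note = if (attr(curve, "no_discrimination")) "no-discrimination" else "ok")
}

#' Linear model of optimal probe length on G/C content
#'
#' Ordinary least-squares fit of optimal probe length (nt) as a function of
#' probe G/C content (%). Across probe sets the optimum shifts to shorter
#' probes as G/C rises, so a negative slope is expected; a non-negative
#' fitted slope triggers a warning.
#'
#' @param gc_percent numeric vector of G/C contents (%).
#' @param optimal_length numeric vector of optimal probe lengths (nt).
#' @param source optional character vector labelling each point
#'   (`"simulated"` / `"experimental"`).
#' @return an object of class `gc_length_model` wrapping the [stats::lm()]
#'   fit, with the training points and residuals stored.
#' @export
fit_gc_length_model <- function(gc_percent, optimal_length, source = NULL) {
  if (length(gc_percent) != length(optimal_length)) {
    stop("gc_percent and optimal_length must have equal length", call. = FALSE)
  }
  if (length(unique(gc_percent)) < 3L) {
    stop("need at least 3 points with distinct G/C content", call. = FALSE)
  }
  d <- data.frame(gc = as.numeric(gc_percent), len = as.numeric(optimal_length))
  fit <- stats::lm(len ~ gc, data = d)
  slope <- unname(stats::coef(fit)[["gc"]])
  if (slope >= 0) {
    warning("fitted slope is non-negative; expected shorter optima at ",
            "higher G/C content", call. = FALSE)
  }
  structure(
    list(fit = fit, slope = slope,
         intercept = unname(stats::coef(fit)[["(Intercept)"]]),
         points = cbind(d, source = if (is.null(source)) NA_character_ else source,
                        residual = unname(stats::residuals(fit)))),
    class = "gc_length_model"
  )
}

#' @export
print.gc_length_model <- function(x, ...) {
  cat(sprintf("G/C-content vs optimal-length model: length = %.3f %+.4f * GC%%  (n = %d, RMS residual %.2f nt)\n",
              x$intercept, x$slope, nrow(x$points),
              sqrt(mean(x$points$residual^2))))
  invisible(x)
}

#' Predict optimal probe length from G/C content
#'
#' @param object a [fit_gc_length_model()] object.
#' @param gc_percent G/C contents (%) to predict for.
#' @param ... unused.
#' @return integer vector of predicted probe lengths (nearest nt).
#' @export
predict.gc_length_model <- function(object, gc_percent, ...) {
  as.integer(round(stats::predict(object$fit,
                                  newdata = data.frame(gc = gc_percent))))
}
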