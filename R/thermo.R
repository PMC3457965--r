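# Gas constant in cal/(mol K).
GAS_CONSTANT <- 1.987

#' Assay conditions for duplex simulation
#'
#' Container for the hybridization conditions under which duplex formation
#' is simulated. Defaults reflect a haplotype-specific extraction assay:
#' hybridization at 64 degrees C, probe at 5 uM in vast excess over a
#' genomic target at 3 fM per allele (roughly 300-500 ng genomic DNA split
#' between two contributors in a 30 ul reaction), 50 mM monovalent salt and
#' 1.5 mM free Mg2+.
#'
#' @param temperature_c assay temperature, degrees C (0-100).
#' @param probe_conc total probe strand concentration, mol/L.
#' @param target_conc total target strand concentration per allele, mol/L.
#' @param monovalent monovalent cation (Na+ equivalent) concentration, mol/L.
#' @param magnesium free Mg2+ concentration, mol/L.
#' @return an object of class `duplex_params`.
#' @examples
#' duplex_params()
#' duplex_params(temperature_c = 58)
#' @export
duplex_params <- function(temperature_c = 64, probe_conc = 5e-6,
                          target_conc = 3e-15, monovalent = 0.05,
                          magnesium = 1.5e-3) {
  if (!is.numeric(temperature_c) || temperature_c < 0 || temperature_c > 100) {
    stop("temperature_c must be between 0 and 100 degrees C", call. = FALSE)
  }
  if (probe_conc <= 0 || target_conc <= 0) {
    stop("strand concentrations must be positive", call. = FALSE)
  }
  if (monovalent <= 0) stop("monovalent salt must be positive", call. = FALSE)
  if (magnesium < 0) stop("magnesium must be non-negative", call. = FALSE)
  if (probe_conc < target_conc) {
    message("note: probe_conc < target_conc; the assay regime modelled here ",
            "has probe in vast excess over target")
  }
  structure(
    list(temperature_c = temperature_c, probe_conc = probe_conc,
         target_conc = target_conc, monovalent = monovalent,
         magnesium = magnesium),
    class = "duplex_params"
  )
}

#' @export
print.duplex_params <- function(x, ...) {
  cat(sprintf(
    "Duplex assay conditions: %g C, probe %g M, target %g M, [Mon+] %g M, [Mg2+] %g M\n",
    x$temperature_c, x$probe_conc, x$target_conc, x$monovalent, x$magnesium))
  invisible(x)
}

#' Nearest-neighbor enthalpy and entropy of a DNA duplex
#'
#' Sums doublet stack contributions plus duplex-initiation terms for a
#' probe/target duplex that is either perfectly matched or carries exactly
#' one mismatch at the probe 3' terminus or at the penultimate (-1)
#' position -- the two geometries used in allele-specific extension probe
#' design. Arbitrary internal mismatches are rejected rather than
#' mis-parameterized.
#'
#' Accounting convention: initiation terms (A/T or G/C) are keyed by the
#' probe's terminal bases; a 3'-terminal mismatch replaces the final stack
#' with a terminal-mismatch doublet; a penultimate mismatch replaces its two
#' flanking stacks with internal-mismatch doublets. This mirrors the widely
#' used accounting of the Biopython `Tm_NN` implementation of the same
#' published tables, so results are cross-checkable.
#'
#' @param probe_seq probe sequence, 5'->3'.
#' @param target_site opposing target strand, written 3'->5' so that
#'   position i of the target faces position i of the probe. Defaults to
#'   the perfect complement.
#' @param params an [nn_params()] parameter set.
#' @return list with `dh` (kcal/mol), `ds` (cal/(mol K)), `n_mismatch`, and
#'   `pairing_kind` (`"match"`, `"terminal_mismatch"` or
#'   `"internal_mismatch_penultimate"`).
#' @examples
#' duplex_energy("AAATGAGTGTGACATCTTC")
#' @export
duplex_energy <- function(probe_seq, target_site = NULL, params = nn_params()) {
  probe_seq <- normalize_dna(probe_seq, min_len = 2L, what = "probe_seq")
  if (is.null(target_site)) target_site <- complement_seq(probe_seq)
  target_site <- normalize_dna(target_site, min_len = 2L, what = "target_site")
  n <- nchar(probe_seq)
  if (nchar(target_site) != n) {
    stop("probe_seq and target_site must have equal length", call. = FALSE)
  }
  pb <- strsplit(probe_seq, "")[[1]]
  tb <- strsplit(target_site, "")[[1]]
  mm <- which(!is_wc_pair(pb, tb))
  if (length(mm) > 1L) {
    stop("more than one mismatch (positions ",
         paste(mm, collapse = ", "), "); only a single 3'-terminal or ",
         "penultimate mismatch is modelled", call. = FALSE)
  }
  kind <- "match"
  if (length(mm) == 1L) {
    if (mm == n) {
      kind <- "terminal_mismatch"
    } else if (mm == n - 1L) {
      kind <- "internal_mismatch_penultimate"
    } else {
      stop("mismatch at position ", mm, " of ", n, " is unsupported; only ",
           "the 3' terminus or the penultimate position is modelled",
           call. = FALSE)
    }
  }

  # initiation, keyed by the probe's terminal bases
  ends <- c(pb[1], pb[n])
  n_at <- sum(ends %in% c("A", "T"))
  dh <- n_at * params$init_at[["dh"]] + (2 - n_at) * params$init_gc[["dh"]]
  ds <- n_at * params$init_at[["ds"]] + (2 - n_at) * params$init_gc[["ds"]]

  for (i in seq_len(n - 1L)) {
    tab <- "wc"
    if (kind == "terminal_mismatch" && i == n - 1L) tab <- "terminal_mm"
    if (kind == "internal_mismatch_penultimate" && i >= n - 2L) tab <- "internal_mm"
    v <- stack_params(params,
                      paste0(pb[i], pb[i + 1L]),
                      paste0(tb[i], tb[i + 1L]),
                      kind = switch(tab, wc = "wc",
                                    terminal_mm = "terminal_mm",
                                    internal_mm = "internal_mm"))
    dh <- dh + v[["dh"]]
    ds <- ds + v[["ds"]]
  }
  list(dh = dh, ds = ds, n_mismatch = length(mm), pairing_kind = kind)
}

#' Sodium-equivalent monovalent concentration
#'
#' Folds divalent magnesium into an equivalent monovalent concentration
#' using the empirical relation of von Ahsen et al. (2001):
#' `[Mon+]eq = [Mon+] + 120 * sqrt([Mg2+] in mM)` (in mM).
#'
#' @param monovalent monovalent cation concentration, mol/L.
#' @param magnesium free Mg2+ concentration, mol/L.
#' @return equivalent monovalent concentration, mol/L.
#' @export
na_equivalent <- function(monovalent, magnesium = 0) {
  if (monovalent <= 0) stop("monovalent salt must be positive", call. = FALSE)
  monovalent + 120 * sqrt(magnesium * 1e3) * 1e-3
}

#' Salt-corrected duplex entropy
#'
#' Applies the entropic salt correction of SantaLucia (1998),
#' `dS[Mon+] = dS(1 M) + 0.368 * (N - 1) * ln [Mon+]`, where `N` is the
#' duplex length in base pairs (so `N - 1` counts phosphate linkages per
#' strand) and `[Mon+]` is the sodium-equivalent concentration from
#' [na_equivalent()]. At the 1 M Na+ / 0 Mg reference condition the
#' correction is the identity.
#'
#' @param delta_s uncorrected entropy, cal/(mol K).
#' @param n_bases duplex length in base pairs.
#' @param params a [duplex_params()] object supplying the ionic conditions.
#' @return corrected entropy, cal/(mol K).
#' @export
salt_corrected_entropy <- function(delta_s, n_bases, params = duplex_params()) {
  mon <- na_equivalent(params$monovalent, params$magnesium)
  delta_s + 0.368 * (n_bases - 1) * log(mon)
}

#' Concentration-dependent melting temperature
#'
#' Two-state melting temperature of a non-self-complementary (hetero)
#' duplex, `Tm = 1000*dH / (dS + R ln(CT/4)) - 273.15`, with
#' `CT = probe_conc + target_conc`. The `CT/4` term is the standard
#' convention for a hetero-duplex formed from two distinct strands; it is
#' retained in the probe-excess regime so that results are reproducible
#' bit-for-bit under one stated convention.
#'
#' @param dh duplex enthalpy, kcal/mol.
#' @param ds salt-corrected duplex entropy, cal/(mol K).
#' @param probe_conc,target_conc strand concentrations, mol/L.
#' @return melting temperature in degrees C, or `NA` (with a warning
#'   identifying the duplex as having no two-state melting transition) when
#'   the denominator is non-negative.
#' @export
melting_temperature <- function(dh, ds, probe_conc, target_conc) {
  if (probe_conc <= 0 || target_conc <= 0) {
    stop("strand concentrations must be positive", call. = FALSE)
  }
  ct <- probe_conc + target_conc
  denom <- ds + GAS_CONSTANT * log(ct / 4)
  if (denom >= 0 || dh >= 0) {
    warning("no two-state melting temperature for this duplex", call. = FALSE)
    return(NA_real_)
  }
  1000 * dh / denom - 273.15
}

#' Equilibrium duplex concentration of a two-state hybridization
#'
#' Solves the mass-action equilibrium `P + T <-> PT` with
#' `K = exp(-1000 * dG / (R T))` for the duplex concentration:
#' the physically meaningful (smaller) root of
#' `K x^2 - (1 + K (P0 + T0)) x + K P0 T0 = 0`, evaluated in the
#' cancellation-free form `x = 2c / (b + sqrt(b^2 - 4 K c))`. The result is
#' guaranteed to lie in `[0, min(P0, T0)]` across the full range of binding
#' constants.
#'
#' @param dg free energy of duplex formation at the assay temperature,
#'   kcal/mol.
#' @param probe_conc,target_conc total strand concentrations, mol/L.
#' @param temperature_c assay temperature, degrees C.
#' @return duplex concentration, mol/L.
#' @export
duplex_concentration <- function(dg, probe_conc, target_conc, temperature_c) {
  if (probe_conc <= 0 || target_conc <= 0) {
    stop("strand concentrations must be positive", call. = FALSE)
  }
  tk <- temperature_c + 273.15
  # cap the exponent: beyond ~e^345 the bound root is saturated to within
  # double precision anyway, and K^2 must stay finite
  ex <- min(-1000 * dg / (GAS_CONSTANT * tk), 345)
  k <- exp(ex)
  duplex_conc_from_k(k, probe_conc, target_conc)
}

# Quadratic two-state solver parameterized directly by K (1/M).
duplex_conc_from_k <- function(k, p0, t0) {
  b <- 1 + k * (p0 + t0)
  c0 <- k * p0 * t0
  disc <- b * b - 4 * k * c0
  x <- 2 * c0 / (b + sqrt(disc))
  min(max(x, 0), min(p0, t0))
}

#' Full thermodynamic characterization of one probe-target pairing
#'
#' Convenience wrapper combining [duplex_energy()],
#' [salt_corrected_entropy()], [melting_temperature()] and
#' [duplex_concentration()] into one result.
#'
#' @inheritParams duplex_energy
#' @param conditions a [duplex_params()] object.
#' @return an object of class `thermo_result`: list with `dh`, `ds`
#'   (salt-corrected), `dg_at_t` (kcal/mol at the assay temperature),
#'   `tm_c`, `duplex_conc` (mol/L) and `pairing_kind`.
#' @examples
#' duplex_thermo("AAATGAGTGTGACATCTTC", conditions = duplex_params())
#' @export
duplex_thermo <- function(probe_seq, target_site = NULL,
                          params = nn_params(),
                          conditions = duplex_params()) {
  e <- duplex_energy(probe_seq, target_site, params)
  ds_c <- salt_corrected_entropy(e$ds, nchar(probe_seq), conditions)
  tk <- conditions$temperature_c + 273.15
  dg <- e$dh - tk * ds_c / 1000
  tm <- suppressWarnings(
    melting_temperature(e$dh, ds_c, conditions$probe_conc,
                        conditions$target_conc))
  conc <- duplex_concentration(dg, conditions$probe_conc,
                               conditions$target_conc,
                               conditions$temperature_c)
  structure(
    list(dh = e$dh, ds = ds_c, dg_at_t = dg, tm_c = tm,
         duplex_conc = conc, pairing_kind = e$pairing_kind),
    class = "thermo_result"
  )
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf(
    "Duplex (%s): dH %.1f kcal/mol, dS %.1f cal/(mol K), dG(T) %.2f kcal/mol, Tm %.1f C, [PT] %.3g M\n",
    x$pairing_kind, x$dh, x$ds, x$dg_at_t,
    if (is.na(x$tm_c)) NaN else x$tm_c, x$duplex_conc))
  invisible(x)
}

#' Simulated melting curve of one probe-target duplex
#'
#' Equilibrium duplex concentration as a function of temperature on an
#' ascending temperature grid. Under the two-state model the curve is
#' monotone non-increasing in temperature, saturating towards
#' `min(P0, T0)` at low temperature and towards zero at high temperature.
#'
#' @inheritParams duplex_thermo
#' @param t_range ascending numeric vector of temperatures, degrees C.
#' @return data.frame with columns `temperature_c` and `duplex_conc`.
#' @export
melting_curve <- function(probe_seq, target_site = NULL,
                          params = nn_params(),
                          conditions = duplex_params(),
                          t_range = seq(0, 100, by = 1)) {
  if (length(t_range) == 0L) stop("t_range must be non-empty", call. = FALSE)
  if (is.unsorted(t_range, strictly = TRUE)) {
    stop("t_range must be strictly ascending", call. = FALSE)
  }
  e <- duplex_energy(probe_seq, target_site, params)
  ds_c <- salt_corrected_entropy(e$ds, nchar(probe_seq), conditions)
  conc <- vapply(t_range, function(tc) {
    dg <- e$dh - (tc + 273.15) * ds_c / 1000
    duplex_concentration(dg, conditions$probe_conc, conditions$target_conc, tc)
  }, numeric(1))
  data.frame(temperature_c = t_range, duplex_conc = conc)
}
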