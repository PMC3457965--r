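#' Generate a synthetic SNP locus with planted off-target sites
#'
#' Builds a random background sequence of controlled G/C composition,
#' places a biallelic SNP centrally (or at a requested position), and
#' optionally plants degenerate copies of the probe binding site elsewhere
#' in the sequence. The planted copies carry a chosen number of internal
#' mismatches and either an intact or a broken 3'-terminal base, so that a
#' specificity screen has known ground truth to recover. It stands in for
#' real flanking sequence, which is locus-specific and not distributed with
#' the package.
#'
#' The generator uses its own RNG stream: the caller's `.Random.seed` is
#' left untouched, and regenerating with the same seed is byte-identical.
#'
#' @param length total sequence length (>= 2x `probe_length`).
#' @param gc_target background G/C fraction in (0, 1).
#' @param snp_pos SNP position (1-based); default the central base.
#' @param alleles two distinct bases, reference first.
#' @param n_offtargets number of planted off-target copies of the probe
#'   site.
#' @param probe_length length of the (forward, 3'-terminal discriminator)
#'   probe site ending at the SNP whose copies are planted.
#' @param offtarget_mismatches internal mismatches introduced into each
#'   planted copy (outside the 3' anchor).
#' @param offtarget_3p_intact logical; keep the 3'-terminal base of each
#'   planted copy intact (extendable) or alter it.
#' @param anchor_len 3'-anchor width kept mismatch-free when
#'   `offtarget_3p_intact` is `TRUE`.
#' @param seed integer seed; required for reproducibility.
#' @return an object of class `synthetic_locus`: list with `sequence`,
#'   `snp_pos`, `alleles`, `planted` (data.frame: `start`, `end`,
#'   `three_prime_pos`, `mismatch_count`, `three_prime_intact`) and `seed`.
#' @examples
#' loc <- generate_locus(length = 4000, gc_target = 0.5, seed = 1,
#'                       n_offtargets = 2)
#' loc$planted
#' @export
generate_locus <- function(length = 10000L, gc_target = 0.5,
                           snp_pos = NULL, alleles = c("C", "T"),
                           n_offtargets = 0L, probe_length = 20L,
                           offtarget_mismatches = 2L,
                           offtarget_3p_intact = TRUE,
                           anchor_len = 3L,
                           seed = 1L) {
  length <- as.integer(length)
  if (gc_target <= 0 || gc_target >= 1) {
    stop("gc_target must lie strictly in (0, 1)", call. = FALSE)
  }
  if (length < 2L * probe_length) {
    stop("locus length must be at least twice the probe length", call. = FALSE)
  }
  alleles <- toupper(alleles)
  if (base::length(alleles) != 2L || alleles[1] == alleles[2] ||
      any(!alleles %in% c("A", "C", "G", "T"))) {
    stop("alleles must be two distinct bases", call. = FALSE)
  }
  if (is.null(snp_pos)) snp_pos <- length %/% 2L
  snp_pos <- as.integer(snp_pos)
  if (snp_pos < probe_length || snp_pos > length - probe_length) {
    stop("snp_pos leaves no room for the probe site", call. = FALSE)
  }

  run_with_seed(seed, {
    base_p <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
                G = gc_target / 2, T = (1 - gc_target) / 2)
    chars <- sample(names(base_p), length, replace = TRUE, prob = base_p)
    chars[snp_pos] <- alleles[1]

    site_start <- snp_pos - probe_length + 1L
    site <- chars[site_start:snp_pos]

    planted <- data.frame(start = integer(), end = integer(),
                          three_prime_pos = integer(),
                          mismatch_count = integer(),
                          three_prime_intact = logical())
    if (n_offtargets > 0L) {
      occupied <- list(c(site_start, snp_pos))
      free_start <- function(cand) {
        all(vapply(occupied, function(iv) {
          cand + probe_length - 1L < iv[1] - 5L || cand > iv[2] + 5L
        }, logical(1)))
      }
      candidates <- sample.int(length - probe_length + 1L)
      placed <- 0L
      for (cand in candidates) {
        if (placed == n_offtargets) break
        if (!free_start(cand)) next
        copy <- site
        protect <- if (offtarget_3p_intact) {
          seq.int(probe_length - anchor_len + 1L, probe_length)
        } else integer()
        mutable <- setdiff(seq_len(probe_length - 1L), protect)
        mm_pos <- sample(mutable, offtarget_mismatches)
        for (p in mm_pos) {
          copy[p] <- sample(setdiff(c("A", "C", "G", "T"), copy[p]), 1L)
        }
        if (!offtarget_3p_intact) {
          copy[probe_length] <- sample(setdiff(c("A", "C", "G", "T"),
                                               copy[probe_length]), 1L)
        }
        chars[cand:(cand + probe_length - 1L)] <- copy
        occupied <- c(occupied, list(c(cand, cand + probe_length - 1L)))
        planted <- rbind(planted, data.frame(
          start = cand, end = cand + probe_length - 1L,
          three_prime_pos = cand + probe_length - 1L,
          mismatch_count = as.integer(offtarget_mismatches +
                                        !offtarget_3p_intact),
          three_prime_intact = offtarget_3p_intact))
        placed <- placed + 1L
      }
      if (placed < n_offtargets) {
        stop("could not place ", n_offtargets,
             " non-overlapping off-target copies", call. = FALSE)
      }
      planted <- planted[order(planted$start), , drop = FALSE]
      rownames(planted) <- NULL
    }

    structure(
      list(sequence = paste(chars, collapse = ""), snp_pos = snp_pos,
           alleles = alleles, probe_length = as.integer(probe_length),
           planted = planted, seed = as.integer(seed)),
      class = "synthetic_locus"
    )
  })
}

#' @export
print.synthetic_locus <- function(x, ...) {
  cat(sprintf(
    "Synthetic locus: %d nt, SNP %s/%s at %d, %d planted off-target site(s), seed %d\n",
    nchar(x$sequence), x$alleles[1], x$alleles[2], x$snp_pos,
    nrow(x$planted), x$seed))
  invisible(x)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
run_with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
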