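# Independent equilibrium solver for P + T <-> PT used as the oracle for
# the closed-form quadratic: log-space bisection on the mass-action residual
# f(x) = K (P0 - x)(T0 - x) - x, which is strictly decreasing on
# [0, min(P0, T0)], followed by Newton polishing. No quadratic formula.
iter_duplex_conc <- function(k, p0, t0) {
  upper <- min(p0, t0)
  f <- function(x) k * (p0 - x) * (t0 - x) - x
  lo <- log(upper) - 120
  hi <- log(upper)
  if (f(exp(hi)) >= 0) return(upper)   # saturated beyond fp resolution
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(exp(mid)) > 0) lo <- mid else hi <- mid
  }
  x <- exp((lo + hi) / 2)
  for (i in 1:8) {
    fp <- -k * (p0 + t0 - 2 * x) - 1
    x_new <- x - f(x) / fp
    if (is.finite(x_new) && x_new > 0 && x_new < upper) x <- x_new
  }
  x
}

# Random unambiguous DNA sequence.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A synthetic reference locus embedding the P224 forward design context,
# with the SNP (allele C) at a known position.
p224_locus <- function(flank_left = 150L, flank_right = 150L, seed = 42L) {
  set.seed(seed)
  core <- "TTTCAGAAATGAGTGTGACATCTTC"   # 25-mer context ending at the SNP
  left <- random_dna(flank_left)
  right <- random_dna(flank_right)
  list(sequence = paste0(left, core, right),
       snp_pos = flank_left + nchar(core))
}

# Plateau-tolerant unimodality: the lengths whose delta_con reaches
# (1 - tol) of the maximum must be contiguous, and outside that plateau the
# curve must not rise again above the tolerance band once it has left it.
is_unimodal <- function(lengths, delta_con, tol = 0.10) {
  ord <- order(lengths)
  d <- delta_con[ord]
  dmax <- max(d)
  if (dmax <= 0) return(TRUE)
  in_band <- d >= (1 - tol) * dmax
  idx <- which(in_band)
  all(diff(idx) == 1L)
}
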