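nnp <- nn_params()

test_that("probe enumeration reproduces the catalogued 5'-trim series", {
  loc <- p224_locus()
  pr <- enumerate_probes(loc$sequence, loc$snp_pos, allele = "C",
                         orientation = "forward", lengths = c(19, 23),
                         other_allele = "T", set_name = "P224FC")
  expect_length(pr, 2L)
  expect_identical(pr[[1]]$sequence, "AAATGAGTGTGACATCTTC")
  expect_identical(pr[[2]]$sequence, "TCAGAAATGAGTGTGACATCTTC")
  expect_identical(pr[[1]]$matched_allele, "C")
  expect_identical(pr[[1]]$mismatch_target_base, "A")   # the printed C-A pair
  # successive lengths differ only by 5' truncation
  expect_identical(pr[[1]]$sequence, substr(pr[[2]]$sequence, 5, 23))
})

test_that("reverse-orientation probes are built on the reverse-complement strand", {
  loc <- p224_locus()
  pr <- enumerate_probes(loc$sequence, loc$snp_pos, allele = "C",
                         orientation = "reverse", lengths = 20,
                         other_allele = "T", set_name = "P224RG")[[1]]
  expect_identical(pr$matched_allele, "G")   # complement of forward allele C
  expect_identical(pr$mismatch_target_base, "T")
  win <- substr(loc$sequence, loc$snp_pos, loc$snp_pos + 19)
  expected <- reverse_complement(win)
  substr(expected, 20, 20) <- "G"
  expect_identical(pr$sequence, expected)
})

test_that("penultimate designs place the discriminator one base inward", {
  loc <- p224_locus()
  pr <- enumerate_probes(loc$sequence, loc$snp_pos, allele = "C",
                         orientation = "forward", discriminator_offset = 1L,
                         lengths = 20, other_allele = "T")[[1]]
  expect_identical(substr(pr$sequence, 19, 19), "C")
  # the last base comes from the reference one position past the SNP
  expect_identical(substr(pr$sequence, 20, 20),
                   substr(loc$sequence, loc$snp_pos + 1, loc$snp_pos + 1))
  tgt <- build_mismatch_target(pr)
  expect_identical(substr(tgt, 19, 19), "A")
  expect_identical(duplex_energy(pr$sequence, tgt, nnp)$pairing_kind,
                   "internal_mismatch_penultimate")
})

test_that("enumeration bounds and degenerate inputs are rejected", {
  loc <- p224_locus(flank_left = 10)
  expect_error(enumerate_probes(loc$sequence, loc$snp_pos, "C",
                                lengths = 40), "too close")
  expect_error(enumerate_probes(loc$sequence, loc$snp_pos, "C",
                                lengths = 5), "\\[6, 40\\]")
  expect_error(probe_spec("x", "ACGT"), "at least 6")
  expect_error(probe_spec("x", "ACGTNACGT"), "non-ACGT")
})

test_that("mismatch targets differ from the matched target only at the SNP", {
  pr <- probe_series("CAGGTGATAGATAAGTTGATCG", lengths = 20:22,
                     mismatch = "G-T", set_name = "P30FG")
  p <- pr[[3]]
  tgt <- build_mismatch_target(p)
  matched <- complement_seq(p$sequence)
  diff_pos <- which(strsplit(tgt, "")[[1]] != strsplit(matched, "")[[1]])
  expect_identical(diff_pos, p$length)
  expect_identical(substr(tgt, p$length, p$length), "T")
  # requesting the matched base is an error
  expect_error(build_mismatch_target(p, "C"), "no mismatch")
})

test_that("the P224FC delta-con curve is unimodal with a decline past the optimum", {
  pr <- probe_series("TTTCAGAAATGAGTGTGACATCTTC", lengths = 9:25,
                     mismatch = "C-A", set_name = "P224FC")
  cv <- delta_con_curve(pr, params = nnp)
  expect_s3_class(cv, "delta_con_curve")
  expect_equal(cv$delta_con, cv$con_m - cv$con_mm)
  expect_true(all(cv$con_m >= cv$con_mm))
  expect_true(is_unimodal(cv$length, cv$delta_con))
  best <- attr(cv, "best_length")
  expect_true(best %in% cv$length)
  # the longest probes lose discrimination: both alleles approach saturation
  expect_lt(cv$delta_con[cv$length == 25], max(cv$delta_con))
  # best length agrees with a plain linear scan of the rows
  expect_identical(best, cv$length[which.max(cv$delta_con)])
})

test_that("delta-con curve validates its probe series", {
  pr <- probe_series("TTTCAGAAATGAGTGTGACATCTTC", lengths = 9:11,
                     mismatch = "C-A", set_name = "P224FC")
  expect_error(delta_con_curve(pr[1:2], params = nnp), "at least 3")
  other <- probe_series("CAGGTGATAGATAAGTTGATCG", lengths = 20,
                        mismatch = "G-T", set_name = "P30FG")
  expect_error(delta_con_curve(c(pr, other), params = nnp), "one set")
})

test_that("optimum selection breaks ties short and flags flat curves", {
  sel <- select_optimum(c(17, 18, 19, 20), c(1, 5, 9, 3) * 1e-16)
  expect_identical(sel$best_length, 19)
  # exact tie: shorter length wins, both in the plateau
  sel <- select_optimum(c(19, 20, 21, 22), c(1, 8, 8, 2) * 1e-16)
  expect_identical(sel$best_length, 20)
  expect_identical(sel$plateau, c(20, 21))
  # all-zero curve carries no discrimination signal
  sel <- select_optimum(9:12, rep(0, 4), floor = 3e-17)
  expect_true(sel$no_discrimination)
  # predict_best_length propagates the rule
  pr <- probe_series("TTTCAGAAATGAGTGTGACATCTTC", lengths = 15:22,
                     mismatch = "C-A", set_name = "P224FC")
  cv <- delta_con_curve(pr, params = nnp)
  out <- predict_best_length(cv)
  expect_identical(out$best_length, attr(cv, "best_length"))
  expect_identical(out$note, "ok")
})

test_that("a mismatch as stable as the match yields no confident optimum", {
  # force con_M == con_MM by simulating the 'mismatch' with the matched
  # target: delta_con is identically zero
  pr <- probe_series("TTTCAGAAATGAGTGTGACATCTTC", lengths = 15:20,
                     mismatch = "C-A", set_name = "P224FC")
  cond <- duplex_params()
  rows <- vapply(pr, function(p) {
    duplex_thermo(p$sequence, conditions = cond, params = nnp)$duplex_conc
  }, numeric(1))
  sel <- select_optimum(15:20, rows - rows, floor = 0.01 * cond$target_conc)
  expect_true(sel$no_discrimination)
})

test_that("G/C-length regression recovers exact fits and matches normal equations", {
  gc <- c(30, 40, 50, 60, 70)
  len <- 28 - 0.2 * gc
  m <- fit_gc_length_model(gc, len)
  expect_equal(m$slope, -0.2, tolerance = 1e-12)
  expect_equal(m$intercept, 28, tolerance = 1e-12)
  expect_identical(predict(m, 45), 19L)

  set.seed(3)
  gc <- stats::runif(12, 25, 85)
  len <- 28 - 0.22 * gc + stats::rnorm(12, sd = 1)
  m <- fit_gc_length_model(gc, len)
  # hand-rolled normal equations
  xbar <- mean(gc); ybar <- mean(len)
  slope <- sum((gc - xbar) * (len - ybar)) / sum((gc - xbar)^2)
  expect_equal(m$slope, slope, tolerance = 1e-12)
  expect_equal(m$intercept, ybar - slope * xbar, tolerance = 1e-12)
  expect_equal(m$points$residual, unname(len - (m$intercept + m$slope * gc)),
               tolerance = 1e-12)
  expect_error(fit_gc_length_model(c(40, 40, 40), c(1, 2, 3)), "distinct")
})

test_that("experimental best probes fit the G/C-length line within two nucleotides", {
  pts <- best_probe_points()
  expect_gte(nrow(pts), 11L)
  m <- fit_gc_length_model(pts$gc_pct, pts$best_length,
                           source = "experimental")
  expect_lt(m$slope, 0)
  pred <- predict(m, pts$gc_pct)
  expect_true(all(abs(pred - pts$best_length) <= 2))
})
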