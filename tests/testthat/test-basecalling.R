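test_that("base calls follow the max/sum rule", {
  b <- call_base(c(10, 2, 1, 1))
  expect_identical(b$base, "A")
  expect_equal(b$quality, 10 / 14)
  expect_false(b$ambiguous)

  tie <- call_base(c(1, 1, 1, 1))
  expect_equal(tie$quality, 0.25)
  expect_true(tie$ambiguous)
  expect_identical(tie$base, "A")  # alphabetically first among tied

  zero <- call_base(c(0, 0, 0, 0))
  expect_true(zero$ambiguous)
  expect_equal(zero$quality, 0)

  neg <- call_base(c(-5, 3, 1, 0))   # negatives clipped before the ratio
  expect_identical(neg$base, "C")
  expect_equal(neg$quality, 3 / 4)
})

test_that("quality stays in [0.25, 1] and matches brute force on
           10,000 random signal vectors", {
  set.seed(99)
  sig <- matrix(runif(40000, 0, 100), ncol = 4)
  sig[sample(40000, 2000)] <- 0            # exercise exact zeros
  out <- call_bases(sig)
  expect_true(all(out$quality >= 0.25 - 1e-12 & out$quality <= 1))
  for (i in sample(10000, 500)) {
    o <- oracle_call(sig[i, ])
    expect_identical(out$base[i], o$base)
    expect_equal(out$quality[i], o$quality)
    expect_identical(out$ambiguous[i], o$ambiguous)
  }
  # quality 1 iff single nonzero channel; 0.25 iff all equal
  expect_equal(call_base(c(0, 7, 0, 0))$quality, 1)
  expect_equal(call_base(c(3, 3, 3, 3))$quality, 0.25)
})

test_that("read assembly applies the quality threshold at every cycle", {
  cb <- codebook(ORTHO4, paste0("Actb_", 1:4))
  calls <- data.frame(
    spot_id = rep(1:2, each = 4), cycle = rep(1:4, 2),
    base = c("A", "C", "G", "T",  "A", "C", "G", "T"),
    quality = c(0.9, 0.8, 0.9, 0.7,  0.9, 0.3, 0.9, 0.7),
    ambiguous = FALSE)
  reads <- assemble_reads(calls, cb, threshold = 0.5)
  expect_identical(reads$status, c("expected", "discarded"))
  expect_identical(reads$sequence[1], "ACGT")
  expect_identical(reads$target[1], "Actb_1")
  expect_identical(reads$reason[2], "low_quality")

  # ambiguous calls and missing cycles are discarded with a reason
  calls2 <- calls
  calls2$ambiguous[3] <- TRUE
  expect_identical(assemble_reads(calls2, cb)$reason[1], "ambiguous")
  reads3 <- assemble_reads(calls[-8, ], cb)
  expect_identical(reads3$reason[2], "missing_cycle")
  expect_identical(reads3$status[2], "discarded")
})

test_that("assembly and classification agree with brute force on 1,200
           randomized spots", {
  set.seed(7)
  calls <- random_calls(1200, 4)
  amb <- sample(nrow(calls), 60)
  calls$ambiguous[amb] <- TRUE
  cb <- codebook(ORTHO4, paste0("Actb_", 1:4))
  mine <- assemble_reads(calls, cb, threshold = 0.5)
  oracle <- oracle_reads(calls, ORTHO4, 0.5, 4)
  expect_identical(mine$spot_id, oracle$spot_id)
  expect_identical(mine$status, oracle$status)
  expect_identical(mine$sequence, oracle$sequence)
})

test_that("classification is exact-match over the full design space", {
  cb <- codebook(ORTHO4, paste0("Actb_", 1:4))
  all_seqs <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 4)),
                    1, paste, collapse = "")
  cl <- classify_read(all_seqs, cb)
  expect_identical(sum(cl$status == "expected"), 4L)
  expect_identical(sum(cl$status == "unexpected"), 252L)
  expect_identical(classify_read("ACGT", cb)$target, "Actb_1")
  expect_error(classify_read("ACG", cb), "length")
})

test_that("codebook capacities follow 4^n", {
  expect_equal(codebook_capacity(2), 16)
  expect_equal(codebook_capacity(3), 64)
  expect_equal(codebook_capacity(4), 256)
  expect_equal(unexpected_capacity(4, 4), 252)
  expect_error(unexpected_capacity(2, 17), "4\\^n")
})

test_that("codebook construction rejects malformed inputs", {
  expect_error(codebook(c("ACGT", "ACG")), "same length")
  expect_error(codebook(c("ACGT", "ACGU")), "alphabet")
  expect_error(codebook(c("ACGT", "ACGT")), "unique")
})

test_that("cycle truncation emulates lower-plex designs", {
  set.seed(31)
  calls <- random_calls(400, 4, qual = c(0.6, 1))
  cb <- codebook(ORTHO4, paste0("Actb_", 1:4))

  # k = n_cycles reproduces plain assembly
  full <- assemble_reads(calls, cb, threshold = 0.5)
  trunc4 <- truncate_to_cycles(calls, 4, cb, threshold = 0.5)
  expect_identical(full, trunc4)

  # orthogonal first positions: 4 distinguishable targets at k = 1
  cb1 <- truncate_codebook(cb, 1)
  expect_identical(sort(cb1$barcode), c("A", "C", "G", "T"))

  # colliding truncation errors, naming the entries
  cb_bad <- codebook(c("AACC", "AAGG", "CCAA", "GGTT"))
  expect_error(truncate_codebook(cb_bad, 2), "AACC")
})

test_that("expected reads can only be lost as more cycles are read", {
  cfg <- small_config(seed = 23L)
  s <- generate_sample(cfg)
  sp <- extract_intensities(detect_spots(s$stack), s$stack,
                            estimate_shifts(s$stack))
  calls <- spots_to_calls(sp)
  cb <- codebook(cfg$codebook_barcodes)
  n_exp <- vapply(2:4, function(k)
    sum(truncate_to_cycles(calls, k, cb)$status == "expected"), numeric(1))
  expect_true(all(diff(n_exp) <= 0))
})

test_that("raising the quality threshold never adds survivors and, in
           expectation, never hurts accuracy", {
  # thresholds chosen inside the feasible quality range of this
  # crosstalk level (a clean call tops out at 0.6/0.9 = 0.67)
  thresholds <- c(0.3, 0.4, 0.5)
  acc <- matrix(NA_real_, 20, length(thresholds))
  surv <- matrix(NA_real_, 20, length(thresholds))
  for (k in seq_len(20)) {
    cfg <- small_config(seed = 400L + k,
                        crosstalk = matrix(0.1, 4, 4) + diag(4) * 0.6,
                        strip_residue = 0.25)
    s <- generate_sample(cfg)
    sp <- extract_intensities(detect_spots(s$stack), s$stack,
                              estimate_shifts(s$stack))
    calls <- spots_to_calls(sp)
    cb <- codebook(cfg$codebook_barcodes)
    for (j in seq_along(thresholds)) {
      r <- assemble_reads(calls, cb, threshold = thresholds[j])
      surv[k, j] <- sum(r$status != "discarded")
      acc[k, j] <- if (surv[k, j] > 0) sequencing_accuracy(r) else NA
    }
  }
  # survivors: monotone per run, exactly
  expect_true(all(apply(surv, 1, function(v) all(diff(v) <= 0))))
  # accuracy: monotone in expectation (mean over runs)
  mean_acc <- colMeans(acc, na.rm = TRUE)
  expect_true(all(diff(mean_acc) >= -0.01))
})

test_that("uniform-random calling attains the analytic null accuracy", {
  set.seed(55)
  calls <- random_calls(10000, 4, qual = c(0.9, 1))
  cb <- codebook(ORTHO4)
  reads <- assemble_reads(calls, cb, threshold = 0.5)
  p0 <- 4 / 256
  expect_lt(abs(sequencing_accuracy(reads) - p0),
            4 * sqrt(p0 * (1 - p0) / 10000))
})

test_that("barcode recovery is high at high SNR and degrades
           monotonically with crosstalk strength", {
  # full imaging pipeline at moderate noise, identity mixing
  cfg <- clean_config(seed = 71L, shot_noise = TRUE, read_noise_sd = 10)
  s <- generate_sample(cfg)
  sp <- extract_intensities(detect_spots(s$stack), s$stack)
  m <- match_truth(sp, s$truth$spots)
  calls <- spots_to_calls(sp)
  truth_bases <- do.call(rbind,
                         strsplit(s$truth$spots$barcode[m$truth_idx], ""))
  hits <- 0; tot <- 0
  for (cyc in 1:4) {
    cc <- calls[calls$cycle == cyc, ]
    hits <- hits + sum(cc$base == truth_bases[, cyc])
    tot <- tot + nrow(cc)
  }
  expect_gt(hits / tot, 0.99)

  # signal-level sweep: recovery falls as the mixing loses diagonal
  # dominance relative to the measurement noise
  set.seed(5)
  rec <- vapply(c(0, 0.08, 0.16, 0.24), function(e) {
    M <- matrix(e, 4, 4); diag(M) <- 1 - 3 * e
    n <- 4000
    true <- sample(1:4, n, replace = TRUE)
    amp <- rlnorm(n, log(10), 0.3)
    sig <- t(vapply(seq_len(n), function(i)
      amp[i] * M[true[i], ] + rnorm(4, 0, 1.5), numeric(4)))
    mean(call_bases(sig)$base == c("A", "C", "G", "T")[true])
  }, numeric(1))
  expect_gt(rec[1], 0.99)
  expect_true(all(diff(rec) < 0))
})
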