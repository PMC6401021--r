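test_that("well-separated noise-free spots are detected perfectly", {
  pos <- expand.grid(x = seq(30, 160, by = 26), y = seq(30, 160, by = 26))
  pos <- pos[seq_len(36), ]
  img <- render_spot_field(c(192L, 192L), pos$x, pos$y, 3000, 1.5) + 100
  sp <- detect_spots(anchor_stack(img))
  expect_identical(nrow(sp), 36L)
  d <- sqrt(outer(sp$x, pos$x, "-")^2 + outer(sp$y, pos$y, "-")^2)
  expect_lt(max(apply(d, 2, min)), 1)
})

test_that("blank and invalid inputs are handled", {
  blank <- anchor_stack(matrix(0, 64, 64))
  expect_identical(nrow(detect_spots(blank)), 0L)
  flat <- anchor_stack(matrix(100, 64, 64))
  expect_identical(nrow(detect_spots(flat)), 0L)
  expect_error(detect_spots(blank, threshold_k = 0), "threshold_k")
})

test_that("pair resolution follows the local-maxima rule", {
  mk <- function(sep) {
    img <- render_spot_field(c(64L, 64L), c(32, 32), c(24, 24 + sep),
                             3000, 1.5) + 50
    detect_spots(anchor_stack(img))
  }
  expect_identical(nrow(mk(15)), 2L)   # 10 sigma apart: resolved
  # at 1 sigma the summed profile is unimodal: one local maximum, merged
  expect_identical(nrow(mk(1.5)), 1L)
})

test_that("detected count is non-increasing in the detection threshold", {
  s <- generate_sample(small_config(seed = 13L))
  counts <- vapply(c(2, 4, 6, 10, 20, 40),
                   function(k) nrow(detect_spots(s$stack, threshold_k = k)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("SNR is 1 on a flat field and max/surround on a plateau", {
  # flat image: every spot has spot mean = surround mean = c
  s <- generate_sample(clean_config(seed = 4L))
  sp <- detect_spots(s$stack)
  flat <- matrix(7.5, nrow(s$stack$data[1, 2, , ]),
                 ncol(s$stack$data[1, 2, , ]))
  snr_flat <- compute_snr(sp, flat)
  expect_true(all(abs(snr_flat$snr - 1) < 1e-12))

  # plateau 20 over background 2: SNR exactly 10
  img <- matrix(2, 64, 64)
  img[30:34, 30:34] <- 20
  sp2 <- detect_spots(anchor_stack(img), min_area = 4L)
  expect_identical(nrow(sp2), 1L)
  # force the mask to the plateau so the ratio is exact
  sp2$mask[[1]] <- which(img == 20)
  out <- compute_snr(sp2, img)
  expect_equal(out$snr, 10)
})

test_that("SNR matches a brute-force pixel-set recomputation", {
  s <- generate_sample(small_config(seed = 17L))
  sp <- detect_spots(s$stack)
  anchor <- get_plane(s$stack, 1, "ANCHOR")
  out <- compute_snr(sp, anchor)

  fd <- dim(anchor)
  allm <- matrix(FALSE, fd[1], fd[2])
  for (m in sp$mask) allm[m] <- TRUE
  for (i in seq_len(min(nrow(sp), 12L))) {
    rc <- cbind((sp$mask[[i]] - 1) %% fd[1] + 1,
                (sp$mask[[i]] - 1) %/% fd[1] + 1)
    surround <- c()
    for (r in seq_len(fd[1])) {
      for (cc in seq_len(fd[2])) {
        if (allm[r, cc]) next
        if (min((rc[, 1] - r)^2 + (rc[, 2] - cc)^2) <= 64) {
          surround <- c(surround, (cc - 1) * fd[1] + r)
        }
      }
    }
    expect_equal(out$snr[i],
                 mean(anchor[sp$mask[[i]]]) / mean(anchor[surround]))
  }
})

test_that("undefined SNR (zero surround) is flagged, not fabricated", {
  img <- matrix(0, 48, 48)
  img[20:24, 20:24] <- 50
  sp <- detect_spots(anchor_stack(img))
  out <- compute_snr(sp, img)
  expect_true(all(out$snr_undefined))
  expect_true(all(is.na(out$snr)))
})

test_that("known rigid shifts are recovered exactly", {
  cfg <- small_config(jitter_sd = 2, seed = 19L)
  s <- generate_sample(cfg)
  est <- estimate_shifts(s$stack)
  expect_identical(est$dx, s$truth$shifts$dx)
  expect_identical(est$dy, s$truth$shifts$dy)
  expect_true(all(est$confident))
})

test_that("identical or degenerate cycles give zero shifts", {
  cfg <- small_config(jitter_sd = 0, seed = 19L, shot_noise = FALSE,
                      read_noise_sd = 0, dropout_prob = 0)
  s <- generate_sample(cfg)
  est <- estimate_shifts(s$stack)
  expect_true(all(est$dx == 0L) && all(est$dy == 0L))

  # featureless stack: zero shift, low confidence
  flat <- iss_stack(array(5, dim = c(2, 6, 32, 32)))
  est2 <- estimate_shifts(flat)
  expect_true(all(est2$dx == 0) && all(!est2$confident))
})

test_that("intensity extraction recovers the true barcode channel", {
  cfg <- clean_config(seed = 4L)
  s <- generate_sample(cfg)
  sp <- detect_spots(s$stack)
  sp <- extract_intensities(sp, s$stack, s$truth$shifts)
  m <- match_truth(sp, s$truth$spots)
  expect_equal(m$recall, 1)
  bases <- c("A", "C", "G", "T")
  for (cyc in seq_len(cfg$n_cycles)) {
    mat <- as.matrix(sp[, sprintf("c%d_%s", cyc, bases)])
    called <- bases[apply(mat, 1, which.max)]
    expect_identical(called,
                     substr(s$truth$spots$barcode[m$truth_idx], cyc, cyc))
  }
})

test_that("extraction is equivariant under a global rigid shift", {
  cfg <- clean_config(seed = 6L)
  s <- generate_sample(cfg)
  sp <- detect_spots(s$stack)
  base <- extract_intensities(sp, s$stack)

  # shift every plane of every cycle by (+3, +2), padding with background
  d <- dim(s$stack$data)
  arr <- array(cfg$background_level[1], dim = d)
  arr[, , 4:d[3], 3:d[4]] <- s$stack$data[, , 1:(d[3] - 3), 1:(d[4] - 2)]
  shifted_stack <- iss_stack(arr, pixel_size = s$stack$pixel_size)
  sh <- data.frame(cycle = seq_len(d[1]), dx = 3L, dy = 2L)
  moved <- extract_intensities(sp, shifted_stack, sh)

  cols <- grep("^c[0-9]+_", names(base), value = TRUE)
  interior <- !moved$partially_measured
  expect_gt(sum(interior), 0)
  expect_equal(as.matrix(moved[interior, cols]),
               as.matrix(base[interior, cols]))
})

test_that("flat-field extraction background-subtracts to zero", {
  s <- generate_sample(clean_config(seed = 4L))
  sp <- detect_spots(s$stack)
  arr <- array(9, dim = dim(s$stack$data))
  flat <- iss_stack(arr, pixel_size = s$stack$pixel_size)
  out <- extract_intensities(sp, flat)
  cols <- grep("^c[0-9]+_", names(out), value = TRUE)
  expect_true(all(abs(as.matrix(out[, cols])) < 1e-12))
})

test_that("disjoint disk nuclei are segmented and located", {
  cx <- c(30, 30, 95, 95, 160)
  cy <- c(40, 140, 90, 160, 50)
  img <- matrix(0, 192, 192)
  for (i in 1:5) {
    for (r in 1:192) for (cc in 1:192) {
      if ((r - cx[i])^2 + (cc - cy[i])^2 <= 12^2) img[r, cc] <- 1000
    }
  }
  cm <- segment_cells(img)
  expect_identical(nrow(cm$centroids), 5L)
  d <- sqrt(outer(cm$centroids$x, cx, "-")^2 +
            outer(cm$centroids$y, cy, "-")^2)
  expect_lt(max(apply(d, 2, min)), 2)

  expect_identical(nrow(segment_cells(matrix(0, 64, 64))$centroids), 0L)
})

test_that("touching nuclei are split by the watershed", {
  img <- matrix(0, 96, 96)
  for (r in 1:96) for (cc in 1:96) {
    if ((r - 48)^2 + (cc - 36)^2 <= 14^2) img[r, cc] <- 1000
    if ((r - 48)^2 + (cc - 58)^2 <= 14^2) img[r, cc] <- 1000
  }
  cm <- segment_cells(img)
  expect_identical(nrow(cm$centroids), 2L)
})

test_that("spots are assigned to their generating cells", {
  cfg <- clean_config(seed = 12L)
  s <- generate_sample(cfg)
  sp <- detect_spots(s$stack)
  cm <- segment_cells(get_plane(s$stack, 1, "DAPI"))
  sp <- assign_spots_to_cells(sp, cm, max_dist = 30,
                              pixel_size = cfg$pixel_size)
  m <- match_truth(sp, s$truth$spots)
  true_cells <- s$truth$spots$cell_id[m$truth_idx]

  # map segmentation labels to truth cells by centroid proximity
  dc <- sqrt(outer(cm$centroids$x, s$truth$cells$x, "-")^2 +
             outer(cm$centroids$y, s$truth$cells$y, "-")^2)
  lab2truth <- apply(dc, 1, which.min)
  assigned <- !is.na(sp$cell_id)
  agree <- lab2truth[sp$cell_id[assigned]] == true_cells[assigned]
  expect_gte(mean(agree), 0.95)
})

test_that("assignment respects the distance cutoff and empty maps", {
  s <- generate_sample(clean_config(seed = 12L))
  sp <- detect_spots(s$stack)
  cm <- segment_cells(get_plane(s$stack, 1, "DAPI"))

  # spot exactly at a centroid gets that cell
  sp$x[1] <- cm$centroids$x[1]; sp$y[1] <- cm$centroids$y[1]
  out <- assign_spots_to_cells(sp, cm, pixel_size = 0.32)
  expect_identical(out$cell_id[1], cm$centroids$cell_id[1])

  # tiny cutoff: a far-away spot stays unassigned
  far <- sp[1, , drop = FALSE]
  far$x <- cm$centroids$x[1] + 50; far$y <- cm$centroids$y[1] + 50
  attr(far, "field_dim") <- attr(sp, "field_dim")
  class(far) <- class(sp)
  out2 <- assign_spots_to_cells(far, cm, max_dist = 1, pixel_size = 0.32)
  expect_true(is.na(out2$cell_id[1]))

  empty <- segment_cells(matrix(0, 32, 32))
  out3 <- assign_spots_to_cells(sp, empty, pixel_size = 0.32)
  expect_true(all(is.na(out3$cell_id)))
})
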