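# shared fixtures and independent oracles

ORTHO4 <- c("ACGT", "CGTA", "GTAC", "TACG")

# a small, quick-to-render configuration; overrides win
small_config <- function(...) {
  args <- utils::modifyList(
    list(field_size = c(192L, 192L), n_cells = 4L,
         nucleus_radius = c(10, 1.5), cell_radius = 24,
         rcps_per_cell = 10),
    list(...))
  do.call(sim_config, args)
}

# fully deterministic render: no shot/read noise, no dropout, no jitter,
# identity crosstalk, no stripping residue, spots kept apart
clean_config <- function(...) {
  args <- utils::modifyList(
    list(n_cells = 6L, rcps_per_cell = 12, crosstalk = diag(4),
         strip_residue = 0, shot_noise = FALSE, read_noise_sd = 0,
         dropout_prob = 0, jitter_sd = 0, min_spot_separation = 12),
    list(...))
  do.call(sim_config, args)
}

# greedy nearest matching of detections to ground-truth spots
match_truth <- function(spots, truth, tol = 1.5) {
  if (nrow(spots) == 0L || nrow(truth) == 0L) {
    return(list(recall = 0, precision = 0, truth_idx = integer(0)))
  }
  d <- sqrt(outer(spots$x, truth$x, "-")^2 + outer(spots$y, truth$y, "-")^2)
  list(recall = mean(apply(d, 2, min) <= tol),
       precision = mean(apply(d, 1, min) <= tol),
       truth_idx = apply(d, 1, which.min))
}

# independent brute-force base caller: plain max/sum, no vectorization
oracle_call <- function(v) {
  v <- pmax(v, 0)
  s <- sum(v)
  if (s == 0) {
    return(list(base = "A", quality = 0, ambiguous = TRUE))
  }
  mx <- max(v)
  tied <- which(v == mx)
  list(base = c("A", "C", "G", "T")[tied[1]], quality = mx / s,
       ambiguous = length(tied) > 1L)
}

# independent read assembly + classification over a calls data frame
oracle_reads <- function(calls, barcodes, threshold, n_cyc) {
  ids <- unique(calls$spot_id)
  out <- data.frame(spot_id = ids, sequence = NA_character_,
                    status = "discarded", stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    ci <- calls[calls$spot_id == ids[i] & calls$cycle <= n_cyc, ]
    ci <- ci[order(ci$cycle), ]
    if (nrow(ci) != n_cyc || any(ci$cycle != seq_len(n_cyc))) next
    sq <- paste(ci$base, collapse = "")
    out$sequence[i] <- sq
    if (any(ci$quality < threshold) || any(ci$ambiguous)) next
    out$status[i] <- if (sq %in% barcodes) "expected" else "unexpected"
  }
  out
}

# random calls table: n spots x n_cyc cycles with given quality range
random_calls <- function(n, n_cyc, qual = c(0, 1)) {
  data.frame(
    spot_id = rep(seq_len(n), each = n_cyc),
    cycle = rep(seq_len(n_cyc), n),
    base = sample(c("A", "C", "G", "T"), n * n_cyc, replace = TRUE),
    quality = runif(n * n_cyc, qual[1], qual[2]),
    ambiguous = FALSE,
    stringsAsFactors = FALSE)
}

# single-cycle stack with an arbitrary anchor plane and flat other channels
anchor_stack <- function(anchor, fill = 0) {
  fd <- dim(anchor)
  arr <- array(fill, dim = c(1, 6, fd[1], fd[2]))
  arr[1, 2, , ] <- anchor
  iss_stack(arr)
}
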