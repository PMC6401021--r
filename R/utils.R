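# internal index helpers: masks are 1-based linear indices into a
# column-major [row, col] plane, like R matrix indexing

idx_to_rc <- function(idx, nrow) {
  cbind(row = ((idx - 1L) %% nrow) + 1L,
        col = ((idx - 1L) %/% nrow) + 1L)
}

rc_to_idx <- function(rc, nrow) {
  (rc[, 2L] - 1L) * nrow + rc[, 1L]
}

shift_idx <- function(idx, dx, dy, dims) {
  rc <- idx_to_rc(idx, dims[1])
  r <- rc[, 1L] + dx
  c <- rc[, 2L] + dy
  ok <- r >= 1L & r <= dims[1] & c >= 1L & c <= dims[2]
  list(idx = (c[ok] - 1L) * dims[1] + r[ok], complete = all(ok))
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}
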