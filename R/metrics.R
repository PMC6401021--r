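#' RCP yield: spots per cell
#'
#' The basic detection-efficiency measure of an ISS run: the number of
#' RCPs divided by the number of cells in the field.  Callers may pass
#' either raw detections or threshold-surviving reads as the numerator,
#' depending on which stage of the assay they are judging.
#'
#' @param n_spots number of RCPs (or a spots data frame).
#' @param n_cells number of cells (or an `iss_cellmap`).
#' @return Spots per cell (numeric scalar).
#' @export
rcp_yield <- function(n_spots, n_cells) {
  if (is.data.frame(n_spots)) n_spots <- nrow(n_spots)
  if (inherits(n_cells, "iss_cellmap")) n_cells <- nrow(n_cells$centroids)
  if (n_cells <= 0) stop("RCP yield undefined for zero cells", call. = FALSE)
  n_spots / n_cells
}

#' Sequencing accuracy
#'
#' The fraction of surviving reads that match a designed barcode:
#' expected / (expected + unexpected).  Discarded reads are excluded
#' from both numerator and denominator, mirroring accuracy evaluation
#' after quality thresholding.
#'
#' @param reads an `iss_reads` data frame from [assemble_reads()].
#' @return Accuracy in \[0, 1\].
#' @export
sequencing_accuracy <- function(reads) {
  ne <- sum(reads$status == "expected")
  nu <- sum(reads$status == "unexpected")
  if (ne + nu == 0) {
    stop("accuracy undefined: no reads survive the quality threshold",
         call. = FALSE)
  }
  ne / (ne + nu)
}

#' Reads per cell, split by expected/unexpected
#'
#' @param reads an `iss_reads` data frame.
#' @param n_cells number of cells (or an `iss_cellmap`).
#' @return A list with `expected`, `unexpected` and `total` reads per
#'   cell.
#' @export
reads_per_cell <- function(reads, n_cells) {
  if (inherits(n_cells, "iss_cellmap")) n_cells <- nrow(n_cells$centroids)
  if (n_cells <= 0) stop("reads per cell undefined for zero cells",
                         call. = FALSE)
  ne <- sum(reads$status == "expected")
  nu <- sum(reads$status == "unexpected")
  list(expected = ne / n_cells, unexpected = nu / n_cells,
       total = (ne + nu) / n_cells)
}

#' Performance efficiency of an on-chip condition against its control
#'
#' Performance efficiency (PE) normalizes a device-run ("on-chip")
#' metric to its matched manual ("off-chip") control.  Two aggregations
#' are computed: the mean of per-replicate matched ratios
#' `mean(on_i / off_i)` (the default headline number) and the ratio of
#' means `mean(on) / mean(off)`; both are reported so the reader can
#' see when they differ.  Pairs whose control value is zero are dropped
#' with a warning under the paired aggregation.
#'
#' @param on,off numeric vectors of replicate metric values; equal
#'   length when `aggregation = "paired-ratio-mean"`.
#' @param metric name of the metric being compared.
#' @param aggregation which PE to report as `pe`.
#' @return A one-row data frame of class `iss_pe`: `metric`, `on_value`
#'   and `off_value` (means), `pe`, `pe_paired`, `pe_ratio_of_means`,
#'   `aggregation`, `n_pairs`.
#' @export
performance_efficiency <- function(on, off, metric = "metric",
                                   aggregation = c("paired-ratio-mean",
                                                   "ratio-of-means")) {
  aggregation <- match.arg(aggregation)
  if (length(on) < 1L || length(off) < 1L) {
    stop("need at least one replicate per condition", call. = FALSE)
  }
  pe_rom <- if (mean(off) > 0) mean(on) / mean(off) else NA_real_
  pe_paired <- NA_real_
  n_pairs <- 0L
  if (length(on) == length(off)) {
    ok <- off != 0
    if (any(!ok)) {
      warning(sum(!ok), " pair(s) with zero control value excluded")
    }
    if (any(ok)) {
      pe_paired <- mean(on[ok] / off[ok])
      n_pairs <- sum(ok)
    }
  } else if (aggregation == "paired-ratio-mean") {
    stop("paired-ratio-mean requires matched replicate vectors",
         call. = FALSE)
  }
  pe <- if (aggregation == "paired-ratio-mean") pe_paired else pe_rom
  out <- data.frame(metric = metric, on_value = mean(on),
                    off_value = mean(off), pe = pe,
                    pe_paired = pe_paired, pe_ratio_of_means = pe_rom,
                    aggregation = aggregation, n_pairs = n_pairs,
                    stringsAsFactors = FALSE)
  class(out) <- c("iss_pe", "data.frame")
  out
}

#' Stacked per-base quality normalized to a control condition
#'
#' Mean RCP quality is computed per base group (A, C, G, T), each group
#' mean is downscaled by four, the four contributions are stacked, and
#' the stack is normalized to the control condition's stack.  A total of
#' 1 means base calling as robust as the control; with orthogonal
#' barcodes each base should contribute ~0.25.  `normalization =
#' "stack"` divides every contribution by the control's stack total (so
#' the contributions sum to the normalized total); `"per-group"` divides
#' each base's contribution by the control's same-base contribution.
#'
#' @param on,off numeric length-4 vectors of per-base mean qualities
#'   (A, C, G, T), entries in (0, 1\].
#' @param normalization `"stack"` (default) or `"per-group"`.
#' @return A list with `contributions` (named length-4 vector) and
#'   `total` (their sum for `"stack"`; the mean quality ratio).
#' @export
stacked_quality <- function(on, off, normalization = c("stack", "per-group")) {
  normalization <- match.arg(normalization)
  stopifnot(length(on) == 4L, length(off) == 4L)
  if (any(off <= 0)) {
    stop("control per-base qualities must be positive", call. = FALSE)
  }
  if (normalization == "stack") {
    denom <- sum(off / 4)
    contrib <- (on / 4) / denom
  } else {
    contrib <- (on / 4) / (off / 4) / 4
  }
  names(contrib) <- BASES
  list(contributions = contrib, total = sum(contrib))
}

#' Per-cycle, per-base mean quality track
#'
#' Groups calls by cycle and called base and reports each group's mean
#' quality (and size).  A steady track across cycles indicates the RCPs
#' survive repeated stripping and restaining; with orthogonal barcodes
#' the four group sizes should be balanced at every cycle.  Empty
#' groups are reported as `NA`, not zero.
#'
#' @param calls long calls data frame (see [assemble_reads()]).
#' @return A data frame with columns `cycle`, `base`, `mean_quality`,
#'   `n`.
#' @export
per_cycle_quality <- function(calls) {
  cycs <- sort(unique(calls$cycle))
  out <- expand.grid(cycle = cycs, base = BASES, stringsAsFactors = FALSE)
  out <- out[order(out$cycle, out$base), ]
  out$mean_quality <- NA_real_
  out$n <- 0L
  for (i in seq_len(nrow(out))) {
    sel <- calls$cycle == out$cycle[i] & calls$base == out$base[i]
    out$n[i] <- sum(sel)
    if (out$n[i] > 0) out$mean_quality[i] <- mean(calls$quality[sel])
  }
  rownames(out) <- NULL
  out
}

#' Stripping efficiency from a pre-/post-strip stack pair
#'
#' Quantifies how completely the previous cycle's sequencing probes were
#' removed: one minus the ratio of the mean background-subtracted
#' base-channel spot signal after stripping to the same quantity before,
#' clipped to \[0, 1\].  A value of 1 means the post-strip base channels
#' are back at background; 0 means nothing was removed.
#'
#' @param pre,post [iss_stack()]s sharing geometry; `pre` is the stained
#'   acquisition, `post` the re-image after stripping.
#' @param spots `iss_spots` detected on the pre-strip anchor channel.
#' @param cycle which cycle of each stack to compare.
#' @param annulus_width background annulus extent, pixels.
#' @return Stripping efficiency in \[0, 1\].
#' @export
stripping_efficiency <- function(pre, post, spots, cycle = 1L,
                                 annulus_width = 8L) {
  stopifnot(inherits(pre, "iss_stack"), inherits(post, "iss_stack"))
  if (!all(field_dim(pre) == field_dim(post))) {
    stop("pre and post stacks must share geometry", call. = FALSE)
  }
  if (nrow(spots) == 0L) stop("no spots to measure", call. = FALSE)
  total_signal <- function(stk) {
    m <- extract_intensities(spots, stk, annulus_width = annulus_width)
    cols <- sprintf("c%d_%s", cycle, BASES)
    v <- rowSums(pmax(as.matrix(m[, cols]), 0))
    mean(v)
  }
  s_pre <- total_signal(pre)
  if (s_pre <= 0) stop("no pre-strip base-channel signal", call. = FALSE)
  s_post <- total_signal(post)
  min(max(1 - s_post / s_pre, 0), 1)
}

#' Summarize one condition into the standard metric set
#'
#' @param spots `iss_spots` with SNR computed.
#' @param reads `iss_reads` for the same spots.
#' @param calls long calls data frame used to build `reads`.
#' @param n_cells cell count (or an `iss_cellmap`).
#' @param condition label for the condition (e.g. `"on-chip"`).
#' @return A one-row data frame: `condition`, `n_cells`, `n_spots`,
#'   `rcp_yield`, `mean_snr`, `reads_per_cell_expected`,
#'   `reads_per_cell_unexpected`, `accuracy`, `n_discarded`.
#' @export
condition_metrics <- function(spots, reads, calls, n_cells,
                              condition = "condition") {
  if (inherits(n_cells, "iss_cellmap")) n_cells <- nrow(n_cells$centroids)
  rpc <- reads_per_cell(reads, n_cells)
  data.frame(
    condition = condition, n_cells = n_cells, n_spots = nrow(spots),
    rcp_yield = rcp_yield(nrow(spots), n_cells),
    mean_snr = mean(spots$snr, na.rm = TRUE),
    reads_per_cell_expected = rpc$expected,
    reads_per_cell_unexpected = rpc$unexpected,
    accuracy = sequencing_accuracy(reads),
    n_discarded = sum(reads$status == "discarded"),
    stringsAsFactors = FALSE)
}
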