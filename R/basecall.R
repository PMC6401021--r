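#' Call a base from four sequencing-probe signals
#'
#' A base is called as the channel with the brightest signal, and the
#' call's quality is the brightest signal divided by the sum of all four
#' — the RCP quality.  For non-negative signals with positive sum the
#' quality lies in \[0.25, 1\]: 1 when a single channel carries all the
#' signal, 0.25 when all four are equal.  Negative inputs (possible
#' after background subtraction) are clipped to zero first.  An exact
#' tie for the maximum is flagged ambiguous, with the alphabetically
#' first tied base reported; an all-zero signal vector yields quality 0
#' and an ambiguous call.
#'
#' @param signals numeric vector of length 4 ordered (A, C, G, T), or a
#'   matrix with 4 such columns for [call_bases()].
#' @return A one-row data frame (`base`, `quality`, `ambiguous`) for
#'   `call_base()`; one row per input row for `call_bases()`.
#' @export
#' @examples
#' call_base(c(10, 2, 1, 1))   # A, quality 10/14
call_base <- function(signals) {
  if (length(signals) != 4L) stop("signals must have length 4", call. = FALSE)
  call_bases(matrix(signals, nrow = 1L))
}

#' @rdname call_base
#' @export
call_bases <- function(signals) {
  signals <- as.matrix(signals)
  if (ncol(signals) != 4L) stop("signals must have 4 columns", call. = FALSE)
  signals[signals < 0] <- 0
  mx <- apply(signals, 1L, max)
  tot <- rowSums(signals)
  n_at_max <- rowSums(signals == mx)
  best <- apply(signals, 1L, which.max)   # first (alphabetical) argmax
  data.frame(
    base = BASES[best],
    quality = ifelse(tot > 0, mx / tot, 0),
    ambiguous = n_at_max > 1L | tot == 0,
    stringsAsFactors = FALSE)
}

#' Convert measured spot intensities to per-cycle base calls
#'
#' Takes the `c<cycle>_<base>` columns added by [extract_intensities()]
#' and produces one base call per spot per cycle.
#'
#' @param spots an `iss_spots` data frame with intensity columns.
#' @param n_cycles number of cycles to call; defaults to every cycle
#'   present in the columns.
#' @return A long data frame with columns `spot_id`, `cycle`, `base`,
#'   `quality`, `ambiguous`.
#' @export
spots_to_calls <- function(spots, n_cycles = NULL) {
  cols <- grep("^c[0-9]+_[ACGT]$", names(spots), value = TRUE)
  cycs <- sort(unique(as.integer(sub("^c([0-9]+)_.*$", "\\1", cols))))
  if (!is.null(n_cycles)) cycs <- cycs[cycs <= n_cycles]
  if (length(cycs) == 0L) stop("no intensity columns found", call. = FALSE)
  out <- vector("list", length(cycs))
  for (k in seq_along(cycs)) {
    m <- as.matrix(spots[, sprintf("c%d_%s", cycs[k], BASES)])
    calls <- call_bases(m)
    out[[k]] <- data.frame(spot_id = spots$id, cycle = cycs[k], calls,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Assemble per-cycle base calls into reads and decode them
#'
#' Concatenates each spot's called bases cycle by cycle into a read.
#' A spot is discarded when its quality drops below `threshold` at any
#' cycle, when any of its calls is ambiguous, or when a cycle is
#' missing; surviving reads are classified against the codebook as
#' expected (sequence is a designed barcode) or unexpected.
#'
#' @param calls long data frame of calls (`spot_id`, `cycle`, `base`,
#'   `quality`, `ambiguous`) as from [spots_to_calls()].
#' @param cb an [codebook()] whose barcode length equals the number of
#'   cycles assembled.
#' @param threshold quality threshold in \[0, 1\]; the original ISS
#'   pipeline's value is unpublished, 0.5 is this package's default.
#' @param n_cycles number of cycles each read must cover; defaults to
#'   the codebook's barcode length.
#' @return A data frame of class `iss_reads` with one row per spot:
#'   `spot_id`, `sequence`, `min_quality`, `status`
#'   (`expected`/`unexpected`/`discarded`), `target` and `reason`
#'   (`NA`, `"low_quality"`, `"ambiguous"` or `"missing_cycle"`).
#' @export
assemble_reads <- function(calls, cb, threshold = 0.5, n_cycles = NULL) {
  stopifnot(inherits(cb, "iss_codebook"))
  if (threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(n_cycles)) n_cycles <- attr(cb, "barcode_length")
  if (attr(cb, "barcode_length") != n_cycles) {
    stop("codebook barcode length must equal n_cycles", call. = FALSE)
  }
  calls <- calls[calls$cycle <= n_cycles, , drop = FALSE]
  ids <- unique(calls$spot_id)
  n <- length(ids)
  ord <- order(match(calls$spot_id, ids), calls$cycle)
  cycv <- as.integer(calls$cycle)[ord]
  basev <- calls$base[ord]
  qv <- calls$quality[ord]
  ambv <- calls$ambiguous[ord]
  grp <- split(seq_along(ord), factor(calls$spot_id[ord], levels = ids))
  seqs <- character(n); minq <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  full <- seq_len(n_cycles)
  for (i in seq_len(n)) {
    j <- grp[[i]]
    if (length(j) != n_cycles || !identical(cycv[j], full)) {
      reason[i] <- "missing_cycle"
      seqs[i] <- NA_character_
      next
    }
    seqs[i] <- paste(basev[j], collapse = "")
    minq[i] <- min(qv[j])
    if (minq[i] < threshold) {
      reason[i] <- "low_quality"
    } else if (any(ambv[j])) {
      reason[i] <- "ambiguous"
    }
  }
  status <- rep("discarded", n)
  target <- rep(NA_character_, n)
  ok <- is.na(reason)
  if (any(ok)) {
    cl <- classify_read(seqs[ok], cb)
    status[ok] <- cl$status
    target[ok] <- cl$target
  }
  out <- data.frame(spot_id = ids, sequence = seqs, min_quality = minq,
                    status = status, target = target, reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("iss_reads", "data.frame")
  out
}

#' Re-assemble reads from the first k cycles only
#'
#' Emulates a lower-plex assay read after `k` sequencing cycles (16-plex
#' at `k = 2`, 64-plex at `k = 3`, 256-plex at `k = 4` for a four-letter
#' alphabet), truncating the codebook to match.
#'
#' @param calls long calls data frame (see [assemble_reads()]).
#' @param k number of leading cycles to use.
#' @param cb the full-length [codebook()].
#' @param threshold quality threshold, as in [assemble_reads()].
#' @return An `iss_reads` data frame over length-`k` sequences.
#' @export
truncate_to_cycles <- function(calls, k, cb, threshold = 0.5) {
  cbk <- truncate_codebook(cb, k)
  assemble_reads(calls, cbk, threshold = threshold, n_cycles = k)
}
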