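#' Detect RCP spots on the anchor channel
#'
#' Rolling circle products appear as bright, near-diffraction-limited
#' spots in the anchor-primer channel.  Detection follows a standard
#' small-spot pipeline: white top-hat background suppression (disc
#' structuring element), a robust global threshold at `threshold_k`
#' median absolute deviations above the median of the top-hat image,
#' connected components with a minimum area, and watershed splitting of
#' merged components around local intensity maxima.  When the top-hat
#' image has zero median absolute deviation (noise-free renders) the
#' threshold falls back to the median plus 2\% of the dynamic range.
#'
#' @param stack an [iss_stack()].
#' @param cycle cycle whose anchor image is used (default 1, the
#'   reference cycle).
#' @param threshold_k threshold in MADs above the median; must be > 0.
#' @param min_area minimum component area in pixels.
#' @param tophat_radius disc radius of the top-hat structuring element,
#'   pixels.
#' @param split_tolerance watershed merge tolerance as a fraction of the
#'   top-hat maximum; larger values split less.
#'
#' @return A data frame of class `iss_spots` with one row per spot:
#'   `id`, centroid `x` (row) and `y` (col, both 1-based), `area`,
#'   `anchor_intensity` (mean raw anchor intensity over the mask),
#'   `snr`, `cell_id` (both `NA` until computed) and a `mask`
#'   list-column of linear pixel indices.  The field dimensions are kept
#'   in attribute `field_dim`.
#' @export
detect_spots <- function(stack, cycle = 1L, threshold_k = 5,
                         min_area = 4L, tophat_radius = 3L,
                         split_tolerance = 0.05) {
  stopifnot(inherits(stack, "iss_stack"))
  if (threshold_k <= 0) stop("threshold_k must be > 0", call. = FALSE)
  img <- get_plane(stack, cycle, "ANCHOR")
  fd <- dim(img)

  empty <- function() {
    out <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      area = integer(0), anchor_intensity = numeric(0),
                      snr = numeric(0), cell_id = integer(0))
    out$mask <- list()
    attr(out, "field_dim") <- fd
    class(out) <- c("iss_spots", "data.frame")
    out
  }
  if (max(img) <= 0) return(empty())

  th <- EBImage::whiteTopHat(img, disc_brush(tophat_radius))
  med <- stats::median(th)
  thr <- med + threshold_k * stats::mad(th)
  if (!(thr > med)) thr <- med + 0.02 * (max(th) - med)
  mask <- th > thr
  if (!any(mask)) return(empty())

  lab <- EBImage::watershed(th * mask,
                            tolerance = split_tolerance * max(th), ext = 1L)
  lab <- as.matrix(lab)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  if (length(keep) == 0L) return(empty())

  sel <- matrix(lab %in% keep, fd[1])
  masks <- split(which(sel), factor(lab[sel], levels = keep))
  n <- length(masks)
  cx <- numeric(n); cy <- numeric(n); ai <- numeric(n)
  for (i in seq_len(n)) {
    rc <- idx_to_rc(masks[[i]], fd[1])
    cx[i] <- mean(rc[, 1]); cy[i] <- mean(rc[, 2])
    ai[i] <- mean(img[masks[[i]]])
  }
  out <- data.frame(id = seq_len(n), x = cx, y = cy,
                    area = lengths(masks), anchor_intensity = ai,
                    snr = NA_real_, cell_id = NA_integer_)
  out$mask <- unname(masks)
  rownames(out) <- NULL
  attr(out, "field_dim") <- fd
  class(out) <- c("iss_spots", "data.frame")
  out
}

# annulus of pixels within Euclidean distance `annulus_width` of the
# spot mask, excluding every detected spot's mask
spot_annuli <- function(spots, annulus_width = 8L) {
  fd <- attr(spots, "field_dim")
  all_mask <- matrix(FALSE, fd[1], fd[2])
  for (m in spots$mask) all_mask[m] <- TRUE
  w <- as.integer(annulus_width)
  off <- expand.grid(dr = -w:w, dc = -w:w)
  off <- off[off$dr^2 + off$dc^2 <= w^2, ]
  lapply(spots$mask, function(m) {
    rc <- idx_to_rc(m, fd[1])
    r <- rep(rc[, 1], each = nrow(off)) + off$dr
    c <- rep(rc[, 2], each = nrow(off)) + off$dc
    ok <- r >= 1L & r <= fd[1] & c >= 1L & c <= fd[2]
    gidx <- unique((c[ok] - 1L) * fd[1] + r[ok])
    gidx[!all_mask[gidx]]
  })
}

#' Per-spot signal-to-noise ratio on the anchor channel
#'
#' The SNR of an RCP is the ratio of its mean anchor fluorescence to
#' that of its immediate surround, taken over an annulus extending
#' `annulus_width` pixels outward from the spot mask and excluding every
#' detected spot's mask.  A spot whose surround mean is zero gets
#' `snr = NA` and is flagged in the `snr_undefined` column.
#'
#' @param spots an `iss_spots` data frame from [detect_spots()].
#' @param anchor_image the anchor-channel matrix the spots were
#'   detected on.
#' @param annulus_width outward extent of the surround annulus, pixels.
#' @return `spots` with the `snr` column filled and a logical
#'   `snr_undefined` column added.
#' @export
compute_snr <- function(spots, anchor_image, annulus_width = 8L) {
  stopifnot(inherits(spots, "iss_spots"))
  fd <- attr(spots, "field_dim")
  stopifnot(all(dim(anchor_image) == fd))
  ann <- spot_annuli(spots, annulus_width)
  snr <- rep(NA_real_, nrow(spots))
  undef <- rep(FALSE, nrow(spots))
  for (i in seq_len(nrow(spots))) {
    s <- mean(anchor_image[spots$mask[[i]]])
    b <- if (length(ann[[i]]) > 0) mean(anchor_image[ann[[i]]]) else 0
    if (b > 0) snr[i] <- s / b else undef[i] <- TRUE
  }
  spots$snr <- snr
  spots$snr_undefined <- undef
  spots
}

#' Estimate per-cycle rigid shifts by cross-correlation
#'
#' Aligns every cycle's anchor channel to cycle 1 by the integer shift
#' maximising the circular cross-correlation (computed via FFT).  The
#' first cycle's shift is `(0, 0)` by construction.  Featureless
#' (constant) cycles get shift `(0, 0)` with `confident = FALSE`.
#'
#' @param stack an [iss_stack()].
#' @return A data frame with columns `cycle`, `dx`, `dy` (pixels, such
#'   that cycle-c content sits at reference position + `(dx, dy)`) and
#'   `confident`.
#' @export
estimate_shifts <- function(stack) {
  stopifnot(inherits(stack, "iss_stack"))
  ncyc <- n_cycles(stack)
  ref <- get_plane(stack, 1L, "ANCHOR")
  fd <- dim(ref)
  out <- data.frame(cycle = seq_len(ncyc), dx = 0L, dy = 0L,
                    confident = TRUE)
  if (stats::sd(ref) == 0) {
    out$confident <- FALSE
    return(out)
  }
  fref <- stats::fft(ref - mean(ref))
  for (cyc in seq_len(ncyc)[-1]) {
    mov <- get_plane(stack, cyc, "ANCHOR")
    if (stats::sd(mov) == 0) {
      out$confident[cyc] <- FALSE
      next
    }
    cc <- Re(stats::fft(stats::fft(mov - mean(mov)) * Conj(fref),
                        inverse = TRUE))
    peak <- arrayInd(which.max(cc), fd)
    dx <- peak[1] - 1L; dy <- peak[2] - 1L
    if (dx > fd[1] / 2) dx <- dx - fd[1]
    if (dy > fd[2] / 2) dy <- dy - fd[2]
    out$dx[cyc] <- dx; out$dy[cyc] <- dy
  }
  out
}

#' Extract per-cycle base-channel intensities for every spot
#'
#' For each spot and cycle, the spot mask (and its surround annulus) is
#' moved by that cycle's rigid shift and the mean intensity of each base
#' channel over the shifted mask is measured, background-subtracted by
#' the median of the shifted annulus in the same channel.  Spots whose
#' shifted mask leaves the field are flagged `partially_measured`.
#'
#' @param spots an `iss_spots` data frame (detected on cycle 1).
#' @param stack the [iss_stack()] to measure.
#' @param shifts per-cycle shifts as returned by [estimate_shifts()] (or
#'   the simulator's ground-truth `shifts`); `NULL` means no shift.
#' @param annulus_width outward extent of the background annulus, pixels.
#' @return `spots` with numeric columns `c<cycle>_<base>` (for example
#'   `c1_A`) holding background-subtracted mean intensities, and a
#'   logical `partially_measured` column.
#' @export
extract_intensities <- function(spots, stack, shifts = NULL,
                                annulus_width = 8L) {
  stopifnot(inherits(spots, "iss_spots"), inherits(stack, "iss_stack"))
  fd <- attr(spots, "field_dim")
  stopifnot(all(field_dim(stack) == fd))
  ncyc <- n_cycles(stack)
  if (is.null(shifts)) {
    shifts <- data.frame(cycle = seq_len(ncyc), dx = 0L, dy = 0L)
  }
  stopifnot(nrow(shifts) >= ncyc)
  ann <- spot_annuli(spots, annulus_width)
  n <- nrow(spots)
  partial <- rep(FALSE, n)
  for (cyc in seq_len(ncyc)) {
    dx <- shifts$dx[cyc]; dy <- shifts$dy[cyc]
    planes <- lapply(BASES, function(b) get_plane(stack, cyc, b))
    for (b in 1:4) {
      col <- sprintf("c%d_%s", cyc, BASES[b])
      spots[[col]] <- NA_real_
    }
    for (i in seq_len(n)) {
      sm <- shift_idx(spots$mask[[i]], dx, dy, fd)
      sa <- shift_idx(ann[[i]], dx, dy, fd)
      if (!sm$complete) partial[i] <- TRUE
      if (length(sm$idx) == 0L) next
      for (b in 1:4) {
        bgv <- if (length(sa$idx) > 0)
          stats::median(planes[[b]][sa$idx]) else 0
        spots[[sprintf("c%d_%s", cyc, BASES[b])]][i] <-
          mean(planes[[b]][sm$idx]) - bgv
      }
    }
  }
  spots$partially_measured <- partial
  spots
}
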