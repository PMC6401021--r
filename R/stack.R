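#' Multi-cycle, multi-channel ISS image stack
#'
#' An `iss_stack` holds the raw input to all readout analysis: a
#' four-dimensional non-negative intensity array indexed
#' `[cycle, channel, row, col]` together with the role of every channel
#' and the physical pixel size.  The six canonical channels of a
#' sequencing-by-ligation acquisition are the nuclear stain (`DAPI`),
#' the anchor-primer stain used for spot detection (`ANCHOR`), and one
#' channel per base-specific sequencing probe (`A`, `C`, `G`, `T`).
#'
#' @param data numeric array `[cycle, channel, row, col]`, finite and
#'   non-negative.
#' @param channel_roles character vector naming each channel along
#'   `dim(data)[2]`.  Must contain `DAPI` and `ANCHOR` exactly once and
#'   the four base channels `A`, `C`, `G`, `T` exactly once each.
#' @param pixel_size physical pixel size in micrometres per pixel.
#'
#' @return An object of class `iss_stack`: a list with elements `data`,
#'   `channel_roles` and `pixel_size`.
#' @export
#' @examples
#' arr <- array(0, dim = c(1, 6, 8, 8))
#' s <- iss_stack(arr, pixel_size = 0.32)
#' n_cycles(s)
iss_stack <- function(data,
                      channel_roles = c("DAPI", "ANCHOR", "A", "C", "G", "T"),
                      pixel_size = 0.32) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    stop("`data` must be a 4-d array [cycle, channel, row, col]", call. = FALSE)
  }
  if (dim(data)[2] != length(channel_roles)) {
    stop("length(channel_roles) must equal dim(data)[2]", call. = FALSE)
  }
  validate_channel_roles(channel_roles)
  if (anyNA(data) || any(!is.finite(data))) {
    stop("stack intensities must be finite", call. = FALSE)
  }
  if (any(data < 0)) {
    stop("stack intensities must be non-negative", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  }
  structure(
    list(data = data, channel_roles = as.character(channel_roles),
         pixel_size = as.numeric(pixel_size)),
    class = "iss_stack"
  )
}

validate_channel_roles <- function(roles) {
  required <- c("DAPI", "ANCHOR", "A", "C", "G", "T")
  unknown <- setdiff(roles, required)
  if (length(unknown) > 0) {
    stop("unknown channel roles: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(roles, levels = required))
  if (any(counts != 1L)) {
    bad <- names(counts)[counts != 1L]
    stop("each channel role must appear exactly once; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(roles)
}

#' @rdname iss_stack
#' @param x an `iss_stack`.
#' @export
n_cycles <- function(x) {
  stopifnot(inherits(x, "iss_stack"))
  dim(x$data)[1]
}

#' @rdname iss_stack
#' @export
field_dim <- function(x) {
  stopifnot(inherits(x, "iss_stack"))
  dim(x$data)[3:4]
}

#' Extract one image plane from a stack
#'
#' @param x an `iss_stack`.
#' @param cycle cycle index (1-based).
#' @param channel channel role name (e.g. `"ANCHOR"`) or index.
#' @return A numeric matrix `[row, col]`.
#' @export
get_plane <- function(x, cycle, channel) {
  stopifnot(inherits(x, "iss_stack"))
  if (is.character(channel)) {
    idx <- match(channel, x$channel_roles)
    if (is.na(idx)) stop("no channel with role ", channel, call. = FALSE)
    channel <- idx
  }
  if (cycle < 1 || cycle > n_cycles(x)) {
    stop("cycle index out of range", call. = FALSE)
  }
  x$data[cycle, channel, , ]
}

#' @export
print.iss_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "iss_stack: %d cycle(s) x %d channel(s) x %d x %d px (%.3g um/px)\n",
    d[1], d[2], d[3], d[4], x$pixel_size))
  cat("channels:", paste(x$channel_roles, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read an image stack as multi-page TIFF
#'
#' Planes are stored cycle-major, channel-minor (all channels of cycle 1,
#' then all channels of cycle 2, ...), as 16-bit greyscale pages.
#' Channel roles, pixel size and cycle count travel in a JSON sidecar
#' file (`<path>.json`), so the pair is self-describing and any TIFF
#' with a matching sidecar can be read back.  Intensities are rounded
#' to integers and clipped to \[0, 65535\] on write; the round trip is
#' lossless for integer-valued 16-bit data, which is what the simulator
#' emits.
#'
#' @param stack an `iss_stack`.
#' @param path file path of the TIFF to write or read; the sidecar
#'   lives at `paste0(path, ".json")`.
#' @return `write_stack()` returns `path` invisibly; `read_stack()`
#'   returns an `iss_stack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "iss_stack"))
  d <- dim(stack$data)
  planes <- vector("list", d[1] * d[2])
  k <- 1L
  for (cyc in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      m <- round(stack$data[cyc, ch, , ])
      m[m < 0] <- 0
      m[m > 65535] <- 65535
      planes[[k]] <- m / 65535
      k <- k + 1L
    }
  }
  tiff::writeTIFF(planes, path, bits.per.sample = 16L, reduce = FALSE)
  jsonlite::write_json(
    list(channel_roles = stack$channel_roles,
         pixel_size = stack$pixel_size,
         n_cycles = d[1]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("no channel-role sidecar (", sidecar, "); not an issread stack",
         call. = FALSE)
  }
  planes <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::fromJSON(sidecar)
  roles <- as.character(meta$channel_roles)
  validate_channel_roles(roles)
  ncyc <- as.integer(meta$n_cycles)
  nch <- length(roles)
  if (length(planes) != ncyc * nch) {
    stop(sprintf("expected %d planes (%d cycles x %d channels), found %d",
                 ncyc * nch, ncyc, nch, length(planes)), call. = FALSE)
  }
  fd <- dim(planes[[1]])
  arr <- array(0, dim = c(ncyc, nch, fd[1], fd[2]))
  k <- 1L
  for (cyc in seq_len(ncyc)) {
    for (ch in seq_len(nch)) {
      arr[cyc, ch, , ] <- round(planes[[k]] * 65535)
      k <- k + 1L
    }
  }
  iss_stack(arr, channel_roles = roles, pixel_size = meta$pixel_size)
}
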