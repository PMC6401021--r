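#' Barcode codebook
#'
#' Maps barcode strings over the alphabet `{A,C,G,T}` to target
#' identifiers.  A read matching an entry is *expected*; any other
#' sequence of the right length is *unexpected*.  With `n` sequencing
#' cycles the design space holds `4^n` sequences, so a codebook with `k`
#' entries leaves `4^n - k` unexpected sequences (4 expected and 252
#' unexpected for a 4-entry, 4-cycle design).
#'
#' @param barcodes character vector of unique, equal-length barcode
#'   strings over `{A,C,G,T}`.
#' @param targets target identifiers, one per barcode.  Defaults to the
#'   barcodes themselves.
#' @return A data frame of class `iss_codebook` with columns `barcode`
#'   and `target`; the barcode length is kept in attribute
#'   `barcode_length`.
#' @export
#' @examples
#' cb <- codebook(c("ACGT", "CGTA", "GTAC", "TACG"), rep("Actb", 4))
#' unexpected_capacity(4, nrow(cb))
codebook <- function(barcodes, targets = barcodes) {
  barcodes <- toupper(as.character(barcodes))
  if (length(barcodes) == 0L) stop("codebook must be non-empty", call. = FALSE)
  if (length(targets) != length(barcodes)) {
    stop("one target per barcode required", call. = FALSE)
  }
  len <- unique(nchar(barcodes))
  if (length(len) != 1L) {
    stop("all barcodes must have the same length", call. = FALSE)
  }
  if (!all(strsplit(paste(barcodes, collapse = ""), "")[[1]] %in% BASES)) {
    stop("barcodes must use only the alphabet A, C, G, T", call. = FALSE)
  }
  if (anyDuplicated(barcodes)) {
    stop("barcodes must be unique", call. = FALSE)
  }
  if (length(barcodes) > 4^len) {
    stop("more entries than the 4^n design space", call. = FALSE)
  }
  out <- data.frame(barcode = barcodes, target = as.character(targets),
                    stringsAsFactors = FALSE)
  attr(out, "barcode_length") <- len
  class(out) <- c("iss_codebook", "data.frame")
  out
}

#' @rdname codebook
#' @param n_cycles number of sequencing cycles.
#' @export
codebook_capacity <- function(n_cycles) {
  if (n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)
  4^n_cycles
}

#' @rdname codebook
#' @param n_entries number of designed barcodes.
#' @export
unexpected_capacity <- function(n_cycles, n_entries) {
  cap <- codebook_capacity(n_cycles)
  if (n_entries < 0 || n_entries > cap) {
    stop("n_entries must lie in [0, 4^n_cycles]", call. = FALSE)
  }
  cap - n_entries
}

#' Truncate a codebook to the first k barcode positions
#'
#' Emulates a lower-plex design read after only `k` cycles.  Fails if
#' truncation makes any two barcodes collide.
#'
#' @param cb an [codebook()].
#' @param k number of leading positions to keep.
#' @return An `iss_codebook` with length-`k` barcodes.
#' @export
truncate_codebook <- function(cb, k) {
  stopifnot(inherits(cb, "iss_codebook"))
  len <- attr(cb, "barcode_length")
  if (k < 1 || k > len) stop("k must lie in [1, barcode length]", call. = FALSE)
  short <- substr(cb$barcode, 1L, k)
  dup <- duplicated(short) | duplicated(short, fromLast = TRUE)
  if (any(dup)) {
    stop("truncation to ", k, " cycles collides: ",
         paste(unique(cb$barcode[dup]), collapse = ", "), call. = FALSE)
  }
  codebook(short, cb$target)
}

#' Classify a read sequence against a codebook
#'
#' Exact-match lookup with no error correction: a sequence matching an
#' entry is `expected` (with its target), anything else `unexpected`.
#'
#' @param sequence character vector of read sequences.
#' @param cb an [codebook()].
#' @return A data frame with columns `sequence`, `status` and `target`
#'   (`NA` for unexpected reads).
#' @export
classify_read <- function(sequence, cb) {
  stopifnot(inherits(cb, "iss_codebook"))
  len <- attr(cb, "barcode_length")
  if (any(nchar(sequence) != len)) {
    stop("sequence length must equal the barcode length (", len, ")",
         call. = FALSE)
  }
  hit <- match(sequence, cb$barcode)
  data.frame(sequence = sequence,
             status = ifelse(is.na(hit), "unexpected", "expected"),
             target = cb$target[hit],
             stringsAsFactors = FALSE)
}
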