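#' Segment nuclei in a DAPI image
#'
#' Nuclei provide the per-cell denominator for RCP yield and reads per
#' cell.  Segmentation is deliberately simple: Gaussian smoothing, Otsu
#' global threshold, then a watershed on the distance map to split
#' touching nuclei.
#'
#' @param dapi_image numeric matrix of the nuclear-stain channel.
#' @param sigma Gaussian smoothing width, pixels.
#' @param min_area minimum nucleus area, pixels.
#' @return A list of class `iss_cellmap` with `labels` (integer matrix,
#'   0 = no cell) and `centroids` (data frame `cell_id, x, y` with `x` =
#'   row, `y` = col, 1-based).  A blank image yields an empty map.
#' @export
segment_cells <- function(dapi_image, sigma = 2, min_area = 50L) {
  fd <- dim(dapi_image)
  empty <- structure(
    list(labels = matrix(0L, fd[1], fd[2]),
         centroids = data.frame(cell_id = integer(0), x = numeric(0),
                                y = numeric(0))),
    class = "iss_cellmap")
  mx <- max(dapi_image)
  if (mx <= 0) return(empty)

  xs <- EBImage::gblur(dapi_image / mx, sigma = sigma)
  thr <- EBImage::otsu(EBImage::Image(xs), range = c(0, 1))
  mask <- xs > thr
  if (!any(mask)) return(empty)

  dmap <- EBImage::distmap(mask)
  lab <- as.matrix(EBImage::watershed(dmap, tolerance = 1, ext = 1L))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  if (length(keep) == 0L) return(empty)

  relabel <- integer(max(lab) + 1L)
  relabel[keep + 1L] <- seq_along(keep)
  labels <- matrix(relabel[lab + 1L], fd[1], fd[2])
  cent <- data.frame(cell_id = seq_along(keep), x = NA_real_, y = NA_real_)
  for (i in seq_along(keep)) {
    rc <- idx_to_rc(which(labels == i), fd[1])
    cent$x[i] <- mean(rc[, 1]); cent$y[i] <- mean(rc[, 2])
  }
  structure(list(labels = labels, centroids = cent), class = "iss_cellmap")
}

#' Assign detected spots to cells
#'
#' Each spot is assigned to the nearest nucleus centroid within
#' `max_dist` micrometres; spots farther than that from every nucleus
#' stay unassigned (`cell_id = NA`).
#'
#' @param spots an `iss_spots` data frame.
#' @param cells an `iss_cellmap` from [segment_cells()].
#' @param max_dist maximum spot-to-centroid distance, micrometres.
#' @param pixel_size micrometres per pixel, used to convert `max_dist`.
#' @return `spots` with the `cell_id` column filled.
#' @export
assign_spots_to_cells <- function(spots, cells, max_dist = 30,
                                  pixel_size = 0.32) {
  stopifnot(inherits(spots, "iss_spots"), inherits(cells, "iss_cellmap"))
  spots$cell_id <- NA_integer_
  if (nrow(cells$centroids) == 0L || nrow(spots) == 0L) return(spots)
  max_px <- max_dist / pixel_size
  cx <- cells$centroids$x; cy <- cells$centroids$y
  for (i in seq_len(nrow(spots))) {
    d2 <- (cx - spots$x[i])^2 + (cy - spots$y[i])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) <= max_px) {
      spots$cell_id[i] <- cells$centroids$cell_id[j]
    }
  }
  spots
}
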