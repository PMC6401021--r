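#' Write condition metrics, PE tables and summary figures
#'
#' Emits the standard result files of a readout run into `out_dir`:
#' `metrics.csv` (one row per condition), `pe.csv` (one row per PE
#' comparison), optionally `per_cycle_quality.csv`, a stacked per-base
#' quality bar figure, and a reads-over-DAPI overlay figure when an
#' overlay input is given.  Empty inputs yield headers-only CSVs.
#'
#' @param metrics data frame of condition metrics
#'   (rows from [condition_metrics()]); may have zero rows.
#' @param pe data frame of PE rows from [performance_efficiency()]; may
#'   be `NULL` or empty.
#' @param per_cycle optional per-cycle quality table from
#'   [per_cycle_quality()].
#' @param stacked optional result of [stacked_quality()] to plot.
#' @param overlay optional list for the spatial figure: `dapi` (matrix),
#'   `spots` (data frame with `x`, `y`) and optionally `status` per
#'   spot.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(metrics, pe = NULL, per_cycle = NULL,
                         stacked = NULL, overlay = NULL, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  written <- character(0)

  if (is.null(metrics)) {
    metrics <- condition_metrics_template()
  }
  f <- file.path(out_dir, "metrics.csv")
  utils::write.csv(metrics, f, row.names = FALSE)
  written <- c(written, f)

  if (is.null(pe)) {
    pe <- data.frame(metric = character(0), on_value = numeric(0),
                     off_value = numeric(0), pe = numeric(0),
                     pe_paired = numeric(0),
                     pe_ratio_of_means = numeric(0),
                     aggregation = character(0), n_pairs = integer(0))
  }
  f <- file.path(out_dir, "pe.csv")
  utils::write.csv(pe, f, row.names = FALSE)
  written <- c(written, f)

  if (!is.null(per_cycle)) {
    f <- file.path(out_dir, "per_cycle_quality.csv")
    utils::write.csv(per_cycle, f, row.names = FALSE)
    written <- c(written, f)
  }

  if (!is.null(stacked)) {
    df <- data.frame(base = factor(names(stacked$contributions),
                                   levels = rev(BASES)),
                     contribution = as.numeric(stacked$contributions))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = "on / off",
                                          y = contribution,
                                          fill = base)) +
      ggplot2::geom_col() +
      ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
      ggplot2::labs(x = NULL, y = "normalized stacked quality",
                    fill = "base") +
      ggplot2::theme_minimal()
    f <- file.path(out_dir, "stacked_quality.png")
    ggplot2::ggsave(f, p, width = 3.5, height = 4, dpi = 150)
    written <- c(written, f)
  }

  if (!is.null(overlay)) {
    dapi <- overlay$dapi
    dd <- data.frame(expand.grid(x = seq_len(nrow(dapi)),
                                 y = seq_len(ncol(dapi))),
                     value = as.vector(dapi))
    sp <- overlay$spots
    sp$status <- if (!is.null(overlay$status)) overlay$status else "read"
    p <- ggplot2::ggplot() +
      ggplot2::geom_raster(data = dd,
                           ggplot2::aes(x = y, y = x,
                                        fill = value)) +
      ggplot2::scale_fill_gradient(low = "black", high = "grey70",
                                   guide = "none") +
      ggplot2::geom_point(data = sp,
                          ggplot2::aes(x = y, y = x,
                                       colour = status),
                          size = 1) +
      ggplot2::scale_y_reverse() +
      ggplot2::coord_fixed() +
      ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
      ggplot2::theme_void()
    f <- file.path(out_dir, "reads_overlay.png")
    ggplot2::ggsave(f, p, width = 5, height = 5, dpi = 150)
    written <- c(written, f)
  }

  invisible(written)
}

condition_metrics_template <- function() {
  data.frame(condition = character(0), n_cells = integer(0),
             n_spots = integer(0), rcp_yield = numeric(0),
             mean_snr = numeric(0), reads_per_cell_expected = numeric(0),
             reads_per_cell_unexpected = numeric(0), accuracy = numeric(0),
             n_discarded = integer(0), stringsAsFactors = FALSE)
}
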