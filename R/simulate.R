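#' Configuration for the synthetic ISS sample generator
#'
#' Bundles every knob of the simulator with defaults emulating a
#' mouse-embryonic-fibroblast experiment in which four padlock probes
#' with orthogonal four-letter barcodes all report the same transcript.
#' Rolling circle products (RCPs) are rendered as Gaussian spots of
#' roughly one micrometre diameter at the default pixel size, clustered
#' around disk-shaped nuclei.
#'
#' @param field_size integer `(rows, cols)` of the imaged field, pixels.
#' @param pixel_size micrometres per pixel.  The default 0.32 um/px is
#'   typical of the 20-40x epifluorescence setups used for ISS and makes
#'   a `spot_sigma` of 1.5 px render ~1 um spots.
#' @param n_cells number of cells in the field.
#' @param nucleus_radius `(mean, sd)` of nucleus radii, pixels.
#' @param cell_radius radius around a nucleus centroid within which that
#'   cell's RCPs are placed, pixels.
#' @param rcps_per_cell expected RCP count per cell (Poisson mean).
#' @param spot_sigma Gaussian PSF width of a rendered RCP, pixels.
#' @param amplitude `(meanlog, sdlog)` of the log-normal peak amplitude
#'   of a spot, arbitrary camera units.
#' @param dapi_level nuclear stain plateau intensity, arbitrary units.
#' @param background_level additive background per channel; a scalar or
#'   a vector of length 6 ordered as (DAPI, ANCHOR, A, C, G, T).
#' @param read_noise_sd standard deviation of additive Gaussian camera
#'   read noise, arbitrary units.
#' @param shot_noise logical; apply Poisson shot noise to signal plus
#'   background?  Turn off (with `read_noise_sd = 0`) for noise-free
#'   renders.
#' @param crosstalk 4x4 mixing matrix, rows = true base (A,C,G,T),
#'   columns = observed channel; rows should sum to ~1.
#' @param strip_residue fraction in \[0,1\] of the previous cycle's
#'   base-channel signal persisting after probe stripping.
#' @param dropout_prob per-cycle probability that a spot yields no
#'   signal in that cycle.
#' @param jitter_sd standard deviation, in pixels, of the per-cycle
#'   rigid stage shift (rounded to integer pixels; cycle 1 is the
#'   unshifted reference).
#' @param min_spot_separation minimum distance between any two spots,
#'   pixels.  0 (default) places spots independently; positive values
#'   use rejection sampling to build well-separated fields for
#'   resolution-controlled experiments (extra uniform draws enter the
#'   RNG stream between the radial-distance and barcode draws).
#' @param n_cycles number of sequencing-by-ligation cycles (2-4).
#' @param codebook_barcodes character vector of barcode strings over
#'   `{A,C,G,T}`, all of length `n_cycles`.  The default four barcodes
#'   are position-orthogonal: at every position each base occurs once.
#' @param seed integer seed; identical configurations produce
#'   bit-identical output.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(field_size = c(384L, 384L),
                       pixel_size = 0.32,
                       n_cells = 8L,
                       nucleus_radius = c(14, 2),
                       cell_radius = 40,
                       rcps_per_cell = 40,
                       spot_sigma = 1.5,
                       amplitude = c(meanlog = log(6000), sdlog = 0.35),
                       dapi_level = 1200,
                       background_level = 200,
                       read_noise_sd = 10,
                       shot_noise = TRUE,
                       crosstalk = default_crosstalk(),
                       strip_residue = 0.1,
                       dropout_prob = 0.01,
                       jitter_sd = 1,
                       min_spot_separation = 0,
                       n_cycles = 4L,
                       codebook_barcodes = c("ACGT", "CGTA", "GTAC", "TACG"),
                       seed = 1L) {
  cfg <- list(
    field_size = as.integer(field_size), pixel_size = pixel_size,
    n_cells = as.integer(n_cells), nucleus_radius = nucleus_radius,
    cell_radius = cell_radius, rcps_per_cell = rcps_per_cell,
    spot_sigma = spot_sigma, amplitude = amplitude,
    dapi_level = dapi_level,
    background_level = if (length(background_level) == 1L)
      rep(background_level, 6L) else background_level,
    read_noise_sd = read_noise_sd, shot_noise = isTRUE(shot_noise),
    crosstalk = crosstalk, strip_residue = strip_residue,
    dropout_prob = dropout_prob, jitter_sd = jitter_sd,
    min_spot_separation = min_spot_separation,
    n_cycles = as.integer(n_cycles),
    codebook_barcodes = toupper(codebook_barcodes),
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_crosstalk <- function() {
  m <- matrix(0.05, 4, 4, dimnames = list(BASES, BASES))
  diag(m) <- 0.85
  m
}

BASES <- c("A", "C", "G", "T")

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$field_size) == 2L)
  if (any(cfg$field_size < 16L)) {
    stop("field_size must be at least 16 px in each dimension", call. = FALSE)
  }
  if (cfg$n_cells < 0L || cfg$rcps_per_cell < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (cfg$spot_sigma <= 0) stop("spot_sigma must be > 0", call. = FALSE)
  for (p in c("strip_residue", "dropout_prob")) {
    v <- cfg[[p]]
    if (v < 0 || v > 1) stop(p, " must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$min_spot_separation < 0) {
    stop("min_spot_separation must be non-negative", call. = FALSE)
  }
  if (any(cfg$background_level < 0) || cfg$read_noise_sd < 0 ||
      cfg$jitter_sd < 0 || cfg$dapi_level < 0) {
    stop("intensity and noise parameters must be non-negative",
         call. = FALSE)
  }
  if (!(cfg$n_cycles %in% 2:4)) {
    stop("n_cycles must be 2, 3 or 4", call. = FALSE)
  }
  if (!all(dim(cfg$crosstalk) == c(4L, 4L))) {
    stop("crosstalk must be a 4x4 matrix", call. = FALSE)
  }
  bcs <- cfg$codebook_barcodes
  if (length(bcs) < 1L) stop("codebook_barcodes must be non-empty", call. = FALSE)
  if (any(nchar(bcs) != cfg$n_cycles)) {
    stop("all barcodes must have length n_cycles (", cfg$n_cycles, ")",
         call. = FALSE)
  }
  if (!all(strsplit(paste(bcs, collapse = ""), "")[[1]] %in% BASES)) {
    stop("barcodes must use only the alphabet A, C, G, T", call. = FALSE)
  }
  if (anyDuplicated(bcs)) stop("barcodes must be unique", call. = FALSE)
  if (cfg$n_cells == 0L && cfg$rcps_per_cell > 0) {
    stop("rcps_per_cell > 0 requires n_cells > 0", call. = FALSE)
  }
  invisible(cfg)
}

#' Render Gaussian spots into an image plane
#'
#' Low-level renderer used by the simulator and handy for constructing
#' controlled detection fixtures.  Each spot is an isotropic Gaussian of
#' peak height `amplitude` truncated at a 4-sigma window.
#'
#' @param dim integer `(rows, cols)`.
#' @param x,y spot centre coordinates, 1-based (row, col); may be
#'   fractional.
#' @param amplitude peak amplitudes (recycled).
#' @param sigma Gaussian width in pixels.
#' @return A numeric matrix of the summed spot intensities.
#' @export
render_spot_field <- function(dim, x, y, amplitude, sigma = 1.5) {
  img <- matrix(0, dim[1], dim[2])
  if (length(x) == 0L) return(img)
  amplitude <- rep_len(amplitude, length(x))
  w <- ceiling(4 * sigma)
  for (i in seq_along(x)) {
    r0 <- max(1L, floor(x[i] - w)); r1 <- min(dim[1], ceiling(x[i] + w))
    c0 <- max(1L, floor(y[i] - w)); c1 <- min(dim[2], ceiling(y[i] + w))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    g <- exp(-(outer((rr - x[i])^2, (cc - y[i])^2, "+")) / (2 * sigma^2))
    img[rr, cc] <- img[rr, cc] + amplitude[i] * g
  }
  img
}

render_nuclei <- function(dim, x, y, radius, level) {
  img <- matrix(0, dim[1], dim[2])
  for (i in seq_along(x)) {
    w <- ceiling(radius[i]) + 1L
    r0 <- max(1L, floor(x[i] - w)); r1 <- min(dim[1], ceiling(x[i] + w))
    c0 <- max(1L, floor(y[i] - w)); c1 <- min(dim[2], ceiling(y[i] + w))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - x[i])^2, (cc - y[i])^2, "+")
    img[rr, cc] <- pmax(img[rr, cc], level * (d2 <= radius[i]^2))
  }
  img
}

#' Generate a synthetic multi-cycle ISS sample with ground truth
#'
#' Draws cell and spot geometry, barcodes and amplitudes from a single
#' seeded RNG stream, then renders, per cycle: the nuclear stain; the
#' anchor stain at every non-dropped spot; and base-channel signal
#' placed in the channel of each spot's barcode letter for that cycle,
#' mixed through the crosstalk matrix, with `strip_residue` of the
#' previous cycle's (mixed) base signal carried over.  Background,
#' Poisson shot noise and Gaussian read noise are then applied and
#' intensities quantised to 16-bit camera counts.
#'
#' The RNG draw order is part of the contract (it makes replay oracles
#' possible): with `set.seed(seed)`, the generator draws, in order,
#' (1) cell centroid rows, (2) cell centroid columns, (3) nucleus radii,
#' (4) per-cell spot counts `rpois(n_cells, rcps_per_cell)`,
#' (5) per-spot placement angles, (6) per-spot radial distances,
#' (7) per-spot barcode indices, (8) per-spot amplitudes,
#' (9) per-cycle jitter shifts (cycles 2..n, dx then dy),
#' (10) the spot-by-cycle dropout uniforms (spot index fastest), and
#' finally the per-plane noise in plane order (cycle-major,
#' channel-minor; shot noise before read noise).
#'
#' @param config a [sim_config()].
#' @return A list with elements `stack` (an [iss_stack()]) and `truth`,
#'   where `truth` is a list of class `iss_truth` with data frames
#'   `spots` (`id, x, y, barcode, cell_id, amplitude, dropped_cycles`),
#'   `cells` (`cell_id, x, y, radius`), `shifts` (`cycle, dx, dy`), the
#'   logical dropout matrix `dropped` (spots by cycles), and a `config`
#'   echo.  `x` is the row and `y` the column coordinate, 1-based.
#' @export
generate_sample <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  sample_latents_and_render(config)
}

sample_latents_and_render <- function(config) {
  fd <- config$field_size
  ncells <- config$n_cells
  margin <- config$cell_radius + 2

  # (1)-(3) cell geometry
  cx <- runif(ncells, 1 + margin, fd[1] - margin)
  cy <- runif(ncells, 1 + margin, fd[2] - margin)
  cr <- pmax(2, stats::rnorm(ncells, config$nucleus_radius[1],
                             config$nucleus_radius[2]))

  # (4) spot counts
  nspots_per_cell <- if (ncells > 0L)
    stats::rpois(ncells, config$rcps_per_cell) else integer(0)
  nspots <- sum(nspots_per_cell)
  cell_of_spot <- rep(seq_len(ncells), nspots_per_cell)

  # (5)-(8) spot placement, barcode, amplitude
  minsep <- config$min_spot_separation
  if (minsep <= 0) {
    ang <- runif(nspots, 0, 2 * pi)
    rad <- config$cell_radius * sqrt(runif(nspots))
    sx <- pmin(pmax(cx[cell_of_spot] + rad * cos(ang), 2), fd[1] - 1)
    sy <- pmin(pmax(cy[cell_of_spot] + rad * sin(ang), 2), fd[2] - 1)
  } else {
    sx <- numeric(nspots); sy <- numeric(nspots)
    for (i in seq_len(nspots)) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        a <- runif(1, 0, 2 * pi)
        r <- config$cell_radius * sqrt(runif(1))
        px <- min(max(cx[cell_of_spot[i]] + r * cos(a), 2), fd[1] - 1)
        py <- min(max(cy[cell_of_spot[i]] + r * sin(a), 2), fd[2] - 1)
        if (i == 1L ||
            min((sx[seq_len(i - 1L)] - px)^2 +
                (sy[seq_len(i - 1L)] - py)^2) >= minsep^2) {
          sx[i] <- px; sy[i] <- py; placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("cannot place spots ", minsep,
             " px apart at this density; lower rcps_per_cell",
             call. = FALSE)
      }
    }
  }
  bc_idx <- if (nspots > 0L)
    sample.int(length(config$codebook_barcodes), nspots, replace = TRUE)
  else integer(0)
  barcode <- config$codebook_barcodes[bc_idx]
  amp <- stats::rlnorm(nspots, config$amplitude[1], config$amplitude[2])

  # (9) per-cycle jitter, cycle 1 is the reference
  ncyc <- config$n_cycles
  shifts <- matrix(0L, ncyc, 2L)
  for (cyc in seq_len(ncyc)[-1]) {
    shifts[cyc, ] <- as.integer(round(stats::rnorm(2, 0, config$jitter_sd)))
  }

  # (10) dropout
  dropped <- matrix(runif(nspots * ncyc) < config$dropout_prob,
                    nrow = nspots, ncol = ncyc)

  roles <- c("DAPI", "ANCHOR", BASES)
  arr <- array(0, dim = c(ncyc, 6L, fd[1], fd[2]))
  base_letters <- if (nspots > 0L)
    do.call(rbind, strsplit(barcode, "")) else
    matrix(character(0), 0, ncyc)

  prev_base <- NULL
  for (cyc in seq_len(ncyc)) {
    dx <- shifts[cyc, 1]; dy <- shifts[cyc, 2]
    live <- if (nspots > 0L) !dropped[, cyc] else logical(0)

    dapi <- render_nuclei(fd, cx + dx, cy + dy, cr, config$dapi_level)
    anchor <- render_spot_field(fd, sx[live] + dx, sy[live] + dy,
                                amp[live], config$spot_sigma)

    clean <- array(0, dim = c(4L, fd[1], fd[2]))
    for (b in 1:4) {
      sel <- live & base_letters[, cyc] == BASES[b]
      clean[b, , ] <- render_spot_field(fd, sx[sel] + dx, sy[sel] + dy,
                                        amp[sel], config$spot_sigma)
    }
    mixed <- array(0, dim = c(4L, fd[1], fd[2]))
    for (ch in 1:4) {
      for (b in 1:4) {
        mixed[ch, , ] <- mixed[ch, , ] + config$crosstalk[b, ch] * clean[b, , ]
      }
    }
    if (!is.null(prev_base) && config$strip_residue > 0) {
      mixed <- mixed + config$strip_residue * prev_base
    }
    prev_base <- mixed

    arr[cyc, 1, , ] <- dapi
    arr[cyc, 2, , ] <- anchor
    for (b in 1:4) arr[cyc, 2 + b, , ] <- mixed[b, , ]
  }

  # background + noise, plane order
  for (cyc in seq_len(ncyc)) {
    for (ch in 1:6) {
      plane <- arr[cyc, ch, , ] + config$background_level[ch]
      if (config$shot_noise) {
        plane <- matrix(stats::rpois(length(plane), lambda = plane),
                        nrow = fd[1])
      }
      if (config$read_noise_sd > 0) {
        plane <- plane + stats::rnorm(length(plane), 0, config$read_noise_sd)
      }
      plane <- round(plane)
      plane[plane < 0] <- 0
      plane[plane > 65535] <- 65535
      arr[cyc, ch, , ] <- plane
    }
  }

  truth <- structure(list(
    spots = data.frame(
      id = seq_len(nspots), x = sx, y = sy, barcode = barcode,
      cell_id = cell_of_spot, amplitude = amp,
      stringsAsFactors = FALSE),
    cells = data.frame(cell_id = seq_len(ncells), x = cx, y = cy,
                       radius = cr),
    shifts = data.frame(cycle = seq_len(ncyc), dx = shifts[, 1],
                        dy = shifts[, 2]),
    dropped = dropped,
    config = config), class = "iss_truth")

  list(stack = iss_stack(arr, channel_roles = roles,
                         pixel_size = config$pixel_size),
       truth = truth)
}

#' Generate a matched on-chip / off-chip condition pair
#'
#' Produces two samples intended to differ only in the parameters the
#' caller varies (e.g. spot density or amplitude), for
#' performance-efficiency comparisons of a device-run condition against
#' its manual control.  Both configurations must share the same
#' codebook.
#'
#' @param config_on,config_off [sim_config()] objects with identical
#'   `codebook_barcodes`.
#' @return A list with elements `on` and `off`, each as returned by
#'   [generate_sample()].
#' @export
generate_paired_conditions <- function(config_on, config_off) {
  validate_sim_config(config_on)
  validate_sim_config(config_off)
  if (!identical(config_on$codebook_barcodes, config_off$codebook_barcodes)) {
    stop("paired conditions must share the same codebook", call. = FALSE)
  }
  list(on = generate_sample(config_on), off = generate_sample(config_off))
}

#' Generate a matched pre-/post-strip stack pair
#'
#' Renders one stained acquisition and its post-strip re-image: the
#' post-strip stack shares all geometry, anchor and nuclear signal with
#' the pre-strip stack but carries only `strip_residue` times the
#' stained base-channel signal, plus the usual background and noise.
#' Used to exercise stripping-efficiency estimation against a known
#' residue fraction.
#'
#' @param config a [sim_config()]; only the first cycle is rendered.
#' @return A list with elements `pre` and `post` (both [iss_stack()])
#'   and `truth`.
#' @export
simulate_strip_pair <- function(config) {
  validate_sim_config(config)
  cfg0 <- config
  cfg0$strip_residue <- 0
  cfg0$shot_noise <- FALSE
  rn <- cfg0$read_noise_sd
  cfg0$read_noise_sd <- 0
  bg <- cfg0$background_level
  cfg0$background_level <- rep(0, 6L)
  set.seed(config$seed)
  clean <- sample_latents_and_render(cfg0)

  finish <- function(arr, scale_bases) {
    for (b in 3:6) arr[, b, , ] <- scale_bases * arr[, b, , ]
    fd <- dim(arr)[3:4]
    for (cyc in seq_len(dim(arr)[1])) {
      for (ch in 1:6) {
        plane <- arr[cyc, ch, , ] + bg[ch]
        if (config$shot_noise) {
          plane <- matrix(stats::rpois(length(plane), plane), nrow = fd[1])
        }
        if (rn > 0) plane <- plane + stats::rnorm(length(plane), 0, rn)
        plane <- round(plane)
        plane[plane < 0] <- 0
        plane[plane > 65535] <- 65535
        arr[cyc, ch, , ] <- plane
      }
    }
    arr
  }

  pre <- finish(clean$stack$data, 1)
  post <- finish(clean$stack$data, config$strip_residue)
  list(pre = iss_stack(pre, pixel_size = config$pixel_size),
       post = iss_stack(post, pixel_size = config$pixel_size),
       truth = clean$truth)
}
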