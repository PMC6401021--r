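#' Reaction-chamber geometry
#'
#' Describes the two chamber formats of an ISS run: the shallow slab
#' chamber a microfluidic processor clamps over the slide, and the
#' cylindrical stick-on hybridization chamber of the manual protocol.
#' The chamber height is the diffusion-relevant dimension: reagents
#' enter the full chamber volume and must diffuse down to the sample
#' surface.
#'
#' @param geometry `"slab"` or `"cylinder"`.
#' @param length,width slab footprint, mm.
#' @param diameter cylinder diameter, mm.
#' @param height chamber height, mm.
#' @return A list of class `chamber_spec` with the given dimensions and
#'   the derived `volume_ul` (microlitres) and `height_um`.
#' @export
#' @examples
#' chamber_spec("slab", length = 17, width = 17, height = 0.1)$volume_ul
chamber_spec <- function(geometry = c("slab", "cylinder"), length = NULL,
                         width = NULL, diameter = NULL, height = NULL) {
  geometry <- match.arg(geometry)
  if (is.null(height) || height <= 0) {
    stop("height must be a positive number (mm)", call. = FALSE)
  }
  if (geometry == "slab") {
    if (is.null(length) || is.null(width) || length <= 0 || width <= 0) {
      stop("slab requires positive length and width (mm)", call. = FALSE)
    }
    area_mm2 <- length * width
  } else {
    if (is.null(diameter) || diameter <= 0) {
      stop("cylinder requires a positive diameter (mm)", call. = FALSE)
    }
    area_mm2 <- pi * (diameter / 2)^2
  }
  structure(list(geometry = geometry, length = length, width = width,
                 diameter = diameter, height = height,
                 height_um = height * 1000,
                 volume_ul = area_mm2 * height),
            class = "chamber_spec")
}

#' @rdname chamber_spec
#' @param spec a `chamber_spec`.
#' @return `chamber_volume()` returns the chamber volume in microlitres
#'   (1 mm^3 = 1 uL).
#' @export
chamber_volume <- function(spec) {
  stopifnot(inherits(spec, "chamber_spec"))
  spec$volume_ul
}

#' Characteristic diffusion time over a distance
#'
#' Returns `distance^2 / (alpha * D)`.  The prefactor `alpha` encodes
#' the convention: 1 for the bare characteristic time `x^2/D` (the
#' package default), 2/4/6 for mean-squared-displacement conventions in
#' 1/2/3 dimensions.
#'
#' @param distance distance to traverse, micrometres.
#' @param D diffusion coefficient, square micrometres per second.
#' @param alpha convention prefactor, one of 1, 2, 4, 6.
#' @return Time in seconds.
#' @export
#' @examples
#' diffusion_time(100, 70)   # ~143 s for a ligase-sized enzyme
diffusion_time <- function(distance, D, alpha = 1) {
  if (any(distance <= 0) || any(D <= 0)) {
    stop("distance and D must be positive", call. = FALSE)
  }
  if (!(alpha %in% c(1, 2, 4, 6))) {
    stop("alpha must be one of 1, 2, 4, 6", call. = FALSE)
  }
  distance^2 / (alpha * D)
}

#' Stokes-Einstein diffusion coefficient of a globular protein
#'
#' Estimates the hydrodynamic radius of a protein as that of a sphere
#' of volume `molar_mass * specific_volume` and applies
#' `D = kT / (6 pi eta r)`.
#'
#' @param molar_mass protein mass, kilodaltons.
#' @param temperature absolute temperature, kelvin.
#' @param viscosity solvent viscosity, millipascal-seconds (water at
#'   25 C is ~0.89; 1 is a convenient round default).
#' @param specific_volume partial specific volume, cm^3/g (0.73 is
#'   typical for proteins).
#' @return Diffusion coefficient in square micrometres per second.
#' @export
#' @examples
#' stokes_einstein_D(77)   # ~78 um^2/s for a 77 kDa ligase
stokes_einstein_D <- function(molar_mass, temperature = 298,
                              viscosity = 1, specific_volume = 0.73) {
  if (any(c(molar_mass, temperature, viscosity, specific_volume) <= 0)) {
    stop("all inputs must be positive", call. = FALSE)
  }
  avogadro <- 6.02214076e23
  k_boltzmann <- 1.380649e-23              # J/K
  mass_g <- molar_mass * 1000 / avogadro   # g per molecule
  vol_m3 <- mass_g * specific_volume * 1e-6
  r_m <- (3 * vol_m3 / (4 * pi))^(1 / 3)
  d_m2s <- k_boltzmann * temperature / (6 * pi * viscosity * 1e-3 * r_m)
  d_m2s * 1e12
}

#' Fraction of enzyme molecules beyond diffusive reach
#'
#' Assume enzyme is delivered uniformly over the chamber height with the
#' sample at the bottom face, and that a molecule is useful only if it
#' can diffuse to the sample within its functional half-life.  The
#' diffusive reach is `sqrt(alpha * D * half_life)` (capped at the
#' chamber height) and the stranded fraction is
#' `1 - reach / chamber_height`.  For a phi29-class polymerase
#' (D = 70 um^2/s, half-life 18 min) in an 0.8 mm-deep manual chamber
#' this is ~0.66 — almost two thirds of the enzyme — while in a 100 um
#' microfluidic chamber it is 0, which is the mass-transport case for
#' shallow chambers.
#'
#' @param chamber_height chamber height, micrometres.
#' @param D diffusion coefficient, square micrometres per second.
#' @param half_life functional half-life, seconds.
#' @param alpha diffusion-convention prefactor (see
#'   [diffusion_time()]).
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' fraction_beyond_reach(800, 70, 18 * 60)   # manual chamber, ~0.66
#' fraction_beyond_reach(100, 70, 18 * 60)   # microfluidic chamber, 0
fraction_beyond_reach <- function(chamber_height, D, half_life, alpha = 1) {
  if (any(c(chamber_height, D, half_life) <= 0)) {
    stop("all inputs must be positive", call. = FALSE)
  }
  if (!(alpha %in% c(1, 2, 4, 6))) {
    stop("alpha must be one of 1, 2, 4, 6", call. = FALSE)
  }
  reach <- pmin(chamber_height, sqrt(alpha * D * half_life))
  1 - reach / chamber_height
}

#' Reagent delivery schedule and total delivered amount
#'
#' A programmable processor delivers a reagent as `n` discrete chamber
#' fills of a given volume and concentration, each incubated before the
#' next; the manual protocol is a single fill.  `delivered_amount()` is
#' the total amount of activity (or substance) introduced:
#' `n_deliveries * volume_per_delivery * concentration`.
#'
#' @param n_deliveries number of deliveries (>= 1).
#' @param volume_per_delivery volume per delivery, microlitres.
#' @param concentration units (or nanomoles) per microlitre.
#' @param incubation_per_delivery minutes incubated after each delivery.
#' @param final_incubation minutes of final incubation.
#' @return `delivery_schedule()` returns a validated list of class
#'   `delivery_schedule`; `delivered_amount()` the total delivered
#'   units.
#' @export
#' @examples
#' delivered_amount(delivery_schedule(9, 29, 0.5))   # 130.5 U
delivery_schedule <- function(n_deliveries, volume_per_delivery,
                              concentration, incubation_per_delivery = 0,
                              final_incubation = 0) {
  if (n_deliveries < 1) stop("n_deliveries must be >= 1", call. = FALSE)
  if (volume_per_delivery <= 0 || concentration <= 0) {
    stop("volume and concentration must be positive", call. = FALSE)
  }
  structure(list(n_deliveries = as.integer(n_deliveries),
                 volume_per_delivery = volume_per_delivery,
                 concentration = concentration,
                 incubation_per_delivery = incubation_per_delivery,
                 final_incubation = final_incubation),
            class = "delivery_schedule")
}

#' @rdname delivery_schedule
#' @param schedule a `delivery_schedule`.
#' @export
delivered_amount <- function(schedule) {
  stopifnot(inherits(schedule, "delivery_schedule"))
  schedule$n_deliveries * schedule$volume_per_delivery *
    schedule$concentration
}
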