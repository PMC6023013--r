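# Physical-parameter registry. Every leaf value carries a provenance tag:
# "stated" for values fixed by the reference device description, "assumed"
# for values the model needs but the description leaves open. Configs
# serialize losslessly to YAML.

#' Default physics configuration
#'
#' Returns the fully populated parameter set for one of the simulation
#' profiles. Values tagged `stated` are fixed by the reference device
#' (10 um cell of density 1050 kg/m^3, magnet magnetization 750 kA/m, drive
#' voltages/frequencies); `assumed` values are documented modelling choices
#' (plasma-like Newtonian fluid, bead-laden cell relative permeability 1.15,
#' inlet speeds, magnet block size and standoff).
#'
#' @param profile `"separator"`, `"mixer"` or `"integrated"`.
#' @return object of class `ctc_config`: nested list with sections `fluid`,
#'   `particle`, `medium`, `constants`, `electrokinetics`, `flow`, `magnet`,
#'   `electrodes`, `solver`, plus a `provenance` map of dotted leaf paths.
#' @export
default_config <- function(profile = c("separator", "mixer", "integrated")) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    fluid = list(
      density      = 1000,    # kg/m^3
      viscosity    = 1e-3,    # Pa s (pre-centrifuged, plasma-like Newtonian)
      eps_r        = 80,
      conductivity = 0.1      # S/m
    ),
    particle = list(
      diameter = 10e-6,       # m
      density  = 1050,        # kg/m^3
      mu_r_p   = 1.15         # bead-laden (tagged) cell relative permeability
    ),
    medium = list(mu_r = 1),
    constants = list(
      mu0  = 4e-7 * pi,       # vacuum permeability, H/m
      eps0 = 8.8541878128e-12, # vacuum permittivity, F/m
      g    = 9.8              # m/s^2
    ),
    electrokinetics = list(
      zeta        = -0.1,     # V, wall zeta potential
      diffusivity = 1e-10     # m^2/s, species diffusivity
    ),
    flow = list(
      main_inlet_velocity  = 10e-3,  # m/s, mean
      ancillary_velocity   = 4e-3,   # m/s, mean
      mixer_inlet_velocity = 6e-3,   # m/s, mean (each arm): set by what the
                                     # separator bottom outlet delivers in the
                                     # integrated chip (~6 mm/s at defaults)
      profile              = "parabolic"
    ),
    magnet = list(
      center_x      = 9e-3,   # m, along-channel position (optimized value)
      width         = 2e-3,   # m
      height        = 2e-3,   # m
      magnetization = 750e3,  # A/m
      direction     = c(0, 1),
      standoff      = 0.5e-3  # m, gap below the wide-section bottom wall
    ),
    electrodes = list(
      v0        = 100,        # V
      frequency = 4,          # Hz
      waveform  = "sinusoid"
    ),
    solver = list(
      tol      = 1e-8,        # relative momentum/update tolerance
      max_iter = 30,          # Picard iterations for the convective term
      nx       = 240, ny = 40,          # separator grid
      mixer_nx = 128, mixer_ny = 24     # mixer grid
    )
  )
  prov <- c(
    "fluid.density" = "assumed", "fluid.viscosity" = "assumed",
    "fluid.eps_r" = "assumed", "fluid.conductivity" = "assumed",
    "particle.diameter" = "stated", "particle.density" = "stated",
    "particle.mu_r_p" = "assumed", "medium.mu_r" = "assumed",
    "constants.mu0" = "stated", "constants.eps0" = "stated",
    "constants.g" = "assumed",
    "electrokinetics.zeta" = "assumed", "electrokinetics.diffusivity" = "assumed",
    "flow.main_inlet_velocity" = "assumed", "flow.ancillary_velocity" = "stated",
    "flow.mixer_inlet_velocity" = "assumed", "flow.profile" = "assumed",
    "magnet.center_x" = "stated", "magnet.width" = "assumed",
    "magnet.height" = "assumed", "magnet.magnetization" = "stated",
    "magnet.direction" = "assumed", "magnet.standoff" = "assumed",
    "electrodes.v0" = "stated", "electrodes.frequency" = "stated",
    "electrodes.waveform" = "assumed"
  )
  cfg$provenance <- as.list(prov)
  class(cfg) <- "ctc_config"
  cfg
}

#' Derived particle radius
#' @param config a `ctc_config`.
#' @return radius (m).
#' @export
particle_radius <- function(config) config$particle$diameter / 2

#' Permeability-contrast factor K
#'
#' Clausius-Mossotti-type contrast (mu_r_p - mu_r) / (mu_r_p + 2 mu_r) that
#' sets the sign and strength of the magnetophoretic force. Untagged cells
#' have mu_r_p = mu_r, hence K = 0.
#'
#' @param mu_r_p particle relative permeability.
#' @param mu_r medium relative permeability.
#' @return dimensionless K in (-0.5, 1).
#' @export
contrast_factor <- function(mu_r_p, mu_r = 1) {
  (mu_r_p - mu_r) / (mu_r_p + 2 * mu_r)
}

#' Write / read a config as YAML
#'
#' @param config a `ctc_config`.
#' @param path file path.
#' @return `read_config` returns the `ctc_config`; `write_config` the path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml reads length-2 numeric vectors back as lists; restore
  cfg$magnet$direction <- as.numeric(unlist(cfg$magnet$direction))
  class(cfg) <- "ctc_config"
  cfg
}

#' @export
print.ctc_config <- function(x, ...) {
  cat("ctc_config profile:", x$profile, "\n")
  cat(sprintf("  fluid: rho=%g kg/m^3, mu=%g Pa s | particle: dp=%g um, rho=%g, mu_r_p=%g\n",
              x$fluid$density, x$fluid$viscosity, 1e6 * x$particle$diameter,
              x$particle$density, x$particle$mu_r_p))
  cat(sprintf("  magnet: M=%g kA/m at x=%g mm | drive: V0=%g V, f=%g Hz\n",
              1e-3 * x$magnet$magnetization, 1e3 * x$magnet$center_x,
              x$electrodes$v0, x$electrodes$frequency))
  invisible(x)
}
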