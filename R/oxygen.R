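# Radial oxygen diffusion--consumption model (mechanistic simulation mode).
# Concentration is a fraction of air saturation in [0, 1] on a uniform
# cell-centred radial grid; the outer boundary is held at 1 (oxygenated
# colony edge), the centre has a zero-flux (symmetry) condition.

#' Initialise a radial oxygen field
#'
#' @param dr grid step (um).
#' @param r_max outer grid radius (um).
#' @param value initial concentration (fraction of air saturation).
#' @return an `oxygen_field`: list with `r_um` (bin centres, strictly
#'   increasing), `conc` in `[0, 1]`, `t_min`.
#' @export
oxygen_field_init <- function(dr = 10, r_max = 3000, value = 1) {
  stopifnot(dr > 0, r_max > dr, value >= 0, value <= 1)
  r <- seq(dr / 2, r_max - dr / 2, by = dr)
  structure(list(r_um = r, conc = rep(value, length(r)), t_min = 0, dr = dr),
            class = "oxygen_field")
}

#' One explicit step of radial oxygen diffusion and consumption
#'
#' Forward-time central-space update of
#' `dC/dt = D * (1/r) d/dr(r dC/dr) - a * rho(r) * C/(C + Km)`
#' with the consumption saturating in `C` (Michaelis form). The explicit
#' scheme is stable for `dt <= dr^2 / (4 D)`; larger steps are refused with
#' the admissible maximum named. Values are clipped to `[0, 1]` and the
#' outer boundary is fixed at 1.
#'
#' @param field an `oxygen_field`.
#' @param density relative cell density per grid bin (dimensionless, >= 0);
#'   scalar or one value per bin.
#' @param dt step (min).
#' @param diffusion diffusion coefficient D (um^2/min).
#' @param consumption maximal consumption rate per unit relative density
#'   (1/min).
#' @param km Michaelis constant (fraction of air saturation).
#' @return the updated `oxygen_field` at `t + dt`.
#' @export
step_oxygen <- function(field, density, dt, diffusion, consumption, km = 0.05) {
  stopifnot(inherits(field, "oxygen_field"), dt > 0, diffusion >= 0,
            consumption >= 0, km > 0)
  dr <- field$dr
  if (diffusion > 0) {
    dt_max <- dr^2 / (4 * diffusion)
    if (dt > dt_max)
      stop(sprintf(
        "step_oxygen: dt = %g min violates the explicit stability bound; max admissible dt = %g min",
        dt, dt_max), call. = FALSE)
  }
  r <- field$r_um
  n <- length(r)
  C <- field$conc
  density <- rep_len(density, n)

  # cylindrical Laplacian on a cell-centred grid; zero flux at r = 0,
  # Dirichlet C = 1 beyond the last bin
  Cm <- c(C[1], C[-n])          # inner ghost mirrors (symmetry)
  Cp <- c(C[-1], 1)             # outer ghost fixed at saturation
  rm <- r - dr / 2
  rp <- r + dr / 2
  lap <- (rp * (Cp - C) - rm * (C - Cm)) / (r * dr^2)

  cons <- consumption * density * C / (C + km)
  Cn <- C + dt * (diffusion * lap - cons)
  Cn <- pmin(pmax(Cn, 0), 1)

  field$conc <- Cn
  field$t_min <- field$t_min + dt
  field
}

#' Query an oxygen field
#'
#' `oxygen_at` interpolates the concentration at arbitrary radii (constant
#' beyond the grid ends); `oxygen_contour` returns the outermost radius at
#' which the concentration crosses `level` from below (`NA` if the field
#' never drops below `level`) -- in mechanistic simulations this contour is
#' the ground-truth ring position.
#'
#' @param field an `oxygen_field`.
#' @param r radii (um).
#' @param level concentration level (fraction of air saturation).
#' @return concentrations at `r`, or the contour radius (um).
#' @export
oxygen_at <- function(field, r) {
  stats::approx(field$r_um, field$conc, xout = r, rule = 2)$y
}

#' @rdname oxygen_at
#' @export
oxygen_contour <- function(field, level) {
  C <- field$conc
  below <- C < level
  if (!any(below)) return(NA_real_)
  i <- max(which(below))
  if (i == length(C)) return(field$r_um[i])
  # linear interpolation between bin i (below) and i+1 (above)
  r1 <- field$r_um[i]; r2 <- field$r_um[i + 1]
  c1 <- C[i]; c2 <- C[i + 1]
  if (c2 == c1) return(r1)
  r1 + (level - c1) / (c2 - c1) * (r2 - r1)
}
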