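#' Mean flow velocity in a rectangular flow cell
#'
#' Cross-section-averaged velocity `v_avg = Q / (h * w)` for volumetric flow
#' rate Q through a channel of height h and width w, together with the
#' centerline maximum of the plane-Poiseuille profile,
#' `v_max = (3/2) * v_avg`. At the standard settings (0.02 ml/min through a
#' 0.1 mm x 1 mm channel) this gives 0.33 cm/s.
#'
#' @param Q_ml_per_min Volumetric flow rate, ml/min (> 0).
#' @param h_um Channel height, um (> 0).
#' @param w_mm Channel width, mm (> 0).
#' @return A tibble with `v_avg_cm_per_s` and `v_max_cm_per_s`.
#' @examples
#' mean_flow_velocity(0.02, 100, 1)
#' @export
mean_flow_velocity <- function(Q_ml_per_min, h_um, w_mm) {
  check_number(Q_ml_per_min, "Q_ml_per_min", lower = 1e-300)
  check_number(h_um, "h_um", lower = 1e-300)
  check_number(w_mm, "w_mm", lower = 1e-300)
  Q <- Q_ml_per_min * 1e-6 / 60            # m^3/s
  area <- (h_um * 1e-6) * (w_mm * 1e-3)    # m^2
  if (area <= 0) abort("channel cross-section area must be positive")
  v_avg <- Q / area                        # m/s
  tibble(v_avg_cm_per_s = v_avg * 100,
         v_max_cm_per_s = 1.5 * v_avg * 100)
}

#' Flow velocity at a height above the coverslip
#'
#' Plane-Poiseuille profile between parallel plates,
#' `v(y) = (3/2) * v_avg * (h*y - y^2) / (h^2 / 4)`, which vanishes at the
#' no-slip walls and reaches `v_max = (3/2) * v_avg` at mid-channel. DNA
#' tethered to the coverslip sits on average ~0.2 um above the surface,
#' where a 0.33 cm/s mean flow translates to ~40 um/s.
#'
#' @param v_avg_cm_per_s Mean flow velocity, cm/s.
#' @param h_um Channel height, um.
#' @param y_um Height above the surface, um, in `[0, h_um]`.
#' @return Velocity at height y, um/s.
#' @examples
#' velocity_at_height(0.333, 100, 0.2)
#' @export
velocity_at_height <- function(v_avg_cm_per_s, h_um, y_um) {
  check_number(v_avg_cm_per_s, "v_avg_cm_per_s", lower = 0)
  check_number(h_um, "h_um", lower = 1e-300)
  check_number(y_um, "y_um", lower = -1e-300)
  if (y_um < 0 || y_um > h_um) abort("`y_um` must lie within [0, h_um]")
  v_avg_um_s <- v_avg_cm_per_s * 1e4
  1.5 * v_avg_um_s * (h_um * y_um - y_um^2) / (h_um^2 / 4)
}

#' Wall-corrected Stokes drag on a DNA-bound particle
#'
#' Drag force `F = 6*pi*eta*r*v * (1 + 9r/(16y))`: Stokes drag on a sphere
#' of radius r moving at speed v in a fluid of viscosity eta, with the
#' first-order Faxen correction for proximity to a plane wall at distance
#' y. The correction factor tends to 1 far from the wall and diverges at
#' y = 0, which is rejected.
#'
#' @param eta_pa_s Dynamic viscosity, Pa s (> 0; water is 1.0e-3).
#' @param r_nm Particle hydrodynamic radius, nm (> 0).
#' @param v_um_per_s Flow speed at the particle, um/s (>= 0).
#' @param y_um Distance from the wall, um (> 0).
#' @return Drag force, fN.
#' @examples
#' stokes_drag(1e-3, 2, 40, 0.2)
#' @export
stokes_drag <- function(eta_pa_s, r_nm, v_um_per_s, y_um) {
  check_number(eta_pa_s, "eta_pa_s", lower = 1e-300)
  check_number(r_nm, "r_nm", lower = 1e-300)
  check_number(v_um_per_s, "v_um_per_s", lower = 0)
  check_number(y_um, "y_um", lower = 0)
  if (y_um <= 0) abort("wall correction diverges at y = 0")
  r <- r_nm * 1e-9
  v <- v_um_per_s * 1e-6
  y <- y_um * 1e-6
  F_newton <- 6 * pi * eta_pa_s * r * v * (1 + 9 * r / (16 * y))
  F_newton * 1e15
}

#' Flow-cell hydrodynamics summary
#'
#' Chains [mean_flow_velocity()], [velocity_at_height()] and
#' [stokes_drag()] for one set of flow-cell conditions. Defaults are the
#' standard single-molecule flow-stretching conditions: 0.02 ml/min through
#' a 100 um x 1 mm channel, DNA at 0.2 um above the surface, water
#' viscosity, and a 2 nm hydrodynamic radius for the DNA-bound protein (the
#' documented default; with it the drag evaluates to ~1.5 fN).
#'
#' @param Q_ml_per_min,h_um,w_mm Channel flow and geometry.
#' @param y_um Height of the DNA above the surface, um.
#' @param eta_pa_s Viscosity, Pa s.
#' @param r_nm Particle radius, nm.
#' @return A one-row tibble with `v_avg_cm_per_s`, `v_max_cm_per_s`,
#'   `v_y_um_per_s`, `drag_fN`.
#' @examples
#' hydro_summary()
#' @export
hydro_summary <- function(Q_ml_per_min = 0.02, h_um = 100, w_mm = 1,
                          y_um = 0.2, eta_pa_s = 1e-3, r_nm = 2) {
  v <- mean_flow_velocity(Q_ml_per_min, h_um, w_mm)
  v_y <- velocity_at_height(v$v_avg_cm_per_s, h_um, y_um)
  tibble(v_avg_cm_per_s = v$v_avg_cm_per_s,
         v_max_cm_per_s = v$v_max_cm_per_s,
         v_y_um_per_s = v_y,
         drag_fN = stokes_drag(eta_pa_s, r_nm, v_y, y_um))
}
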