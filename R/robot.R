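# Desk-scale stand-in for the admittance arm-support robot: arm kinematics,
# 1-DOF vertical dynamics with virtual rigid surfaces, simulated load cell.
#
# Sign conventions: z is the vertical end-effector position relative to the
# 90-degree-abduction plane, upward positive. Forces are upward positive; the
# load cell reports the force the arm exerts on the robot, so a passive arm
# resting on a rigid surface reads approximately -W.

#' Arm / robot parameter set
#'
#' @param L_u Upper-arm length (m).
#' @param L_f Forearm + hand length (m).
#' @param W Limb weight (N); the real device measures it, here it is a
#'   parameter.
#' @param m_eff Effective vertical mass (kg); defaults to `W / 9.81`.
#' @param b Vertical damping (N s/m).
#' @param theta_limits Virtual-surface abduction limits (deg), default
#'   `c(70, 100)`.
#' @return Object of class `arm_model`.
#' @export
arm_model <- function(L_u = 0.30, L_f = 0.35, W = 30, m_eff = W / 9.81,
                      b = 20, theta_limits = c(70, 100)) {
  stopifnot(L_u > 0, L_f > 0, W > 0, m_eff > 0, b >= 0,
            theta_limits[1] < theta_limits[2])
  structure(list(L_u = L_u, L_f = L_f, W = W, m_eff = m_eff, b = b,
                 theta_limits = theta_limits),
            class = "arm_model")
}

#' Vertical height of the end effector from the abduction angle
#'
#' `z = L_u * sin(theta_abd - 90 deg)` relative to the 90-degree-abduction
#' plane.
#'
#' @param theta_abd Shoulder abduction (deg; 90 = horizontal).
#' @param arm An [arm_model()].
#' @return Height z in metres.
#' @export
abduction_to_height <- function(theta_abd, arm) {
  arm$L_u * sin((theta_abd - 90) * pi / 180)
}

#' Abduction angle from end-effector height (inverse of [abduction_to_height()])
#' @param z Height (m), `|z| <= L_u`.
#' @inheritParams abduction_to_height
#' @return Abduction angle in degrees.
#' @export
height_to_abduction <- function(z, arm) {
  90 + asin(pmin(1, pmax(-1, z / arm$L_u))) * 180 / pi
}

#' Horizontal shoulder-to-endpoint reach distance
#'
#' Law of cosines on the upper arm and forearm:
#' `sqrt(L_u^2 + L_f^2 + 2 L_u L_f cos(phi_e))`; full elbow extension
#' (`phi_e = 0`) gives `L_u + L_f`.
#'
#' @param theta_h Horizontal shoulder adduction (deg; unused by the distance,
#'   kept for interface symmetry with pose traces).
#' @param phi_e Elbow flexion from full extension (deg).
#' @inheritParams abduction_to_height
#' @return Distance in metres.
#' @export
reach_distance <- function(theta_h, phi_e, arm) {
  sqrt(arm$L_u^2 + arm$L_f^2 + 2 * arm$L_u * arm$L_f * cos(phi_e * pi / 180))
}

#' One explicit integration step of the vertical arm dynamics
#'
#' Semi-implicit Euler on `m_eff * zdd = F_robot + F_user - W - b * zd`,
#' with virtual rigid surfaces at the abduction limits: on contact z is
#' clamped, vertical velocity zeroed, and the constraint normal force appears
#' in the sensed force. The load cell reads
#' `F_sensed = -(F_robot + N)`, the (negated) total force the robot applies
#' to the arm; a passive resting arm reads `-W`.
#'
#' @param z,zdot Current height (m) and vertical velocity (m/s).
#' @param F_robot Robot-applied vertical force (N, up).
#' @param F_user Net user vertical muscle force (N, up; negative = pressing
#'   down).
#' @param arm An [arm_model()].
#' @param dt Time step (s); rejected above 10 ms for stability.
#' @return List `z`, `zdot`, `F_sensed`, `contact` (`"floor"`, `"ceiling"` or
#'   `""`).
#' @export
vertical_dynamics_step <- function(z, zdot, F_robot, F_user, arm, dt = 1e-3) {
  if (dt <= 0 || dt > 0.01)
    stop("dt must be in (0, 10 ms] for stable integration, got ", dt, " s")
  z_floor <- abduction_to_height(arm$theta_limits[1], arm)
  z_ceil <- abduction_to_height(arm$theta_limits[2], arm)
  Fnet <- F_robot + F_user - arm$W - arm$b * zdot
  zdot <- zdot + dt * Fnet / arm$m_eff
  z <- z + dt * zdot
  N <- 0
  contact <- ""
  if (z <= z_floor) {
    z <- z_floor
    if (zdot < 0) zdot <- 0
    N <- max(0, arm$W - F_robot - F_user)   # surface pushes up
    contact <- "floor"
  } else if (z >= z_ceil) {
    z <- z_ceil
    if (zdot > 0) zdot <- 0
    N <- min(0, arm$W - F_robot - F_user)   # surface pushes down
    contact <- "ceiling"
  }
  list(z = z, zdot = zdot, F_sensed = -(F_robot + N), contact = contact)
}

#' Configure the robot environment for a support condition
#'
#' The five task conditions: `no_support` (robot force 0), `limb_weight`
#' (constant upward force equal to the limb weight), `table` (rigid
#' frictionless horizontal surface at 90 degrees abduction on which the arm
#' rests), and the controller-driven `position` and `force` conditions. All
#' retain the 70/100-degree virtual vertical limits.
#'
#' @param condition One of `"table"`, `"position"`, `"no_support"`, `"force"`,
#'   `"limb_weight"`.
#' @param arm An [arm_model()].
#' @return List describing the environment: `condition`, `F_robot_const`
#'   (NA when controller-driven), `z_lock` (NA unless the tabletop locks z),
#'   `controller_driven`, and the z limits.
#' @export
make_condition <- function(condition, arm) {
  conds <- c("table", "position", "no_support", "force", "limb_weight")
  if (!condition %in% conds)
    stop("unknown support condition '", condition, "'; expected one of: ",
         paste(conds, collapse = ", "))
  z_floor <- abduction_to_height(arm$theta_limits[1], arm)
  z_ceil <- abduction_to_height(arm$theta_limits[2], arm)
  list(condition = condition,
       F_robot_const = switch(condition, no_support = 0, limb_weight = arm$W,
                              table = 0, NA_real_),
       z_lock = if (condition == "table") 0 else NA_real_,
       controller_driven = condition %in% c("position", "force"),
       z_floor = z_floor, z_ceiling = z_ceil)
}
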