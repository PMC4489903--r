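#' Sensor layout on the upper head surface
#'
#' Places `n_sensors` sensors quasi-uniformly (Fibonacci lattice) on a
#' spherical cap over the parietal region of a unit-radius head sphere.
#' The construction is deterministic, so two layouts with the same
#' `n_sensors` are identical.
#'
#' @param n_sensors number of sensors (default 84, the parietal subset
#'   used for online decoding).
#' @return A `sensor_layout`: list with `n_sensors`, `positions`
#'   (n x 3 matrix on the unit sphere) and `labels`.
#' @export
sensor_layout <- function(n_sensors = 84) {
  if (n_sensors < 2) stop("`n_sensors` must be at least 2")
  # Fibonacci lattice on the cap z in [0.35, 0.98]
  k <- seq_len(n_sensors)
  z <- 0.35 + (0.98 - 0.35) * (k - 0.5) / n_sensors
  golden <- pi * (3 - sqrt(5))
  theta <- golden * (k - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(x = r * cos(theta), y = r * sin(theta), z = z)
  structure(
    list(n_sensors = n_sensors, positions = pos,
         labels = sprintf("MEG%03d", k)),
    class = "sensor_layout"
  )
}

#' Two-hemisphere cortical source model with a toy leadfield
#'
#' Places `n_vertices_per_hemisphere` vertices in each of two patches
#' ("contra" on the left, "ipsi" on the right, for a moved right hand)
#' on a cortical sphere of radius 0.78 under the sensor cap, and builds
#' a dipolar gain matrix mapping vertex currents to sensor signals: each
#' vertex carries a tangentially oriented current dipole, and the gain
#' at a sensor falls off with the squared/cubed sensor-vertex distance,
#' producing the characteristic two-lobed sensor topography of a
#' cortical dipole. Columns are scaled to unit peak gain so source
#' amplitudes are expressed in peak-sensor units.
#'
#' @param layout a [sensor_layout()].
#' @param n_vertices_per_hemisphere vertices per hemisphere (default 84).
#' @param cortex_radius radius of the source sphere (default 0.78).
#' @return A `source_model`: list with `positions` (vertices x 3),
#'   `hemisphere` (factor `contra`/`ipsi`), `leadfield`
#'   (sensors x vertices) and `layout`.
#' @export
source_model <- function(layout, n_vertices_per_hemisphere = 84,
                         cortex_radius = 0.78) {
  stopifnot(inherits(layout, "sensor_layout"))
  if (n_vertices_per_hemisphere < 1)
    stop("`n_vertices_per_hemisphere` must be positive")
  patch <- function(center, n) {
    k <- seq_len(n)
    z <- (k - 0.5) / n * 2 - 1
    golden <- pi * (3 - sqrt(5))
    theta <- golden * (k - 1)
    r <- sqrt(pmax(0, 1 - z^2))
    p <- cbind(r * cos(theta), r * sin(theta), z)
    v <- sweep(0.35 * p, 2, center, "+")
    v / sqrt(rowSums(v^2)) * cortex_radius
  }
  n <- n_vertices_per_hemisphere
  contra <- patch(c(-0.45, -0.15, 0.88), n) # left sensorimotor patch
  ipsi <- patch(c(0.45, -0.15, 0.88), n)    # right sensorimotor patch
  positions <- rbind(contra, ipsi)
  colnames(positions) <- c("x", "y", "z")
  hemisphere <- factor(rep(c("contra", "ipsi"), each = n),
                       levels = c("contra", "ipsi"))
  lf <- toy_leadfield(layout$positions, positions)
  structure(
    list(positions = positions, hemisphere = hemisphere,
         leadfield = lf, layout = layout,
         n_vertices_per_hemisphere = n),
    class = "source_model"
  )
}

#' Dipolar toy leadfield
#'
#' Gain from a unit current at each vertex to each sensor. Each vertex
#' is assigned a tangential dipole orientation; the sensor gain is the
#' projection of the sensor-vertex displacement onto that orientation,
#' divided by the cubed distance (so the magnitude falls off as 1/r^2
#' and the sign flips across the dipole axis).
#'
#' @param sensors sensors x 3 position matrix.
#' @param vertices vertices x 3 position matrix.
#' @return sensors x vertices gain matrix.
#' @export
toy_leadfield <- function(sensors, vertices) {
  ns <- nrow(sensors); nv <- nrow(vertices)
  gain <- matrix(0, ns, nv)
  up <- c(0, 0, 1)
  for (v in seq_len(nv)) {
    pos <- vertices[v, ]
    ori <- c(pos[2] * up[3] - pos[3] * up[2],
             pos[3] * up[1] - pos[1] * up[3],
             pos[1] * up[2] - pos[2] * up[1])
    nrm <- sqrt(sum(ori^2))
    if (nrm < 1e-9) ori <- c(1, 0, 0) else ori <- ori / nrm
    d <- sweep(sensors, 2, pos)              # sensor - vertex
    r <- sqrt(rowSums(d^2))
    g <- (d %*% ori) / pmax(r, 0.05)^3
    gain[, v] <- g / max(abs(g))             # unit peak gain per vertex
  }
  rownames(gain) <- rownames(sensors)
  gain
}
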