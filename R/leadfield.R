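#' Compute the spherical-conductor lead field
#'
#' Gain matrix mapping unit dipole moments (1 A.m, along each vertex normal)
#' to the field picked up by each magnetometer (projection of B onto the
#' sensor orientation), using the closed-form solution for the magnetic
#' field of a current dipole in a homogeneous conducting sphere (Sarvas
#' formula). Ohmic volume currents are fully accounted for by the closed
#' form; a purely radial dipole produces exactly zero external field.
#'
#' @param sensors a `meg_sensors` object (all positions outside the sphere).
#' @param sources a `meg_sources` object (all positions inside the sphere).
#' @param center conductor centre, length-3 (default origin).
#' @param head_radius conductor radius in meters, used for validation.
#' @return a `meg_leadfield`: `gain` (channels x vertices, tesla per A.m),
#'   `center`, `head_radius`, and the `sensors`/`sources` objects.
#' @export
compute_lead_field <- function(sensors, sources, center = c(0, 0, 0),
                               head_radius = NULL) {
  sens_r <- sweep(sensors$positions, 2, center)
  src_r <- sweep(sources$positions, 2, center)
  d_sens <- sqrt(rowSums(sens_r^2))
  d_src <- sqrt(rowSums(src_r^2))
  if (is.null(head_radius)) head_radius <- max(d_src) * 1.0001
  if (any(d_sens <= head_radius))
    stop_invalid("all sensors must lie strictly outside the conductor sphere")
  if (any(d_src >= head_radius))
    stop_invalid("all sources must lie strictly inside the conductor sphere")

  nc <- nrow(sens_r)
  nv <- nrow(src_r)
  gain <- matrix(0, nc, nv)
  for (v in seq_len(nv)) {
    B <- sarvas_field(sens_r, src_r[v, ], sources$orientations[v, ])
    gain[, v] <- rowSums(B * sensors$orientations)
  }
  structure(list(gain = gain, center = center, head_radius = head_radius,
                 sensors = sensors, sources = sources),
            class = "meg_leadfield")
}

# Magnetic field (tesla) at sensor positions `r` (n x 3, conductor-centred)
# of a dipole with moment `q` (A.m) at position `rq`, in a homogeneous
# spherical conductor.  Vectorised over sensors.
sarvas_field <- function(r, rq, q) {
  mu0_4pi <- 1e-7
  a <- sweep(r, 2, rq)            # r - rq
  an <- sqrt(rowSums(a^2))
  rn <- sqrt(rowSums(r^2))
  ar <- rowSums(a * r)
  F <- an * (rn * an + rn^2 - as.vector(r %*% rq))
  # gradient of F with respect to the sensor position
  c1 <- an^2 / rn + ar / an + 2 * an + 2 * rn
  c2 <- an + 2 * rn + ar / an
  gradF <- c1 * r - outer(c2, rq)
  qxrq <- c(q[2] * rq[3] - q[3] * rq[2],
            q[3] * rq[1] - q[1] * rq[3],
            q[1] * rq[2] - q[2] * rq[1])
  dot_qxrq_r <- as.vector(r %*% qxrq)
  B <- (outer(F, qxrq) - dot_qxrq_r * gradF) * (mu0_4pi / F^2)
  B
}

#' @export
print.meg_leadfield <- function(x, ...) {
  cat("MEG lead field: ", nrow(x$gain), " channels x ", ncol(x$gain),
      " vertices (tesla per A.m), |gain| max ",
      format(max(abs(x$gain)), digits = 3), "\n", sep = "")
  invisible(x)
}
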