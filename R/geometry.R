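#' Build sensor-array and source-space geometry on spherical shells
#'
#' Places MEG magnetometers on a helmet-like spherical cap 2 cm above the
#' scalp sphere and cortical current dipoles on a shell at 0.85 of the head
#' radius, both by a deterministic golden-spiral layout with a small seeded
#' angular jitter. Head coordinates: +x right, +y anterior, +z superior,
#' origin at the conductor centre.
#'
#' Channels are tagged `frontal` (the most anterior quarter, the channels
#' later excluded to avoid blink artifacts), `occipitotemporal`
#' (posterior-inferior-lateral), or `other`. Vertices are tagged
#' `EBA-like` (a posterior-lateral extrastriate patch where body-sensitive
#' responses are injected), `early-visual` (posterior-medial), or
#' `background`.
#'
#' @param n_channels number of magnetometers (default 160).
#' @param n_vertices number of source dipoles (default 4004).
#' @param head_radius conductor sphere radius in meters (default 0.09).
#' @param seed integer seed for the angular jitter and dipole orientations.
#' @return a list with elements `sensors` (class `meg_sensors`: `positions`,
#'   `orientations` (radial unit vectors), `channel_id`, `region`) and
#'   `sources` (class `meg_sources`: `positions`, `orientations` (oblique
#'   unit normals), `vertex_id`, `region`), plus `center` and `head_radius`.
#' @examples
#' geom <- build_geometry(32, 64, 0.09, seed = 1)
#' table(geom$sensors$region)
#' @export
build_geometry <- function(n_channels = 160, n_vertices = 4004,
                           head_radius = 0.09, seed = 1) {
  if (!is.numeric(head_radius) || head_radius <= 0)
    stop_invalid("head_radius must be positive")
  if (n_channels < 8) stop_invalid("n_channels must be >= 8")
  if (n_vertices < 16) stop_invalid("n_vertices must be >= 16")

  with_seed(seed, {
    sensors <- make_sensor_array(n_channels, head_radius + 0.02)
    sources <- make_source_space(n_vertices, 0.85 * head_radius)
  })
  structure(list(sensors = sensors, sources = sources,
                 center = c(0, 0, 0), head_radius = head_radius),
            class = "meg_geometry")
}

# Golden-spiral points on a spherical zone z/r in [z_lo, z_hi], with small
# angular jitter so repeated seeds give distinct but statistically
# equivalent layouts.
golden_shell <- function(n, radius, z_lo, z_hi, jitter = 0.01) {
  i <- seq_len(n) - 0.5
  z <- z_lo + (z_hi - z_lo) * i / n
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  z <- pmin(pmax(z + stats::rnorm(n, 0, jitter), -0.999), 0.999)
  phi <- phi + stats::rnorm(n, 0, jitter)
  rho <- sqrt(1 - z^2)
  radius * cbind(x = rho * sin(phi), y = rho * cos(phi), z = z)
}

make_sensor_array <- function(n, radius) {
  # helmet covers the upper head down to just below the equator
  pos <- golden_shell(n, radius, -0.15, 0.98)
  ori <- pos / sqrt(rowSums(pos^2))          # radial pickup
  region <- rep("other", n)
  n_frontal <- floor(n / 4)                  # anterior quarter
  region[order(pos[, "y"], decreasing = TRUE)[seq_len(n_frontal)]] <- "frontal"
  ot_score <- -pos[, "y"] + 0.3 * abs(pos[, "x"]) - 0.5 * pos[, "z"]
  ot_score[region == "frontal"] <- -Inf
  region[order(ot_score, decreasing = TRUE)[seq_len(ceiling(0.3 * n))]] <-
    "occipitotemporal"
  structure(list(channel_id = sprintf("MEG%03d", seq_len(n)),
                 positions = pos, orientations = ori, region = region),
            class = "meg_sensors")
}

make_source_space <- function(n, radius) {
  pos <- golden_shell(n, radius, -0.55, 0.98)
  # oblique unit normals with a guaranteed tangential component (a purely
  # radial dipole is magnetically silent in a spherical conductor)
  ori <- matrix(stats::rnorm(3 * n), n, 3)
  ori <- ori / sqrt(rowSums(ori^2))
  rad <- pos / sqrt(rowSums(pos^2))
  cosang <- rowSums(ori * rad)
  flip <- abs(cosang) > 0.8
  if (any(flip)) {  # shave off the radial part for near-radial draws
    ori[flip, ] <- ori[flip, ] - (cosang[flip] * 0.8 / abs(cosang[flip])) * rad[flip, ]
    ori <- ori / sqrt(rowSums(ori^2))
  }
  region <- rep("background", n)
  eba_score <- -pos[, "y"] + 0.6 * abs(pos[, "x"]) - 0.4 * pos[, "z"]
  n_eba <- max(3L, ceiling(0.15 * n))
  eba_idx <- order(eba_score, decreasing = TRUE)[seq_len(n_eba)]
  region[eba_idx] <- "EBA-like"
  ev_score <- -pos[, "y"] - 0.8 * abs(pos[, "x"])
  ev_score[region == "EBA-like"] <- -Inf
  n_ev <- max(2L, ceiling(0.05 * n))
  region[order(ev_score, decreasing = TRUE)[seq_len(n_ev)]] <- "early-visual"
  structure(list(vertex_id = seq_len(n), positions = pos,
                 orientations = ori, region = region),
            class = "meg_sources")
}

#' @export
print.meg_geometry <- function(x, ...) {
  cat("MEG geometry: ", nrow(x$sensors$positions), " channels, ",
      nrow(x$sources$positions), " vertices, head radius ",
      x$head_radius, " m\n", sep = "")
  cat("  channel regions:",
      paste(names(table(x$sensors$region)), table(x$sensors$region),
            sep = "=", collapse = ", "), "\n")
  cat("  vertex regions: ",
      paste(names(table(x$sources$region)), table(x$sources$region),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
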