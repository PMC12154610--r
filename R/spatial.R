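# Virtual rooms, source-location grids, and binaural rendering.
#
# Azimuth convention: degrees clockwise from the listener's front, in
# [0, 360); 90 deg is to the listener's right. Elevation in degrees,
# positive above the horizontal plane.

SPEED_OF_SOUND <- 343 # m/s
HEAD_RADIUS <- 0.0875 # m, spherical head model

#' Sample a shoebox room and listener pose
#'
#' Room length and width are drawn log-uniformly from 3-30 m and height
#' from 2.2-10 m. The listener position is uniform within the room subject
#' to being at least 1.45 m from every wall and no higher than 2 m from the
#' floor; heading is uniform on the circle. Uses R's global RNG
#' (seed with [set.seed()] for reproducibility).
#'
#' @return list of class `room_spec` with fields `length`, `width`,
#'   `height` (m), `listener_position` (x, y, z in m), `listener_heading`
#'   (degrees clockwise from the +y axis).
#' @export
sample_room_and_listener <- function() {
  loguni <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  len <- loguni(3, 30)
  wid <- loguni(3, 30)
  hei <- loguni(2.2, 10)
  margin <- 1.45
  pos <- c(
    stats::runif(1, margin, len - margin),
    stats::runif(1, margin, wid - margin),
    stats::runif(1, 1, min(2, hei - 0.2))
  )
  structure(
    list(length = len, width = wid, height = hei,
         listener_position = pos,
         listener_heading = stats::runif(1, 0, 360)),
    class = "room_spec"
  )
}

# horizontal distance from the listener to the nearest wall along the ray
# at world angle phi (degrees clockwise from +y)
ray_wall_distance <- function(room, phi) {
  p <- room$listener_position
  d <- c(sin(phi * pi / 180), cos(phi * pi / 180))
  hits <- c(
    if (d[1] > 1e-12) (room$length - p[1]) / d[1] else Inf,
    if (d[1] < -1e-12) (0 - p[1]) / d[1] else Inf,
    if (d[2] > 1e-12) (room$width - p[2]) / d[2] else Inf,
    if (d[2] < -1e-12) (0 - p[2]) / d[2] else Inf
  )
  min(hits)
}

#' Build the per-environment source-location grid
#'
#' 72 azimuths (5-degree spacing) x 11 elevations x 2 distances per
#' direction = 1584 source locations. The first distance is fixed at 1.4 m;
#' the second is drawn uniformly between 1 m and 0.1 m less than the
#' distance from the listener to the wall along that azimuth. Uses R's
#' global RNG.
#'
#' @param room `room_spec`.
#' @param elevations the 11 elevation values in degrees (default -40 to
#'   +60 in 10-degree steps).
#' @return data.frame with columns `azimuth`, `elevation`, `distance`.
#' @export
build_location_grid <- function(room,
                                elevations = seq(-40, 60, by = 10)) {
  azimuths <- seq(0, 355, by = 5)
  walls <- vapply(azimuths, function(az) {
    ray_wall_distance(room, room$listener_heading + az)
  }, numeric(1))
  stopifnot(all(walls >= 1.1)) # guaranteed by the 1.45 m listener margin
  az <- rep(azimuths, each = length(elevations))
  el <- rep(elevations, times = length(azimuths))
  d2 <- stats::runif(length(az), 1, rep(walls, each = length(elevations)) - 0.1)
  data.frame(
    azimuth = rep(az, each = 2),
    elevation = rep(el, each = 2),
    distance = as.vector(rbind(1.4, d2))
  )
}

#' Source location
#'
#' @param azimuth degrees clockwise from the listener's front, `[0, 360)`.
#' @param elevation degrees.
#' @param distance meters (> 0).
#' @return list of class `source_location`.
#' @export
source_location <- function(azimuth, elevation = 0, distance = 1.4) {
  if (distance <= 0) stop_config("distance must be positive")
  azimuth <- azimuth %% 360
  structure(list(azimuth = azimuth, elevation = elevation,
                 distance = distance),
            class = "source_location")
}

#' Woodworth spherical-head interaural time difference
#'
#' `itd = r/c (theta + sin theta)` with `theta` the lateral angle from the
#' median plane; front-back symmetric. Positive values mean the right ear
#' leads.
#'
#' @param azimuth degrees clockwise from front.
#' @param head_radius head radius in meters (default 8.75 cm).
#' @return ITD in seconds.
#' @export
woodworth_itd <- function(azimuth, head_radius = HEAD_RADIUS) {
  az <- (azimuth %% 360) * pi / 180
  lat <- asin(sin(az)) # in [-pi/2, pi/2], front-back mirrored
  sign(lat) * head_radius / SPEED_OF_SOUND * (abs(lat) + sin(abs(lat)))
}

# first-order recursive lowpass (head shadow for the far ear)
one_pole_lowpass <- function(x, cutoff, fs) {
  a <- exp(-2 * pi * cutoff / fs)
  as.numeric(stats::filter((1 - a) * x, a, method = "recursive"))
}

#' Render a mono source to binaural stereo
#'
#' In `parametric` mode the renderer applies a spherical-head Woodworth
#' interaural time difference and a frequency-dependent interaural level
#' difference (a first-order lowpass head shadow on the far ear whose
#' cutoff falls as the source moves laterally), plus 1/distance gain
#' relative to the 1.4 m reference. Elevation affects neither cue in
#' parametric mode (a documented limitation of the spherical-head model).
#' In `brir` mode each ear's supplied impulse response is convolved with
#' the source. Output is stereo at the input rate, same length as the
#' input.
#'
#' @param mono mono `waveform`.
#' @param loc `source_location`.
#' @param mode `"parametric"` or `"brir"`.
#' @param brir stereo `waveform` holding the left/right impulse responses
#'   (required in `brir` mode).
#' @param head_radius spherical-head radius, m.
#' @param shadow_ref reference cutoff of the head-shadow lowpass at full
#'   lateralization, Hz.
#' @return stereo `waveform` of class `binaural_render` carrying `itd`
#'   (s), `ild` (dB, broadband right-minus-left), and `source`.
#' @export
render_binaural <- function(mono, loc, mode = c("parametric", "brir"),
                            brir = NULL, head_radius = HEAD_RADIUS,
                            shadow_ref = 1200) {
  mode <- match.arg(mode)
  if (n_channels(mono) != 1L) stop_input("render_binaural expects mono input")
  fs <- mono$sample_rate
  x <- mono$samples[1, ]
  n <- length(x)
  if (mode == "brir") {
    if (is.null(brir) || n_channels(brir) != 2L) {
      stop_config("brir mode requires a stereo impulse-response waveform")
    }
    conv_trim <- function(h) {
      nfft <- stats::nextn(n + length(h) - 1, 2)
      y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                           stats::fft(c(h, numeric(nfft - length(h)))),
                         inverse = TRUE)) / nfft
      y[seq_len(n)]
    }
    left <- conv_trim(brir$samples[1, ])
    right <- conv_trim(brir$samples[2, ])
    out <- waveform(rbind(left, right), fs)
    out$itd <- NA_real_
    out$ild <- NA_real_
    out$source <- loc
    class(out) <- c("binaural_render", class(out))
    return(out)
  }
  itd <- woodworth_itd(loc$azimuth, head_radius)
  lag <- round(abs(itd) * fs)
  lat <- asin(sin(loc$azimuth %% 360 * pi / 180)) # lateral angle
  gain <- 1.4 / loc$distance
  near <- x * gain
  # far-ear head shadow: the lowpass cutoff falls (log-linearly) from
  # near-Nyquist at the midline to shadow_ref at full lateralization, so
  # the filter fades out smoothly as the source approaches the median plane
  shadow_amount <- abs(sin(lat))
  far <- near
  if (shadow_amount > 1e-9) {
    fmax <- 0.45 * fs
    cutoff <- exp(log(fmax) + shadow_amount * (log(shadow_ref) - log(fmax)))
    far <- one_pole_lowpass(near, cutoff, fs)
  }
  if (lag > 0) far <- c(numeric(lag), far)[seq_len(n)]
  if (itd > 0) { # source on the right: right ear near, left ear far+lagged
    left <- far
    right <- near
  } else if (itd < 0) {
    left <- near
    right <- far
  } else {
    left <- near
    right <- near
  }
  out <- waveform(rbind(left, right), fs)
  rl <- rms(left)
  out$itd <- itd
  out$ild <- if (rl > 0) 20 * log10(rms(right) / rl) else NA_real_
  out$source <- loc
  class(out) <- c("binaural_render", class(out))
  out
}

#' Lead-lag precedence-effect stimulus
#'
#' Renders the signal at the lead location, renders a copy whose onset is
#' delayed by zero-padding at the lag location, and sums the two binaural
#' waveforms in each channel. The delay is floored to integer samples.
#'
#' @param signal mono `waveform`.
#' @param lead_loc,lag_loc `source_location`s.
#' @param delay lag onset delay in seconds (>= 0).
#' @param ... passed to [render_binaural()].
#' @return stereo `waveform` of length `n + floor(delay * fs)` samples.
#' @export
precedence_stimulus <- function(signal, lead_loc, lag_loc, delay, ...) {
  if (delay < 0) stop_input("delay must be nonnegative")
  fs <- signal$sample_rate
  d <- floor(delay * fs)
  lead <- render_binaural(signal, lead_loc, ...)
  lagged <- waveform(c(numeric(d), signal$samples[1, ]), fs)
  lag <- render_binaural(lagged, lag_loc, ...)
  n_out <- ncol(lag$samples)
  lead_pad <- cbind(lead$samples, matrix(0, 2, n_out - ncol(lead$samples)))
  waveform(lead_pad + lag$samples, fs)
}
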