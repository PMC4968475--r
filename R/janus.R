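# Synthetic fluorescence video of half-coated (Janus) microspheres and the
# tracking / rotation-analysis pipeline: translational velocity from centroid
# tracking, rotational velocity from the periodicity of the projected
# fluorescent area (one cycle of the area signal per revolution).
#
# Imaging model: orthographic projection along the camera axis (wall-normal
# y).  The sphere core is uniformly fluorescent; a metal-coated spherical cap
# of configurable half-angle blocks emission.  A surface point with outward
# normal n is visible when n_y > 0 and bright when it lies outside the coated
# cap.  The coated-cap pole rotates in the x-y plane as the particle rolls
# about z, so the projected bright area oscillates once per revolution
# between the full disc and a bright annular band; with the default 45
# degree cap the minimum equivalent diameter stays above the 5 um detection
# gate, emulating continuously trackable particles.

#' Video configuration
#'
#' Acquisition and rendering parameters for the synthetic Janus-particle
#' movies.  Defaults emulate a 25 frames/s fluorescence acquisition at 10x
#' magnification with a 960 x 500 sensor binned 2 x 2 (stored frames are
#' 480 x 250) and a pixel pitch of 1.3 um per binned pixel.
#'
#' @param frame_rate Frames per second.
#' @param width_px,height_px Stored frame size in pixels (after binning).
#' @param pixel_pitch_um Object-plane size of one stored pixel, um.
#' @param particle_diameter_um Sphere diameter, um.
#' @param fg,bg Foreground (fluorescent) and background intensity levels.
#' @param noise_sd Gaussian pixel-noise standard deviation.
#' @param coated_halfangle_deg Half-angle of the metal-coated cap, degrees;
#'   the default 45 keeps the projected bright area above the 5 um detection
#'   gate at every rotation phase (directional evaporation coats less than a
#'   full hemisphere optically).
#' @param exposure_s Exposure time (s); retained as metadata only -- motion
#'   blur is not modelled.
#' @return An object of class `video_config`.
#' @export
video_config <- function(frame_rate = 25, width_px = 480, height_px = 250,
                         pixel_pitch_um = 1.3, particle_diameter_um = 10,
                         fg = 0.85, bg = 0.08, noise_sd = 0.02,
                         coated_halfangle_deg = 45, exposure_s = NULL) {
  stopifnot(frame_rate > 0, pixel_pitch_um > 0, width_px > 0, height_px > 0,
            particle_diameter_um > 0, fg > bg)
  structure(list(frame_rate = frame_rate, width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_pitch_um = pixel_pitch_um,
                 particle_diameter_um = particle_diameter_um,
                 fg = fg, bg = bg, noise_sd = noise_sd,
                 coated_halfangle_deg = coated_halfangle_deg,
                 exposure_s = exposure_s),
            class = "video_config")
}

#' Render a synthetic Janus-particle video
#'
#' Renders particles translating downstream at `u_um_s` and rolling at
#' `omega_rad_s`, with 2 x 2 subpixel anti-aliasing and Gaussian noise, and
#' attaches the ground truth used (for pipeline validation).
#'
#' @param cfg A [video_config()].
#' @param u_um_s True translational velocity, um/s.
#' @param omega_rad_s True angular velocity, rad/s (forward rolling).  Must
#'   satisfy the Nyquist bound `omega < pi * frame_rate`.
#' @param n_particles Number of particles.
#' @param duration_s Movie length (s); default: time for a particle to cross
#'   the field of view (10 s if `u_um_s` is 0).
#' @param seed RNG seed (initial positions, phases, pixel noise).
#' @param plain_spheres If `TRUE`, particles are rendered uncoated (constant
#'   projected area; no rotation signal).
#' @param diameters_um Optional per-particle diameters (defaults to
#'   `cfg$particle_diameter_um`).
#' @return An object of class `janus_stack`: a list of frame matrices
#'   (rows = image rows, values in [0, ~1]) with attributes `cfg` and `truth`.
#' @export
#' @examples
#' cfg <- video_config(width_px = 120, height_px = 60)
#' stack <- render_janus_video(cfg, u_um_s = 30, omega_rad_s = 5, seed = 1,
#'                             duration_s = 3)
#' length(stack)
render_janus_video <- function(cfg, u_um_s, omega_rad_s, n_particles = 1,
                               duration_s = NULL, seed = 1,
                               plain_spheres = FALSE, diameters_um = NULL) {
  stopifnot(inherits(cfg, "video_config"))
  if (abs(omega_rad_s) >= pi * cfg$frame_rate)
    stop(sprintf(
      "rotation rate %.3g rad/s violates the Nyquist bound pi*fps = %.3g",
      omega_rad_s, pi * cfg$frame_rate))
  set.seed(seed)
  pitch <- cfg$pixel_pitch_um
  W <- cfg$width_px; H <- cfg$height_px
  if (is.null(diameters_um))
    diameters_um <- rep(cfg$particle_diameter_um, n_particles)
  a_um <- diameters_um / 2
  if (is.null(duration_s)) {
    duration_s <- if (u_um_s > 0)
      (W * pitch - 4 * max(a_um)) / u_um_s else 10
  }
  nf <- max(2L, as.integer(round(duration_s * cfg$frame_rate)))

  # seeded initial layout: particles staggered in x near the left edge and
  # spread over the rows, with random rotation phases
  x0 <- 2 * max(a_um) + (seq_len(n_particles) - 1) * 3.5 * max(a_um) +
    runif(n_particles, 0, pitch)
  z0 <- (seq_len(n_particles)) * H * pitch / (n_particles + 1) +
    runif(n_particles, -2, 2)
  phi0 <- runif(n_particles, 0, 2 * pi)
  cosc <- cos(cfg$coated_halfangle_deg * pi / 180)

  px <- (seq_len(W) - 0.5) * pitch
  pz <- (seq_len(H) - 0.5) * pitch
  sub <- c(-0.25, 0.25) * pitch
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    t <- (f - 1) / cfg$frame_rate
    img <- matrix(cfg$bg, H, W)
    for (p in seq_len(n_particles)) {
      a <- a_um[p]
      cx <- x0[p] + u_um_s * t
      cz <- z0[p]
      if (cx - a > W * pitch || cx + a < 0) next
      phi <- phi0[p] + omega_rad_s * t
      mx <- cos(phi); my <- sin(phi)
      cols <- which(px >= cx - a - pitch & px <= cx + a + pitch)
      rows <- which(pz >= cz - a - pitch & pz <= cz + a + pitch)
      if (!length(cols) || !length(rows)) next
      acc <- matrix(0, length(rows), length(cols))
      for (sx in sub) for (sz in sub) {
        xi <- outer(rep(1, length(rows)), px[cols] + sx - cx)
        ze <- outer(pz[rows] + sz - cz, rep(1, length(cols)))
        r2 <- (xi^2 + ze^2) / a^2
        inside <- r2 <= 1
        eta <- sqrt(pmax(0, 1 - r2))
        bright <- if (plain_spheres) inside else
          inside & ((xi / a) * mx + eta * my <= cosc)
        acc <- acc + ifelse(bright, cfg$fg, cfg$bg)
      }
      img[rows, cols] <- pmax(img[rows, cols], acc / 4)
    }
    img <- img + matrix(rnorm(H * W, 0, cfg$noise_sd), H, W)
    frames[[f]] <- img
  }
  structure(frames, class = "janus_stack", cfg = cfg,
            truth = list(u_um_s = u_um_s, omega_rad_s = omega_rad_s,
                         particles = data.frame(x0_um = x0, z0_um = z0,
                                                phi0 = phi0,
                                                diameter_um = diameters_um),
                         duration_s = nf / cfg$frame_rate, n_frames = nf,
                         seed = seed))
}

# Ritter's approximate minimum enclosing circle of a 2-column point matrix;
# returns c(cx, cy, r).  Deterministic and adequate for convex blob shapes.
min_enclosing_circle <- function(P) {
  p1 <- P[1, ]
  d1 <- (P[, 1] - p1[1])^2 + (P[, 2] - p1[2])^2
  p2 <- P[which.max(d1), ]
  d2 <- (P[, 1] - p2[1])^2 + (P[, 2] - p2[2])^2
  p3 <- P[which.max(d2), ]
  cen <- (p2 + p3) / 2
  r <- sqrt(max(d2)) / 2
  for (i in seq_len(nrow(P))) {
    d <- sqrt(sum((P[i, ] - cen)^2))
    if (d > r) {
      r <- (r + d) / 2
      cen <- cen + (d - r) / d * (P[i, ] - cen)
    }
  }
  c(cen, r)
}

detect_particles <- function(img, cfg, threshold, min_diameter_um) {
  bw <- img > threshold
  lab <- EBImage::imageData(EBImage::bwlabel(bw))
  nl <- max(lab)
  if (nl == 0) return(NULL)
  out <- vector("list", nl)
  for (k in seq_len(nl)) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < 4) next
    mec <- min_enclosing_circle(idx[, c(2, 1)])  # (col, row)
    diam_um <- 2 * mec[3] * cfg$pixel_pitch_um
    if (diam_um <= min_diameter_um) next         # size gate
    w <- img[idx] - threshold                    # intensity-weighted centroid
    w <- pmax(w, 1e-6)
    out[[k]] <- data.frame(x_px = sum(idx[, 2] * w) / sum(w),
                           y_px = sum(idx[, 1] * w) / sum(w),
                           area_px2 = nrow(idx), diameter_um = diam_um)
  }
  out <- do.call(rbind, out)
  if (!is.null(out) && nrow(out)) out[order(out$x_px), , drop = FALSE]
  else NULL
}

#' Track particles through a video stack
#'
#' Detects particles in each frame by thresholding and connected-component
#' contour labelling, gates them by minimum enclosing-circle diameter, and
#' associates detections across frames under the rolling-assay constraints:
#' forward (downstream) displacement less than half the previously detected
#' particle diameter per elapsed frame, and a divergence angle to the flow
#' direction of at most `max_angle_deg`.  A look-ahead window tolerates short
#' detection dropouts.
#'
#' @param stack A `janus_stack` (or list of frame matrices).
#' @param cfg A [video_config()]; defaults to the stack's own.
#' @param threshold Detection threshold; default between background and
#'   foreground levels.
#' @param min_diameter_um Size gate: detections with enclosing-circle
#'   diameter at or below this are discarded (default 5 um).
#' @param max_angle_deg Divergence-angle gate relative to the flow direction.
#' @param lookahead Number of frames a track may go undetected before it is
#'   closed.
#' @param min_track_frames Tracks shorter than this are dropped.
#' @return A list of `particle_track` objects: data frames with per-frame
#'   `frame`, `x_px`, `y_px`, `area_px2`, `diameter_um`.
#' @export
track_particles <- function(stack, cfg = attr(stack, "cfg"), threshold = NULL,
                            min_diameter_um = 5, max_angle_deg = 15,
                            lookahead = 5, min_track_frames = 5) {
  stopifnot(inherits(cfg, "video_config"))
  if (is.null(threshold)) threshold <- cfg$bg + 0.25 * (cfg$fg - cfg$bg)
  tracks <- list(); active <- list()
  for (f in seq_along(stack)) {
    det <- detect_particles(stack[[f]], cfg, threshold, min_diameter_um)
    used <- logical(if (is.null(det)) 0 else nrow(det))
    for (ti in seq_along(active)) {
      tr <- active[[ti]]
      if (is.null(tr)) next
      last <- tr[nrow(tr), ]
      gap <- f - last$frame
      if (gap > lookahead + 1) next
      if (is.null(det) || all(used)) next
      dx <- det$x_px - last$x_px
      dy <- det$y_px - last$y_px
      hyp <- sqrt(dx^2 + dy^2)
      maxd <- gap * (last$diameter_um / cfg$pixel_pitch_um) / 2
      ang <- atan2(abs(dy), dx) * 180 / pi
      # forward motion within half the previous diameter per elapsed frame
      # and within the divergence angle; sub-pixel jitter (the centroid of
      # the bright lune wobbles with rotation phase) is exempt from both
      ok <- !used & dx >= -1 & hyp <= maxd &
        (ang <= max_angle_deg | hyp <= 1.5)
      if (!any(ok)) next
      j <- which(ok)[which.min(abs(dx[ok]))]
      used[j] <- TRUE
      det_j <- det[j, ]; det_j$frame <- f
      active[[ti]] <- rbind(tr, det_j[names(tr)])
    }
    # close stale tracks
    for (ti in seq_along(active)) {
      tr <- active[[ti]]
      if (!is.null(tr) && f - tr[nrow(tr), "frame"] > lookahead) {
        tracks[[length(tracks) + 1]] <- tr
        active[ti] <- list(NULL)
      }
    }
    # new tracks from unmatched detections
    if (!is.null(det) && any(!used)) {
      for (j in which(!used)) {
        det_j <- det[j, ]; det_j$frame <- f
        active[[length(active) + 1]] <-
          det_j[c("frame", "x_px", "y_px", "area_px2", "diameter_um")]
      }
    }
  }
  for (tr in active) if (!is.null(tr)) tracks[[length(tracks) + 1]] <- tr
  tracks <- Filter(function(tr) nrow(tr) >= min_track_frames, tracks)
  lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    rownames(tr) <- NULL
    attr(tr, "id") <- i
    class(tr) <- c("particle_track", class(tr))
    tr
  })
}

#' Mean translational velocity of a track
#'
#' Mean particle velocity from the total tracked distance (net displacement
#' between the first and last detection, which for these unidirectional
#' tracks equals the path length but is robust to centroid noise) and the
#' frame rate.
#'
#' @param track A `particle_track` from [track_particles()].
#' @param cfg A [video_config()].
#' @return Velocity in um/s.
#' @export
track_velocity <- function(track, cfg) {
  stopifnot(nrow(track) >= 2)
  n <- nrow(track)
  dist_px <- sqrt((track$x_px[n] - track$x_px[1])^2 +
                  (track$y_px[n] - track$y_px[1])^2)
  dt <- (track$frame[n] - track$frame[1]) / cfg$frame_rate
  dist_px * cfg$pixel_pitch_um / dt
}

#' Rotation rate from the projected-area signal
#'
#' Estimates the particle's angular velocity from the periodicity of its
#' frame-resolved projected area: one cycle of the area change corresponds to
#' one revolution, so `omega = 2 pi * cycles / duration`.  Cycles are counted
#' as upward crossings of the signal midline with a hysteresis band (robust
#' to the flat extremes of the area signal, where the coated cap is entirely
#' hidden or entirely visible), with sub-frame interpolation of the crossing
#' times and a spectral (FFT) cross-check of the dominant periodicity.
#'
#' @param track A `particle_track`.
#' @param cfg A [video_config()].
#' @param hysteresis Half-width of the crossing hysteresis band as a fraction
#'   of the signal's robust range.
#' @param min_relative_range Signals whose standard deviation is below this
#'   fraction of their mean are flagged as aperiodic (no estimate); the
#'   default separates rotation signals (relative sd above 0.1) from the
#'   pixelation jitter of a constant projected area (below 0.04).
#' @return An object of class `area_signal`: the area series, estimated
#'   `cycles`, `omega_rad_s` (NA with `flag = "no_estimate"` when the track
#'   is too short or aperiodic), and the spectral cross-check.
#' @export
rotation_from_area <- function(track, cfg, hysteresis = 0.2,
                               min_relative_range = 0.05) {
  A <- track$area_px2
  out <- list(frames = track$frame, area = A, cycles = NA_real_,
              omega_rad_s = NA_real_, omega_fft_rad_s = NA_real_,
              flag = "ok")
  class(out) <- "area_signal"
  if (nrow(track) < 8 || stats::sd(A) < min_relative_range * mean(A)) {
    out$flag <- "no_estimate"
    return(out)
  }
  # light smoothing against pixelation noise
  As <- as.numeric(stats::filter(A, rep(1 / 3, 3)))
  As[is.na(As)] <- A[is.na(As)]
  # spectral estimate of the dominant periodicity (zero-padded), kept as the
  # cross-check on the counted cycles
  xa <- c(As - mean(As), numeric(7 * length(As)))
  sp <- Mod(fft(xa))[2:floor(length(xa) / 2)]
  fdom <- which.max(sp) / (length(xa) / cfg$frame_rate)
  out$omega_fft_rad_s <- 2 * pi * fdom
  # upward midline crossings with hysteresis, interpolated to sub-frame times
  qs <- stats::quantile(As, c(0.1, 0.9), names = FALSE)
  mid <- mean(qs)
  band <- hysteresis * diff(qs)
  state <- As[1] > mid
  tcross <- numeric(0)
  for (i in 2:length(As)) {
    if (!state && As[i] > mid + band) {
      j <- i
      while (j > 1 && As[j - 1] > mid - band && As[j - 1] < As[j]) j <- j - 1
      frac <- if (As[i] != As[max(j - 1, 1)])
        (mid - As[max(j - 1, 1)]) / (As[i] - As[max(j - 1, 1)]) else 0.5
      tcross <- c(tcross, max(j - 1, 1) + frac * (i - max(j - 1, 1)))
      state <- TRUE
    } else if (state && As[i] < mid - band) state <- FALSE
  }
  if (length(tcross) < 3) {      # need at least two full cycles
    out$flag <- "no_estimate"
    return(out)
  }
  cycles <- length(tcross) - 1
  duration <- (tcross[length(tcross)] - tcross[1]) / cfg$frame_rate
  omega <- 2 * pi * cycles / duration
  out$cycles <- cycles
  out$omega_rad_s <- omega
  if (abs(out$omega_fft_rad_s - omega) > 0.2 * omega)
    out$flag <- "spectral_mismatch"
  out
}

#' Measure a video end to end
#'
#' Tracks all particles and estimates per-track translational and rotational
#' velocities.
#'
#' @inheritParams track_particles
#' @param ... Passed to [track_particles()].
#' @return A data frame: one row per track with `u_um_s`, `omega_rad_s`,
#'   `cycles`, `n_frames`, `flag`.
#' @export
measure_video <- function(stack, cfg = attr(stack, "cfg"), ...) {
  tracks <- track_particles(stack, cfg, ...)
  if (!length(tracks))
    return(data.frame(track = integer(), u_um_s = numeric(),
                      omega_rad_s = numeric(), cycles = numeric(),
                      n_frames = integer(), flag = character()))
  do.call(rbind, lapply(tracks, function(tr) {
    rot <- rotation_from_area(tr, cfg)
    data.frame(track = attr(tr, "id"), u_um_s = track_velocity(tr, cfg),
               omega_rad_s = rot$omega_rad_s, cycles = rot$cycles,
               n_frames = nrow(tr), flag = rot$flag)
  }))
}

#' Write a video stack as multi-page TIFF
#'
#' @param stack A `janus_stack`.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
janus_write_tiff <- function(stack, file) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  frames <- lapply(stack, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, file)
  invisible(file)
}

#' @export
print.janus_stack <- function(x, ...) {
  cfg <- attr(x, "cfg")
  cat(sprintf("janus video stack: %d frames, %d x %d px @ %g fps\n",
              length(x), cfg$width_px, cfg$height_px, cfg$frame_rate))
  invisible(x)
}
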