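#' Propagation and room model for synthetic click recordings
#'
#' Encodes the acoustic facts a synthetic measurement series is anchored to:
#' the direct click's 1-ms windowed maximum sound pressure level, the
#' distance at which the reflected click is as loud as the direct one (the
#' loudspeaker radiates little energy backwards, so nearby reflections can
#' exceed the direct sound at the receiver), the reflected-level decay per
#' doubling of distance, and a room tail with a fixed reverberation time.
#'
#' The reflected-level law is
#' `R(d) = direct_level_db - reflected_decay_per_doubling_db * log2(d / crossover_distance)`
#' and the echo delay is `delay(d) = (2 d - geometry_offset) / sound_speed`.
#'
#' @param sound_speed Speed of sound in m/s.
#' @param direct_level_db 1-ms windowed maximum SPL of the direct click, dB.
#' @param crossover_distance Distance in metres where the reflected level
#'   equals the direct level.
#' @param reflected_decay_per_doubling_db Reflected-level decay in dB per
#'   doubling of distance.
#' @param reverb_time Room reverberation time in seconds (time for the tail
#'   to decay by 60 dB).
#' @param tail_level_db 1-ms SPL of the room tail at its onset (just after
#'   the direct click), dB. `-Inf` disables the tail.
#' @param noise_floor_db Stationary measurement noise level, dB. `-Inf`
#'   disables it.
#' @param geometry_offset Path-length correction in metres subtracted inside
#'   the delay formula (0 for a co-located source and receiver).
#' @param level_jitter_db Standard deviation of a per-recording Gaussian
#'   perturbation of the reflected level, modelling the scatter seen beyond
#'   about 2 m in real rooms. Off by default.
#' @param room_seed Integer seed for the room-tail realisation. The tail is
#'   the room's response to the same click and therefore identical across
#'   replicate recordings of a batch; change the seed to get a different
#'   "room".
#' @return An object of class `propagation_config`.
#' @export
propagation_config <- function(sound_speed = 343,
                               direct_level_db = 76,
                               crossover_distance = 1.2,
                               reflected_decay_per_doubling_db = 11,
                               reverb_time = 0.07,
                               tail_level_db = 48,
                               noise_floor_db = 15,
                               geometry_offset = 0,
                               level_jitter_db = 0,
                               room_seed = 104729L) {
  stopifnot(sound_speed > 0, crossover_distance > 0, reverb_time > 0,
            level_jitter_db >= 0, geometry_offset >= 0)
  structure(
    list(sound_speed = sound_speed, direct_level_db = direct_level_db,
         crossover_distance = crossover_distance,
         reflected_decay_per_doubling_db = reflected_decay_per_doubling_db,
         reverb_time = reverb_time, tail_level_db = tail_level_db,
         noise_floor_db = noise_floor_db, geometry_offset = geometry_offset,
         level_jitter_db = level_jitter_db,
         room_seed = as.integer(room_seed)),
    class = "propagation_config"
  )
}

#' Echo delay at a distance
#'
#' Two-way travel time of the reflection relative to the direct click.
#'
#' @param distance Distance to the reflector in metres (vectorised).
#' @param prop A [propagation_config()].
#' @return Delay in seconds.
#' @examples
#' echo_delay(2.0)  # 4 m / 343 m/s, about 11.66 ms
#' @export
echo_delay <- function(distance, prop = propagation_config()) {
  (2 * distance - prop$geometry_offset) / prop$sound_speed
}

#' Reflected-click level at a distance
#'
#' @inheritParams echo_delay
#' @return 1-ms windowed maximum SPL of the reflection in dB.
#' @examples
#' reflected_level(1.2)  # equals the direct level at the crossover
#' @export
reflected_level <- function(distance, prop = propagation_config()) {
  prop$direct_level_db - prop$reflected_decay_per_doubling_db *
    log2(distance / prop$crossover_distance)
}

# peak mean-square over running windows of `win` samples
window_peak_power <- function(x, win) {
  cs <- cumsum(c(0, x^2))
  max(cs[(win + 1):length(cs)] - cs[1:(length(cs) - win)]) / win
}

#' Synthesize one click recording
#'
#' Builds a mono waveform emulating a measurement at a given reflector
#' distance and state: the direct click at time zero, calibrated so its 1-ms
#' windowed maximum equals `direct_level_db`; in reflecting mode a copy of
#' the click delayed by [echo_delay()] and scaled to [reflected_level()]; an
#' exponentially decaying room-noise tail excited by the direct click
#' (present in both states, identical across replicates of a batch); and
#' stationary measurement noise at the noise floor.
#'
#' The waveform is in arbitrary linear units; the calibration constant
#' `cal_db` declares the mapping from windowed mean-square power to dB SPL
#' (`spl = 10 log10(power) + cal_db`) and is constant across all recordings
#' generated with the same click and propagation settings.
#'
#' @param distance Reflector distance in metres, within the rail (0.7--3.9).
#' @param disk_state `"reflecting"` or `"nonreflecting"`.
#' @param click A [click_template()].
#' @param prop A [propagation_config()].
#' @param seed Optional integer seed (drives the measurement noise and level
#'   jitter; with equal seeds, a reflecting and a non-reflecting recording
#'   differ by exactly the reflection component).
#' @param duration Recording length in seconds; must cover the reflected
#'   analysis window and the farthest echo.
#' @return An object of class `echo_recording`: list with `samples`,
#'   `sample_rate`, `distance`, `disk_state`, `cal_db`, `seed`.
#' @export
synthesize_recording <- function(distance,
                                 disk_state = c("reflecting", "nonreflecting"),
                                 click = click_template(),
                                 prop = propagation_config(),
                                 seed = NULL, duration = 0.06) {
  disk_state <- match.arg(disk_state)
  stopifnot(is.numeric(distance), length(distance) == 1L)
  if (distance < 0.7 || distance > 3.9) {
    stop("`distance` must lie on the rail, between 0.7 and 3.9 m")
  }
  if (click$amplitude <= 0) {
    stop("the click template must have positive amplitude for synthesis")
  }
  if (!is.null(seed)) set.seed(seed)
  fs <- click$sample_rate
  n <- round(duration * fs)
  win <- round(fs / 1000)
  delay_samp <- round(echo_delay(distance, prop) * fs)
  ck <- make_click(click)
  if (delay_samp + length(ck) > n || n < round(0.031 * fs)) {
    stop("recording too short for the reflected window and echo delay")
  }

  # calibration: a unit-scale click reads direct_level_db
  p0 <- window_peak_power(ck / click$amplitude, win)
  cal_db <- prop$direct_level_db - 10 * log10(p0)

  x <- numeric(n)
  x[seq_along(ck)] <- ck / click$amplitude

  # room tail: fixed room realisation, exponential 60 dB decay per reverb_time
  if (is.finite(prop$tail_level_db)) {
    onset <- length(ck)
    nt <- n - onset
    sigma0 <- 10^((prop$tail_level_db - cal_db) / 20)
    decay <- 10^(-3 * ((seq_len(nt) - 1) / fs) / prop$reverb_time)
    tail <- withr::with_seed(prop$room_seed, stats::rnorm(nt))
    x[(onset + 1):n] <- x[(onset + 1):n] + sigma0 * decay * tail
  }

  # jitter is drawn in both states to keep the random streams aligned
  jitter <- if (prop$level_jitter_db > 0) {
    stats::rnorm(1, 0, prop$level_jitter_db)
  } else {
    0
  }
  if (disk_state == "reflecting") {
    r_db <- reflected_level(distance, prop) + jitter
    gain <- 10^((r_db - prop$direct_level_db) / 20)
    idx <- delay_samp + seq_along(ck)
    x[idx] <- x[idx] + gain * ck / click$amplitude
  }

  if (is.finite(prop$noise_floor_db)) {
    x <- x + stats::rnorm(n, 0, 10^((prop$noise_floor_db - cal_db) / 20))
  }

  structure(
    list(samples = x, sample_rate = fs, distance = distance,
         disk_state = disk_state, cal_db = cal_db,
         seed = seed, click = click, prop = prop),
    class = "echo_recording"
  )
}

#' @export
print.echo_recording <- function(x, ...) {
  cat(sprintf(
    "echo recording: %.2f m, %s, %d samples @ %d Hz (cal %.2f dB)\n",
    x$distance, x$disk_state, length(x$samples), x$sample_rate, x$cal_db))
  invisible(x)
}

#' Synthesize a measurement series
#'
#' Generates recordings over a distance grid, for one or both reflector
#' states, with a number of replicates per condition, mirroring a batch
#' measurement run (default 0.7 to 3.9 m in 0.1 m steps).
#'
#' Replicates of the same condition share the room tail (a fixed room
#' responds identically to the same click) and differ in their measurement
#' noise; the reflecting and non-reflecting recording of the same replicate
#' index share a noise seed so that their difference isolates the reflection.
#'
#' @param distances Numeric vector of distances in metres.
#' @param disk_states Character vector of states to generate.
#' @param replicates Replicate recordings per distance and state.
#' @param click A [click_template()].
#' @param prop A [propagation_config()].
#' @param seed Optional integer base seed; per-recording seeds are derived
#'   from it.
#' @param duration Recording length in seconds.
#' @return A list of [synthesize_recording()] objects with class
#'   `echo_recording_set`.
#' @export
synthesize_series <- function(distances = seq(0.7, 3.9, by = 0.1),
                              disk_states = c("reflecting", "nonreflecting"),
                              replicates = 1L,
                              click = click_template(),
                              prop = propagation_config(),
                              seed = NULL, duration = 0.06) {
  disk_states <- match_enum(disk_states, c("reflecting", "nonreflecting"),
                            "disk_states")
  stopifnot(replicates >= 1L)
  recs <- list()
  k <- 0L
  for (i in seq_along(distances)) {
    for (r in seq_len(replicates)) {
      rec_seed <- if (is.null(seed)) NULL else seed + 1000L * i + r
      for (state in disk_states) {
        k <- k + 1L
        recs[[k]] <- synthesize_recording(
          distances[i], state, click = click, prop = prop,
          seed = rec_seed, duration = duration)
      }
    }
  }
  structure(recs, class = "echo_recording_set")
}

#' Write a recording as WAV plus JSON manifest
#'
#' @param recording An `echo_recording`.
#' @param path Output WAV path; the manifest is written next to it with a
#'   `.json` extension.
#' @param bit_depth Passed to [write_wav()]. The waveform is scaled to fit
#'   \[-1, 1\] and the scaling folded into the manifest's calibration
#'   constant.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, bit_depth = "float32") {
  stopifnot(inherits(recording, "echo_recording"))
  peak <- max(abs(recording$samples), 1e-12)
  scale <- if (peak > 1) 1 / peak else 1
  write_wav(recording$samples * scale, path,
            sample_rate = recording$sample_rate, bit_depth = bit_depth)
  manifest <- list(
    distance_m = recording$distance,
    disk_state = recording$disk_state,
    sample_rate = recording$sample_rate,
    cal_db = recording$cal_db - 20 * log10(scale),
    seed = recording$seed
  )
  jsonlite::write_json(manifest, manifest_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

manifest_path <- function(wav_path) sub("\\.wav$", ".json", wav_path)

#' Read a recording written by [write_recording()]
#'
#' @param path WAV path with a sidecar `.json` manifest.
#' @return An `echo_recording`.
#' @export
read_recording <- function(path) {
  wav <- read_wav(path)
  mpath <- manifest_path(path)
  if (!file.exists(mpath)) {
    stop("manifest not found: ", mpath)
  }
  m <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  structure(
    list(samples = wav$samples, sample_rate = wav$sample_rate,
         distance = m$distance_m, disk_state = m$disk_state,
         cal_db = m$cal_db, seed = m$seed, click = NULL, prop = NULL),
    class = "echo_recording"
  )
}

#' Write a measurement series to a directory
#'
#' One WAV + manifest pair per recording, named by distance, state, and
#' replicate index.
#'
#' @param recordings An `echo_recording_set` (or list of `echo_recording`).
#' @param dir Output directory (created if needed).
#' @param bit_depth Passed to [write_recording()].
#' @return `dir`, invisibly.
#' @export
write_measurement_series <- function(recordings, dir, bit_depth = "float32") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- new.env()
  for (rec in recordings) {
    key <- sprintf("%.3f_%s", rec$distance, rec$disk_state)
    idx <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    counts[[key]] <- idx
    path <- file.path(dir, sprintf("rec_d%05.2f_%s_r%02d.wav",
                                   rec$distance, rec$disk_state, idx))
    write_recording(rec, path, bit_depth = bit_depth)
  }
  invisible(dir)
}

#' Read a measurement series directory
#'
#' @param dir Directory of WAV + manifest pairs.
#' @return An `echo_recording_set`.
#' @export
read_measurement_series <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.wav$", full.names = TRUE))
  if (!length(paths)) stop("no WAV files found in ", dir)
  structure(lapply(paths, read_recording), class = "echo_recording_set")
}
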