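#' Extract a kymograph from an image stack
#'
#' Slices a 1-pixel-wide line region of interest out of every frame of a
#' multi-frame image stack, mirroring how kymographs are produced from raw
#' TIFF stacks along the long axis of an individual ssDNA molecule.
#'
#' @param stack Numeric array, frames x rows x columns.
#' @param roi_line List specifying the line, either `list(row = r)` (the
#'   ssDNA lies along a camera row) or `list(col = c)`; 1-based index.
#' @param imaging An [imaging_model()].
#' @param channel Channel label for the result.
#' @return A [as_kymograph()] object with one row per frame.
#' @export
extract_kymograph <- function(stack, roi_line, imaging, channel = "ch1") {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  if (!is.null(roi_line$row)) {
    r <- roi_line$row
    if (r < 1L || r > dim(stack)[2]) {
      abort("ROI row outside image bounds.", class = "curtainr_bounds_error")
    }
    mat <- stack[, r, , drop = TRUE]
  } else if (!is.null(roi_line$col)) {
    cl <- roi_line$col
    if (cl < 1L || cl > dim(stack)[3]) {
      abort("ROI column outside image bounds.", class = "curtainr_bounds_error")
    }
    mat <- stack[, , cl, drop = TRUE]
  } else {
    abort_invalid("`roi_line` must specify `row` or `col`.")
  }
  if (dim(stack)[1] == 1L) mat <- matrix(mat, nrow = 1L)
  as_kymograph(mat, imaging, channel = channel)
}

# Half-plateau crossing displacement for a box tract of width w blurred by
# a Gaussian of sd sigma: the 0.5-crossing sits delta inside the true edge,
# with Phi(delta/sigma) - Phi((delta - w)/sigma) = 0.5. Returns the inward
# displacement delta given the MEASURED width w_m = w - 2 delta.
narrow_tract_delta <- function(w_m, sigma) {
  if (!is.finite(w_m) || w_m <= 0 || sigma <= 0) return(0)
  delta_of_w <- function(w) {
    g <- function(d) stats::pnorm(d / sigma) - stats::pnorm((d - w) / sigma) - 0.5
    if (g(w / 2) <= 0) return(w / 2) # peak barely reaches half-plateau
    stats::uniroot(g, c(0, w / 2), tol = 1e-6)$root
  }
  h <- function(w) w - 2 * delta_of_w(w) - w_m
  if (h(w_m + 6 * sigma) < 0) return(0)
  w <- stats::uniroot(h, c(w_m, w_m + 6 * sigma), tol = 1e-6)$root
  delta_of_w(w)
}

# 0.5-crossings of a normalized profile, with linear sub-pixel interpolation.
# Returns positions in pixels (0-based, at pixel centers).
half_crossings <- function(norm, direction = c("down", "up")) {
  direction <- match.arg(direction)
  n <- length(norm)
  above <- norm > 0.5
  idx <- if (direction == "down") which(above[-n] & !above[-1L]) else which(!above[-n] & above[-1L])
  if (length(idx) == 0L) return(numeric())
  frac <- (0.5 - norm[idx]) / (norm[idx + 1L] - norm[idx])
  (idx - 1L) + 0.5 + frac
}

#' Detect the moving clearing/exchange front in a kymograph
#'
#' For each frame the intensity profile is smoothed, normalised to the coat
#' (or trail) plateau, and the motor front is located where the profile
#' crosses half the plateau, refined by linear interpolation between pixels.
#' The half-plateau threshold is symmetric under PSF blur, so the crossing
#' sits at the true edge position. In `clearing` mode the front is the first
#' bright-to-dark transition scanning from the 5' end; in `exchange` mode
#' the first dark-to-bright transition. The second transition of the tract
#' (at the motor's binding site) is reported as `origin_px`. Frames without
#' a crossing are marked missing, never silently interpolated. A final
#' isotonic pass enforces the 3'->5' non-retreating property of the front.
#'
#' @param kymo A [as_kymograph()] object.
#' @param mode `"clearing"` or `"exchange"`.
#' @param threshold Crossing threshold as a fraction of the plateau (0.5).
#' @param smooth_px Gaussian smoothing sigma applied to each profile, pixels.
#' @param isotonic Apply the monotone (non-retreating) cleanup pass?
#' @return A tibble with `frame`, `time_s`, `front_px`, `origin_px`,
#'   `missing`.
#' @export
detect_front <- function(kymo, mode = c("clearing", "exchange"),
                         threshold = 0.5, smooth_px = 1, isotonic = TRUE) {
  stopifnot(inherits(kymo, "kymograph"))
  mode <- match.arg(mode)
  dat <- kymo$data
  nf <- nrow(dat)

  # plateau: mean of pixels near the global high level; dark level: low
  # quantile (camera baseline). Normalisation runs between the two.
  hi <- stats::quantile(dat, 0.995, names = FALSE)
  dark <- stats::quantile(dat, 0.01, names = FALSE)
  plateau <- mean(dat[dat > dark + 0.7 * (hi - dark)])
  if (!is.finite(plateau) || plateau <= dark) {
    abort_fit("Cannot estimate a coat plateau: kymograph has no bright level.")
  }
  if (plateau - dark < 0.1 * abs(plateau)) {
    # no contrast: nothing cleared/deposited anywhere, every front is missing
    return(tibble(
      frame = seq_len(nf), time_s = kymo$frame_times,
      front_px = NA_real_, origin_px = NA_real_, missing = TRUE
    ))
  }

  front <- origin <- rep(NA_real_, nf)
  for (f in seq_len(nf)) {
    norm <- (gauss_smooth(dat[f, ], smooth_px) - dark) / (plateau - dark) *
      (0.5 / threshold)
    if (mode == "clearing") {
      if (norm[1L] <= 0.5) {
        front[f] <- 0
        up <- half_crossings(norm, "up")
        origin[f] <- if (length(up)) up[1L] else ncol(dat) - 1L
      } else {
        dn <- half_crossings(norm, "down")
        if (length(dn)) {
          front[f] <- dn[1L]
          up <- half_crossings(norm, "up")
          up <- up[up > front[f]]
          origin[f] <- if (length(up)) up[1L] else ncol(dat) - 1L
        }
      }
    } else {
      if (norm[1L] > 0.5) {
        front[f] <- 0
        dn <- half_crossings(norm, "down")
        origin[f] <- if (length(dn)) dn[1L] else ncol(dat) - 1L
      } else {
        up <- half_crossings(norm, "up")
        if (length(up)) {
          front[f] <- up[1L]
          dn <- half_crossings(norm, "down")
          dn <- dn[dn > front[f]]
          origin[f] <- if (length(dn)) dn[1L] else ncol(dat) - 1L
        }
      }
    }
  }

  # finite-width correction: on a nascent tract both half-plateau crossings
  # sit inside the true edges because the two PSF-blurred edges overlap;
  # invert the box (x) Gaussian model to push them back out
  sig_eff <- sqrt(kymo$imaging$psf_sigma^2 + smooth_px^2)
  if (sig_eff > 0) {
    np <- ncol(dat)
    for (f in seq_len(nf)) {
      if (is.na(front[f]) || front[f] <= 0 || is.na(origin[f]) ||
          origin[f] >= np - 1L) next
      delta <- narrow_tract_delta(origin[f] - front[f], sig_eff)
      front[f] <- front[f] - delta
      origin[f] <- origin[f] + delta
    }
  }

  if (isotonic && sum(!is.na(front)) >= 2L) {
    ok <- which(!is.na(front))
    iso <- stats::isoreg(ok, -front[ok])
    front[ok] <- -iso$yf
  }

  tibble(
    frame = seq_len(nf),
    time_s = kymo$frame_times,
    front_px = front,
    origin_px = origin,
    missing = is.na(front)
  )
}

#' Track diffraction-limited puncta across kymograph frames
#'
#' Per frame, candidate puncta are local intensity maxima rising `min_snr`
#' robust noise SDs above the background; each is refined to an
#' intensity-weighted centroid in a window around the maximum (ties in the
#' local maximum broken toward the 3' side, the direction motors come from).
#' Detections closer than the resolution limit (2 px) are flagged
#' `ambiguous`. Frame-to-frame linking is nearest-neighbour with a maximum
#' jump gate.
#'
#' @param kymo A [as_kymograph()] object.
#' @param min_snr Detection threshold in robust noise SDs above background.
#' @param window Half-width of the centroid window, pixels.
#' @param max_jump_px Maximum frame-to-frame jump for linking, pixels.
#' @return A tibble with `track_id`, `frame`, `time_s`, `position_px`,
#'   `intensity`, `ambiguous`; zero rows if nothing is detected.
#' @export
track_puncta <- function(kymo, min_snr = 3, window = 3L, max_jump_px = 5) {
  stopifnot(inherits(kymo, "kymograph"))
  dat <- kymo$data
  nf <- nrow(dat); np <- ncol(dat)

  # temporal noise estimate: frame-to-frame differences are untouched by
  # (near-)static structure, so this is robust both to bright puncta that
  # contaminate spatial quantiles on short strips and to the zero-clipped
  # background of a dark channel, where a spatial mad() collapses
  sig <- if (nf >= 2L) stats::mad(dat[-1L, , drop = FALSE] - dat[-nf, , drop = FALSE]) / sqrt(2) else 0
  if (sig <= 0) sig <- max(1e-9, 1e-6 * max(abs(dat)))

  detections <- vector("list", nf)
  for (f in seq_len(nf)) {
    prof <- dat[f, ]
    bg <- stats::median(prof)
    thr <- bg + min_snr * sig
    # local maxima; ties toward higher pixel index (3' side)
    is_max <- prof >= thr &
      prof >= c(-Inf, prof[-np]) &
      prof > c(prof[-1L], -Inf)
    cand <- which(is_max)
    if (length(cand) == 0L) next
    pos <- int <- numeric(length(cand))
    for (j in seq_along(cand)) {
      lo <- max(1L, cand[j] - window); hi <- min(np, cand[j] + window)
      w <- pmax(prof[lo:hi] - bg, 0)
      # pixel i (1-based) has its centre at i - 0.5 in continuous px units
      pos[j] <- sum(((lo:hi) - 0.5) * w) / sum(w)
      int[j] <- prof[cand[j]] - bg
    }
    amb <- rep(FALSE, length(cand))
    if (length(cand) > 1L) {
      d <- diff(sort(pos))
      close_pairs <- which(d < 2)
      ord <- order(pos)
      for (cp in close_pairs) amb[ord[c(cp, cp + 1L)]] <- TRUE
    }
    detections[[f]] <- tibble(frame = f, position_px = pos, intensity = int, ambiguous = amb)
  }
  det <- bind_rows(detections)
  if (nrow(det) == 0L) {
    return(tibble(
      track_id = integer(), frame = integer(), time_s = double(),
      position_px = double(), intensity = double(), ambiguous = logical()
    ))
  }

  # greedy nearest-neighbour linking
  det$track_id <- NA_integer_
  next_id <- 1L
  last_pos <- numeric(0) # position of each open track
  last_frame <- integer(0)
  for (f in sort(unique(det$frame))) {
    rows <- which(det$frame == f)
    open <- which(last_frame >= f - 3L) # allow short gaps
    assigned_tracks <- integer(0)
    for (r in rows[order(-det$intensity[rows])]) {
      p <- det$position_px[r]
      cand <- setdiff(open, assigned_tracks)
      if (length(cand)) {
        dists <- abs(last_pos[cand] - p)
        k <- which.min(dists)
        if (dists[k] <= max_jump_px) {
          id <- cand[k]
          det$track_id[r] <- id
          last_pos[id] <- p; last_frame[id] <- f
          assigned_tracks <- c(assigned_tracks, id)
          next
        }
      }
      det$track_id[r] <- next_id
      last_pos[next_id] <- p; last_frame[next_id] <- f
      assigned_tracks <- c(assigned_tracks, next_id)
      next_id <- next_id + 1L
    }
  }
  det$time_s <- kymo$frame_times[det$frame]
  det |>
    select("track_id", "frame", "time_s", "position_px", "intensity", "ambiguous") |>
    arrange(.data$track_id, .data$frame)
}

#' Segment a trajectory into a translocation event
#'
#' Identifies the moving portion of a front or punctum trajectory and turns
#' it into a quantified translocation event. The moving interval runs from
#' the first valid point to the last frame before the trajectory settles
#' onto its final plateau; velocity is the magnitude of the regression slope
#' of position vs time over the interior of that interval, converted to
#' nt/s. Distance is the net displacement in nt unless `origin_px` is given
#' (front tracking), in which case the tract extent `origin - final front`
#' is used, which is insensitive to frame discretisation. Events shorter
#' than `min_frames`, smaller than `min_displacement_nt`, slower than
#' `motion_threshold_nt_s`, or moving away from the 5' end are rejected
#' (empty result, not an error).
#'
#' @param trajectory Tibble with `time_s` and `position_px` (optionally
#'   `frame`); e.g. one track from [track_puncta()] or the non-missing rows
#'   of [detect_front()] (rename `front_px` to `position_px`).
#' @param imaging An [imaging_model()].
#' @param min_frames Minimum number of trajectory points (default 3).
#' @param min_displacement_nt Minimum displacement (default 1450 nt = 2 px).
#' @param motion_threshold_nt_s Minimum speed to count as directed motion.
#' @param origin_px Optional static tract-origin position (pixels) used for
#'   the distance measurement.
#' @param appearance_correction Add half a frame-interval of travel to the
#'   distance when the trajectory starts with the appearance of a punctum
#'   (binding happens mid-interval, so on average half a frame of travel
#'   precedes the first detection). Ignored when `origin_px` is given.
#' @param plateau_gate_px Jitter gate used to find the final stationary
#'   plateau, pixels.
#' @return A tibble with zero or one row: `start_frame`, `end_frame`,
#'   `start_s`, `end_s`, `start_px`, `end_px`, `velocity_nt_s`,
#'   `distance_nt`, `censored`, `n_frames`, `r_squared`.
#' @export
segment_translocation <- function(trajectory, imaging, min_frames = 3L,
                                  min_displacement_nt = 1450,
                                  motion_threshold_nt_s = 10,
                                  origin_px = NULL,
                                  appearance_correction = FALSE,
                                  plateau_gate_px = 0.3) {
  stopifnot(inherits(imaging, "imaging_model"))
  empty <- tibble(
    start_frame = integer(), end_frame = integer(), start_s = double(),
    end_s = double(), start_px = double(), end_px = double(),
    velocity_nt_s = double(), distance_nt = double(), censored = logical(),
    n_frames = integer(), r_squared = double()
  )
  tr <- as_tibble(trajectory)
  if (!"frame" %in% names(tr)) tr$frame <- seq_len(nrow(tr))
  tr <- tr |> filter(!is.na(.data$position_px)) |> arrange(.data$time_s)
  if (nrow(tr) < min_frames) return(empty)

  final_pos <- tr$position_px[nrow(tr)]
  moving <- which(tr$position_px > final_pos + plateau_gate_px)
  last_moving <- if (length(moving)) max(moving) else 0L
  # moving interval: first point through the first plateau point
  end_idx <- min(last_moving + 1L, nrow(tr))
  if (end_idx < min_frames) return(empty)
  seg <- tr[seq_len(end_idx), ]

  # interior fit: the last moving point may be a partial frame, and the
  # first one is distorted while a clearing/exchange tract is still
  # narrower than the PSF
  n_seg <- nrow(seg)
  fit_rows <- seq_len(n_seg)
  if (n_seg >= 4L) fit_rows <- fit_rows[-n_seg]
  if (n_seg >= 5L) fit_rows <- fit_rows[-1L]
  fit <- stats::lm(position_px ~ time_s, data = seg[fit_rows, ])
  # trim distorted boundary points (e.g. the first frames of a clearing or
  # exchange tract, where the tract is still narrower than the PSF and the
  # half-plateau edge is displaced), then refit
  repeat {
    r <- stats::resid(fit)
    if (length(fit_rows) <= 3L || abs(r[1L]) <= 0.07) break
    fit_rows <- fit_rows[-1L]
    fit <- stats::lm(position_px ~ time_s, data = seg[fit_rows, ])
  }
  slope <- stats::coef(fit)[["time_s"]]
  r2 <- suppressWarnings(summary(fit)$r.squared)

  if (slope >= 0 && last_moving > 0L) return(empty)  # wrong direction (away from 5')
  velocity <- abs(slope) * imaging$nt_per_pixel / 1  # px/s -> nt/s

  if (!is.null(origin_px)) {
    distance <- (origin_px - final_pos) * imaging$nt_per_pixel
  } else {
    distance <- (seg$position_px[1L] - final_pos) * imaging$nt_per_pixel
    if (appearance_correction) {
      distance <- distance + velocity * imaging$frame_interval / 2
    }
  }

  if (last_moving == 0L || velocity < motion_threshold_nt_s ||
      distance < min_displacement_nt) {
    return(empty)
  }

  # censored if still moving at the last observed frame, or front hit the 5' end
  censored <- (last_moving == nrow(tr)) || final_pos <= 1

  tibble(
    start_frame = tr$frame[1L], end_frame = tr$frame[end_idx],
    start_s = tr$time_s[1L], end_s = tr$time_s[end_idx],
    start_px = tr$position_px[1L], end_px = final_pos,
    velocity_nt_s = velocity, distance_nt = distance,
    censored = censored, n_frames = nrow(seg), r_squared = r2
  )
}
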