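# The discrete-time survey engine. Each tick advances, in order: environment,
# whales (movement + dive cycle), sonobuoy lifecycle, listening/bearing events,
# vessel decision + movement, then visual detection and encounter logging.
# Three survey modes are supported: AMR (acoustically assisted mark-recapture),
# VMR (visual-only mark-recapture) and LT (visual line transect).
#
# Whale movement does not depend on the vessel, so whole-population tracks are
# simulated up front as (group x tick) matrices; the per-tick loop then only
# runs the acoustics and the vessel state machine. All randomness flows from
# one stream: whale draws first, then the vessel/acoustics draws in tick
# order, so a seed fully determines a replicate.

#' Classify an encounter by its source
#'
#' An encounter is an acoustic-track encounter only when the sighted group is
#' the vessel's current acoustic target in targeted or direct-track mode; every
#' other sighting is an incidental visual encounter (found by chance).
#'
#' @param sighted_id Sighted group id.
#' @param vessel_mode Vessel mode string at the time of sighting.
#' @param target_id Current acoustic target id (or `NA`).
#' @return `"acoustic_track"` or `"incidental_visual"`.
#' @export
classify_encounter <- function(sighted_id, vessel_mode, target_id) {
  if (!is.na(target_id) && sighted_id == target_id &&
      vessel_mode %in% c("TARGETED", "DIRECT")) "acoustic_track"
  else "incidental_visual"
}

# squared distance from points (x, y) to the segment (x1,y1)-(x2,y2), vectorised
dist2_to_segment <- function(x, y, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx * dx + dy * dy
  if (L2 < 1e-12) return((x - x1)^2 + (y - y1)^2)
  t <- pmin(1, pmax(0, ((x - x1) * dx + (y - y1) * dy) / L2))
  (x - (x1 + t * dx))^2 + (y - (y1 + t * dy))^2
}

# circular mean of a true bearing plus n independent Normal errors
noisy_bearing <- function(station, gpos, sd, n = 1L) {
  b <- true_bearing(station, gpos) + stats::rnorm(n, 0, sd)
  if (n == 1L) return(b %% 360)
  (atan2(mean(sin(b * DEG)), mean(cos(b * DEG))) / DEG) %% 360
}

# simulate all whale-group tracks for a replicate up front
simulate_tracks <- function(w, n_steps, dt, mp, dive, area, clumped) {
  n <- length(w$x)
  X <- matrix(0, n, n_steps); Y <- matrix(0, n, n_steps)
  VOC <- matrix(FALSE, n, n_steps)
  DIVING <- matrix(FALSE, n, n_steps)
  SURF_REM <- matrix(0, n, n_steps)
  for (k in seq_len(n_steps)) {
    w <- step_population(w, dt, mp, area, clumped)
    w <- update_dive_state(w, dt, dive)
    X[, k] <- w$x; Y[, k] <- w$y
    VOC[, k] <- is_vocalising(w, dive)
    if (dive$enabled) {
      DIVING[, k] <- w$diving
      SURF_REM[, k] <- ifelse(w$diving, 0, w$phase_duration - w$phase_elapsed)
    }
  }
  list(X = X, Y = Y, VOC = VOC, DIVING = DIVING, SURF_REM = SURF_REM, n = n)
}

#' Run one simulated survey replicate
#'
#' Advances the whole world (whales, weather, acoustics, vessel) over
#' `cfg$duration` hours in steps of `cfg$dt` and records every encounter,
#' tagged by source. Encounters are deduplicated per group: re-encounters
#' within a replicate are never logged, and already-marked groups are ignored
#' by acoustic targeting.
#'
#' @param cfg An [survey_config()] object.
#' @param seed Optional integer seed; all randomness in the replicate flows
#'   from this single stream, so equal seeds give bit-identical results.
#' @param track If `TRUE`, record the vessel state each tick; the result then
#'   carries a `track` data frame (`time, x, y, mode, target`) for debugging
#'   and plotting.
#' @return An object of class `amr_survey`: encounter table, effort hours,
#'   buoys used and encounter rates (per hour of total survey time,
#'   `rate = acoustic_rate + visual_rate`).
#' @export
run_survey <- function(cfg, seed = NULL, track = FALSE) {
  validate_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  dt <- cfg$dt
  n_steps <- as.integer(round(cfg$duration / dt))
  area <- cfg$area
  pop <- cfg$pop; mp <- cfg$move; dive <- cfg$dive
  ap <- cfg$ac; vp <- cfg$ves
  amr <- cfg$survey_mode == "AMR"
  lt <- cfg$survey_mode == "LT"
  hydro <- ap$instrument == "hydrophone"
  clumped <- pop$distribution == "clumped"
  esw2 <- vp$visual_esw_half^2
  recog <- vp$recognise_marked
  rng2 <- ap$effective_range^2
  vhf2 <- ap$vhf_range^2
  vstep <- vp$speed * dt
  dive_on <- dive$enabled

  wx <- generate_weather(cfg$wx, n_steps)
  daylight <- is_daylight((seq_len(n_steps) - 1) * dt, vp$dawn, vp$dusk,
                          cfg$start_hour)
  acoustic_ok_v <- wx$sea_state <= ap$max_sea_state &
    (cfg$overnight_acoustics | daylight)
  visual_ok_v <- daylight & wx$sightability >= vp$min_sightability &
    wx$sea_state <= 5

  w0 <- init_population(pop, area, dive)
  n <- length(w0$x)
  tr <- if (n > 0L) simulate_tracks(w0, n_steps, dt, mp, dive, area, clumped)
  encountered <- rep(FALSE, n)
  # identity-blind tracking still keeps short-term acoustic continuity on a
  # group the team just marked or just recognised: it is excluded from
  # targeting until contact has been stale for the pending-staleness window
  known_until <- rep(-Inf, n)

  # vessel state
  vx <- area[1] / 2; vy <- area[2] / 2
  mode <- "NAIVE"
  target <- NA_integer_
  tgt_ex <- NA_real_; tgt_ey <- NA_real_   # estimated target position
  ray <- NULL                              # list(sx, sy, brg) ray-following
  tracking_started <- -Inf
  last_bearing <- -Inf
  mark_remaining <- 0
  sweep_sign <- 1
  # dead reckoning of the target between acoustic fixes (hydrophone tracking)
  fix_t <- NA_real_
  tvel_x <- 0; tvel_y <- 0
  dwell_remaining <- 0
  dist_since_dip <- Inf
  time_since_listen <- Inf
  carry <- 0
  listen_now <- FALSE
  max_buoys <- if (amr && !hydro)
    as.integer(cfg$duration / min(ap$drop_interval_search,
                                  ap$drop_interval_target)) + 2L else 0L
  bx <- numeric(max_buoys); by <- numeric(max_buoys)
  bt <- numeric(max_buoys); bact <- logical(max_buoys)
  nb <- 0L
  last_drop <- -Inf
  # pending prior detections (FIFO with staleness cap)
  pn <- 0L
  pid <- integer(n); ppx <- numeric(n); ppy <- numeric(n); ppt <- numeric(n)

  grid <- search_grid(area, 2 * vp$visual_esw_half)
  gvis <- grid$visited
  nav_cell <- NA_integer_
  min_cell <- min(grid$cw, grid$ch)

  if (lt) {
    sp <- 4 * vp$visual_esw_half
    nlines <- max(1L, as.integer(floor(area[1] / sp)))
    lx <- (seq_len(nlines) - 0.5) * (area[1] / nlines)
    wpx <- rep(lx, each = 2)
    wpy <- as.vector(vapply(seq_len(nlines), function(i)
      if (i %% 2 == 1) c(0, area[2]) else c(area[2], 0), numeric(2)))
    wp_i <- 1L
    vx <- wpx[1]; vy <- wpy[1]
  }

  enc_id <- integer(n); enc_t <- numeric(n)
  enc_ac <- logical(n); enc_x <- numeric(n); enc_y <- numeric(n)
  n_enc <- 0L
  visual_hours <- 0
  buoys_used <- 0L
  if (track) {
    tk_x <- numeric(n_steps); tk_y <- numeric(n_steps)
    tk_mode <- character(n_steps); tk_tgt <- integer(n_steps)
  }
  # state-machine diagnostics (hours per mode, episode outcome counts)
  mode_hours <- c(NAIVE = 0, TARGETED = 0, DIRECT = 0, MARKING = 0, DWELL = 0)
  n_adopt <- n_giveup <- n_maxtrack <- n_abandon <- 0L
  n_surf_track <- n_surf_in_strip <- 0L
  surf_dists <- numeric(0)

  pend_add <- function(id, x, y, tnow) {
    j <- match(id, if (pn > 0L) pid[1:pn] else integer(0))
    if (!is.na(j)) {
      ppx[j] <<- x; ppy[j] <<- y; ppt[j] <<- tnow
    } else if (pn < n) {
      pn <<- pn + 1L
      pid[pn] <<- id; ppx[pn] <<- x; ppy[pn] <<- y; ppt[pn] <<- tnow
    }
  }
  pend_adopt <- function(tnow, fifo = TRUE) {
    if (!amr) return(FALSE)   # visual-only MR alternates naive search/marking
    if (pn > 0L) {
      keep <- which(ppt[1:pn] > tnow - vp$pending_staleness &
                      (!encountered[pid[1:pn]] |
                         (!recog & known_until[pid[1:pn]] < tnow)))
      m <- length(keep)
      if (m > 0L) {
        pid[1:m] <<- pid[keep]; ppx[1:m] <<- ppx[keep]
        ppy[1:m] <<- ppy[keep]; ppt[1:m] <<- ppt[keep]
      }
      pn <<- m
    }
    if (pn == 0L) return(FALSE)
    i <- if (fifo) 1L else pn
    target <<- pid[i]
    tgt_ex <<- ppx[i]; tgt_ey <<- ppy[i]
    ray <<- NULL
    fix_t <<- NA_real_; tvel_x <<- 0; tvel_y <<- 0
    mode <<- "TARGETED"
    tracking_started <<- tnow
    # the give-up clock runs from the last actual acoustic contact with the
    # whale, so revisits of stale detections time out sooner
    last_bearing <<- ppt[i]
    n_adopt <<- n_adopt + 1L
    if (i < pn) {
      idx <- (i + 1L):pn
      pid[i:(pn - 1L)] <<- pid[idx]; ppx[i:(pn - 1L)] <<- ppx[idx]
      ppy[i:(pn - 1L)] <<- ppy[idx]; ppt[i:(pn - 1L)] <<- ppt[idx]
    }
    pn <<- pn - 1L
    TRUE
  }

  for (k in seq_len(n_steps)) {
    if (track && k > 1L) {
      tk_x[k - 1L] <- vx; tk_y[k - 1L] <- vy
      tk_mode[k - 1L] <- if (lt) "LT" else mode
      tk_tgt[k - 1L] <- if (lt || is.na(target)) NA_integer_ else target
    }
    now <- (k - 1) * dt
    visual_ok <- visual_ok_v[k]
    if (visual_ok) visual_hours <- visual_hours + dt
    if (n > 0L) {
      wxk <- tr$X[, k]; wyk <- tr$Y[, k]
    }

    if (lt) {
      lpx <- vx; lpy <- vy
      travel <- vstep
      while (travel > 0) {
        ddx <- wpx[wp_i] - vx; ddy <- wpy[wp_i] - vy
        d <- sqrt(ddx * ddx + ddy * ddy)
        if (d > travel) {
          vx <- vx + ddx / d * travel
          vy <- vy + ddy / d * travel
          travel <- 0
        } else {
          vx <- wpx[wp_i]; vy <- wpy[wp_i]
          travel <- travel - d
          wp_i <- wp_i + 1L
          if (wp_i > length(wpx)) { wp_i <- 1L; travel <- 0 }
        }
      }
      if (visual_ok && n > 0L) {
        d2 <- dist2_to_segment(wxk, wyk, lpx, lpy, vx, vy)
        avail <- !encountered & d2 <= esw2
        if (dive_on) avail <- avail & !tr$DIVING[, k]
        seen <- which(avail)
        if (length(seen) > 0L && vp$g0 < 1)
          seen <- seen[stats::runif(length(seen)) < vp$g0]
        for (id in seen) {
          n_enc <- n_enc + 1L
          enc_id[n_enc] <- id; enc_t[n_enc] <- now + dt
          enc_ac[n_enc] <- FALSE
          enc_x[n_enc] <- wxk[id]; enc_y[n_enc] <- wyk[id]
          encountered[id] <- TRUE
        }
      }
      next
    }

    # --- sonobuoy lifecycle + drops ---
    if (amr && !hydro) {
      if (nb > 0L) {
        act <- which(bact[1:nb])
        if (length(act) > 0L) {
          d2b <- (bx[act] - vx)^2 + (by[act] - vy)^2
          bact[act] <- (now - bt[act] < ap$buoy_life) & (d2b <= vhf2)
        }
      }
      targeting <- mode == "TARGETED" || mode == "DIRECT"
      if (mode != "MARKING" &&
          now - last_drop >= (if (targeting) ap$drop_interval_target
                              else ap$drop_interval_search)) {
        nb <- nb + 1L
        bx[nb] <- vx; by[nb] <- vy; bt[nb] <- now; bact[nb] <- TRUE
        last_drop <- now
        buoys_used <- buoys_used + 1L
      }
    }

    # --- listening / bearing events ---
    if (hydro && !lt) {
      # the stop-start listening-station cadence is part of the vessel
      # protocol; in a visual-only survey the stations yield no information
      # but the vessel still runs the same pattern (the visual-only survey is
      # the baseline case of the acoustic one)
      time_since_listen <- time_since_listen + dt
      listen_now <- FALSE
      if (dwell_remaining <= 1e-9 && (mode == "NAIVE" || mode == "TARGETED")) {
        if (dist_since_dip >= ap$dip_spacing) {
          listen_now <- TRUE
        } else if (mode == "TARGETED" && !is.na(tgt_ex) &&
                   (tgt_ex - vx)^2 + (tgt_ey - vy)^2 < 0.09 &&
                   time_since_listen >= ap$dwell_time * 0.99) {
          # a vessel holding at the estimated position is a continuous
          # listening station: re-listen every dwell rather than waiting
          # on a silent whale at the underway dip cadence
          listen_now <- TRUE
        }
      }
      if (listen_now) {
        # dwell rounded to whole ticks (nearest, at least one when nonzero)
        dwell_remaining <- max(if (ap$dwell_time > 0) 1 else 0,
                               round(ap$dwell_time / dt)) * dt - 1e-9
        dist_since_dip <- 0
        time_since_listen <- 0
      } else {
        listen_now <- FALSE
      }
    }
    if (amr && acoustic_ok_v[k] && n > 0L) {
      if (hydro) {
        if (listen_now) {
          d2 <- (wxk - vx)^2 + (wyk - vy)^2
          det <- which(tr$VOC[, k] & d2 <= rng2 &
                         (!encountered | (!recog & known_until < now)))
          nd <- length(det)
          if (nd > 0L) {
            tb <- (atan2(wxk[det] - vx, wyk[det] - vy) / DEG +
                     stats::rnorm(nd, 0, ap$bearing_sd)) %% 360
            # detection implies the source is within the effective range, so
            # the aural estimate is capped there
            dst <- if (ap$distance_additive)
              pmax(0.1, sqrt(d2[det]) + stats::rnorm(nd, 0, ap$distance_sd_frac))
            else
              pmax(0.1, sqrt(d2[det]) * (1 + stats::rnorm(nd, 0, ap$distance_sd_frac)))
            dst <- pmin(dst, ap$effective_range)
            ex <- vx + dst * sin(tb * DEG)
            ey <- vy + dst * cos(tb * DEG)
            if (mode == "TARGETED" && !is.na(target) && target %in% det) {
              j <- match(target, det)
              last_bearing <- now
              # alpha-beta tracking filter over successive noisy fixes: smooth
              # the position and carry a course estimate, so the dead-reckoned
              # track stays near the whale through its silent pre-surfacing
              # tail (the estimate is advanced by the velocity every tick)
              if (is.na(fix_t)) {
                tgt_ex <- ex[j]; tgt_ey <- ey[j]
                tvel_x <- 0; tvel_y <- 0
              } else {
                g <- max(now - fix_t, dt)
                rx <- ex[j] - tgt_ex; ry <- ey[j] - tgt_ey
                # close fixes have small absolute error: weight them harder
                al <- if (dst[j] < 2) 0.6 else 0.5
                tgt_ex <- tgt_ex + al * rx
                tgt_ey <- tgt_ey + al * ry
                tvel_x <- tvel_x + 0.25 * rx / g
                tvel_y <- tvel_y + 0.25 * ry / g
                spd <- sqrt(tvel_x^2 + tvel_y^2)
                if (spd > 10) { tvel_x <- tvel_x * 10 / spd; tvel_y <- tvel_y * 10 / spd }
              }
              fix_t <- now
              for (j2 in seq_len(nd)) if (det[j2] != target)
                pend_add(det[j2], ex[j2], ey[j2], now)
            } else if (mode == "NAIVE") {
              j <- which.min((ex - vx)^2 + (ey - vy)^2)
              target <- det[j]
              tgt_ex <- ex[j]; tgt_ey <- ey[j]
              mode <- "TARGETED"
              tracking_started <- now
              last_bearing <- now
              n_adopt <- n_adopt + 1L
              fix_t <- now
              tvel_x <- 0; tvel_y <- 0
              for (j2 in seq_len(nd)) if (j2 != j)
                pend_add(det[j2], ex[j2], ey[j2], now)
            } else {
              for (j2 in seq_len(nd)) pend_add(det[j2], ex[j2], ey[j2], now)
            }
          }
        }
      } else {
        acc <- carry + ap$bearings_per_hour * dt
        nbear <- as.integer(floor(acc + 1e-9))
        carry <- acc - nbear
        if (nbear > 0L && nb > 0L && any(bact[1:nb])) {
          ab <- which(bact[1:nb])
          ab <- ab[order(bt[ab], decreasing = TRUE)]  # most recent first
          na_b <- length(ab)
          vocal_free <- tr$VOC[, k] &
            (!encountered | (!recog & known_until < now))
          if (mode %in% c("TARGETED", "DIRECT") && !is.na(target)) {
            gx <- wxk[target]; gy <- wyk[target]
            d2t <- (bx[ab] - gx)^2 + (by[ab] - gy)^2
            sees <- ab[d2t <= rng2]
            ns <- length(sees)
            if (ns >= 1L) {
              s1 <- c(bx[sees[1]], by[sees[1]])
              b1 <- noisy_bearing(s1, c(gx, gy), ap$bearing_sd)
              fx <- NULL
              if (ns >= 2L) {
                s2 <- c(bx[sees[2]], by[sees[2]])
                b2 <- noisy_bearing(s2, c(gx, gy), ap$bearing_sd)
                fx <- cross_fix(s1, b1, s2, b2)
              }
              if (!is.null(fx)) {
                tgt_ex <- fx[1]; tgt_ey <- fx[2]
                ray <- NULL
                mode <- "DIRECT"
              } else {
                ray <- list(sx = s1[1], sy = s1[2], brg = b1)
                tgt_ex <- NA_real_; tgt_ey <- NA_real_
                mode <- "TARGETED"
              }
              last_bearing <- now
            }
            # other audible groups seen by the most recent buoy -> pending
            j1 <- ab[1]
            d2o <- (wxk - bx[j1])^2 + (wyk - by[j1])^2
            oth <- which(vocal_free & d2o <= rng2)
            for (id in oth) if (id != target)
              pend_add(id, bx[j1], by[j1], now)
          } else if (mode == "MARKING") {
            # the whole team works the group being marked; no acoustic watch
          } else {
            # searching: collect detections per buoy, nearest estimated source
            det_any <- logical(n)
            first_buoy <- integer(n)
            second_buoy <- integer(n)
            for (j in seq_len(na_b)) {
              bj <- ab[j]
              d2b <- (wxk - bx[bj])^2 + (wyk - by[bj])^2
              dj <- vocal_free & d2b <= rng2
              newly <- dj & !det_any
              second <- dj & det_any & second_buoy == 0L
              first_buoy[newly] <- bj
              second_buoy[second] <- bj
              det_any <- det_any | dj
            }
            all_det <- which(det_any)
            if (length(all_det) > 0L) {
              estx <- esty <- numeric(length(all_det))
              for (q in seq_along(all_det)) {
                id <- all_det[q]
                i1 <- first_buoy[id]; i2 <- second_buoy[id]
                fx <- NULL
                if (i2 > 0L) {
                  gp <- c(wxk[id], wyk[id])
                  fx <- cross_fix(c(bx[i1], by[i1]),
                                  noisy_bearing(c(bx[i1], by[i1]), gp,
                                                ap$bearing_sd),
                                  c(bx[i2], by[i2]),
                                  noisy_bearing(c(bx[i2], by[i2]), gp,
                                                ap$bearing_sd))
                }
                if (is.null(fx)) fx <- c(bx[i1], by[i1])
                estx[q] <- fx[1]; esty[q] <- fx[2]
              }
              q <- which.min((estx - vx)^2 + (esty - vy)^2)
              target <- all_det[q]
              tgt_ex <- estx[q]; tgt_ey <- esty[q]
              ray <- NULL
              mode <- "TARGETED"
              tracking_started <- now
              last_bearing <- now
              n_adopt <- n_adopt + 1L
              for (q2 in seq_along(all_det)) if (q2 != q)
                pend_add(all_det[q2], estx[q2], esty[q2], now)
            }
          }
        }
      }
    }

    if (dive_on && mode == "TARGETED" && !is.na(target) && k > 1L &&
        tr$SURF_REM[target, k] > 0 && tr$SURF_REM[target, k - 1L] == 0) {
      n_surf_track <- n_surf_track + 1L
      sdist <- sqrt((wxk[target] - vx)^2 + (wyk[target] - vy)^2)
      surf_dists <- c(surf_dists, sdist)
      if (sdist^2 <= esw2) n_surf_in_strip <- n_surf_in_strip + 1L
    }
    # dead-reckon the target estimate between fixes
    if (hydro && mode == "TARGETED" && !is.na(tgt_ex) &&
        (tvel_x != 0 || tvel_y != 0) && !is.na(fix_t) && fix_t < now) {
      tgt_ex <- min(max(tgt_ex + tvel_x * dt, 0), area[1])
      tgt_ey <- min(max(tgt_ey + tvel_y * dt, 0), area[2])
    }

    # --- tracking time-outs ---
    if (mode == "TARGETED" || mode == "DIRECT") {
      if (vp$p_abandon_per_hour > 0 &&
          stats::runif(1) < 1 - (1 - vp$p_abandon_per_hour)^dt) {
        target <- NA_integer_; ray <- NULL
        tgt_ex <- NA_real_; tgt_ey <- NA_real_
        fix_t <- NA_real_; tvel_x <- 0; tvel_y <- 0
        mode <- "NAIVE"
        n_abandon <- n_abandon + 1L
      } else if (now - tracking_started >= vp$max_tracking_time) {
        target <- NA_integer_; ray <- NULL
        tgt_ex <- NA_real_; tgt_ey <- NA_real_
        fix_t <- NA_real_; tvel_x <- 0; tvel_y <- 0
        mode <- "NAIVE"
        n_maxtrack <- n_maxtrack + 1L
      } else if (now - last_bearing >= vp$give_up_time) {
        target <- NA_integer_; ray <- NULL
        tgt_ex <- NA_real_; tgt_ey <- NA_real_
        fix_t <- NA_real_; tvel_x <- 0; tvel_y <- 0
        mode <- "NAIVE"
        n_giveup <- n_giveup + 1L
        pend_adopt(now, fifo = FALSE)  # retarget the freshest detection
      }
    }
    mode_hours[[if (hydro && dwell_remaining > 1e-9 && mode != "MARKING")
      "DWELL" else mode]] <- mode_hours[[if (hydro && dwell_remaining > 1e-9 &&
      mode != "MARKING") "DWELL" else mode]] + dt

    # --- vessel decision + movement ---
    px <- vx; py <- vy
    moved <- 0
    if (wx$sea_state[k] > 5) {
      # above Beaufort 5 all operations are suspended: the vessel heaves to
      # (tracking clocks keep running, so long storms lose targets)
    } else if (!daylight[k] && !(amr && acoustic_ok_v[k])) {
      # without operable acoustics there is nothing to do in the dark: the
      # vessel drifts overnight and resumes at first light
    } else if (mode == "MARKING") {
      # the vessel works alongside the group it is marking, so it drifts with
      # the group (and stays with its aggregation) rather than anchoring
      if (!is.na(target) && n > 0L) {
        vx <- wxk[target]; vy <- wyk[target]
      }
      if (visual_ok) {
        mark_remaining <- mark_remaining - dt
        if (mark_remaining <= 0) {
          target <- NA_integer_
          if (!pend_adopt(now + dt)) mode <- "NAIVE"
        }
      } else if (!vp$mark_until_fluke && mark_remaining < vp$time_to_mark) {
        # an identification session interrupted by nightfall or weather
        # cannot be resumed against a re-mixed group hours later: it restarts
        mark_remaining <- vp$time_to_mark
      }
    } else if (hydro && dwell_remaining > 1e-9) {
      dwell_remaining <- dwell_remaining - dt   # stationary listening stop
    } else if (mode == "NAIVE") {
      if (is.na(nav_cell) || gvis[nav_cell]) {
        if (all(gvis)) gvis[] <- FALSE
        grid$visited <- gvis
        ns <- naive_search_heading(grid, c(vx, vy), sweep_sign)
        nav_cell <- ns$cell
        sh <- sin(ns$heading * DEG)
        if (abs(sh) > 0.2) sweep_sign <- sign(sh)
      }
      ddx <- grid$cx[nav_cell] - vx; ddy <- grid$cy[nav_cell] - vy
      d <- sqrt(ddx * ddx + ddy * ddy)
      if (d <= 1e-9) {
        # already at the cell centre; marked below, new cell next tick
      } else if (d <= vstep) {
        vx <- grid$cx[nav_cell]; vy <- grid$cy[nav_cell]
        moved <- d
      } else {
        vx <- vx + ddx / d * vstep
        vy <- vy + ddy / d * vstep
        moved <- vstep
      }
    } else if (mode == "TARGETED" || mode == "DIRECT") {
      if (!is.null(ray)) {
        hd <- targeted_heading(c(vx, vy), c(ray$sx, ray$sy), ray$brg,
                               vp$corridor_half_width)
        vx <- vx + vstep * sin(hd * DEG)
        vy <- vy + vstep * cos(hd * DEG)
        moved <- vstep
        if (vx < 0) vx <- 0 else if (vx > area[1]) vx <- area[1]
        if (vy < 0) vy <- 0 else if (vy > area[2]) vy <- area[2]
      } else if (!is.na(tgt_ex)) {
        ddx <- tgt_ex - vx; ddy <- tgt_ey - vy
        d <- sqrt(ddx * ddx + ddy * ddy)
        if (d <= vstep) {
          vx <- tgt_ex; vy <- tgt_ey
          moved <- d
        } else {
          vx <- vx + ddx / d * vstep
          vy <- vy + ddy / d * vstep
          moved <- vstep
        }
      }
    }
    if (moved > 0) {
      dist_since_dip <- dist_since_dip + moved
      if (moved > min_cell)   # long steps also sweep the midpoint
        gvis[grid_cell_at(grid, (vx + px) / 2, (vy + py) / 2)] <- TRUE
    }
    gvis[grid_cell_at(grid, vx, vy)] <- TRUE

    # an already-marked target is recognised once sighted in workable
    # conditions and released without logging a re-encounter
    if (!recog && visual_ok && !is.na(target) && mode != "MARKING" &&
        n > 0L && encountered[target] &&
        (wxk[target] - vx)^2 + (wyk[target] - vy)^2 <= esw2) {
      known_until[target] <- now + vp$pending_staleness
      target <- NA_integer_; ray <- NULL
      tgt_ex <- NA_real_; tgt_ey <- NA_real_
      fix_t <- NA_real_; tvel_x <- 0; tvel_y <- 0
      mode <- "NAIVE"
      if (!pend_adopt(now + dt)) mode <- "NAIVE"
    }

    # --- visual detection + encounter logging ---
    if (amr && hydro && mode == "MARKING" && visual_ok && n > 0L) {
      # observers still watch while marking: unmarked groups surfacing inside
      # the strip are queued for a revisit, not encountered
      d2 <- (wxk - vx)^2 + (wyk - vy)^2
      avail <- !encountered & d2 <= esw2
      if (dive_on) avail <- avail & tr$SURF_REM[, k] > 0
      for (id in which(avail)) pend_add(id, wxk[id], wyk[id], now)
    }
    # at small-boat transit speed the observers only search effectively when
    # the vessel is stopped or at a listening station; a tracking team
    # underway, however, is on full alert watching for the surfacing
    scan_now <- !hydro || moved == 0 || listen_now ||
      ((mode == "TARGETED" || mode == "DIRECT") && !is.na(target))
    if (mode != "MARKING" && visual_ok && scan_now && n > 0L) {
      # the strip swept this tick is the capsule around the movement segment,
      # so coarse steps do not leave gaps between per-tick detection discs
      d2 <- if (moved > 0) dist2_to_segment(wxk, wyk, px, py, vx, vy)
            else (wxk - vx)^2 + (wyk - vy)^2
      avail <- !encountered & d2 <= esw2
      if (dive_on) avail <- avail & tr$SURF_REM[, k] > 0
      seen <- which(avail)
      if (length(seen) > 0L && vp$g0 < 1)
        seen <- seen[stats::runif(length(seen)) < vp$g0]
      if (length(seen) > 0L) {
        sighted <- if (!is.na(target) && target %in% seen) target
                   else seen[which.min(d2[seen])]
        is_ac <- !is.na(target) && sighted == target &&
          (mode == "TARGETED" || mode == "DIRECT")
        n_enc <- n_enc + 1L
        enc_id[n_enc] <- sighted; enc_t[n_enc] <- now + dt
        enc_ac[n_enc] <- is_ac
        enc_x[n_enc] <- wxk[sighted]; enc_y[n_enc] <- wyk[sighted]
        encountered[sighted] <- TRUE
        known_until[sighted] <- now + vp$pending_staleness
        if (!is.na(target) && target != sighted)
          pend_add(target, if (is.na(tgt_ex)) wxk[target] else tgt_ex,
                   if (is.na(tgt_ey)) wyk[target] else tgt_ey, now)
        target <- sighted
        ray <- NULL
        tgt_ex <- NA_real_; tgt_ey <- NA_real_
        fix_t <- NA_real_; tvel_x <- 0; tvel_y <- 0
        mark_remaining <- if (vp$mark_until_fluke && dive_on)
          tr$SURF_REM[sighted, k] else vp$time_to_mark
        mode <- "MARKING"
        if (mark_remaining <= 0) {
          target <- NA_integer_
          if (!pend_adopt(now + dt)) mode <- "NAIVE"
        }
      }
    }
  }

  if (track) {
    tk_x[n_steps] <- vx; tk_y[n_steps] <- vy
    tk_mode[n_steps] <- if (lt) "LT" else mode
    tk_tgt[n_steps] <- if (lt || is.na(target)) NA_integer_ else target
  }
  keep <- seq_len(n_enc)
  enc <- data.frame(group = enc_id[keep], time = enc_t[keep],
                    source = ifelse(enc_ac[keep], "acoustic_track",
                                    "incidental_visual"),
                    x = enc_x[keep], y = enc_y[keep], stringsAsFactors = FALSE)
  n_ac <- sum(enc_ac[keep])
  res <- list(encounters = enc, total_hours = cfg$duration,
              on_effort_visual_hours = visual_hours, buoys_used = buoys_used,
              n_groups = n, encounter_rate = n_enc / cfg$duration,
              acoustic_rate = n_ac / cfg$duration,
              visual_rate = (n_enc - n_ac) / cfg$duration,
              survey_mode = cfg$survey_mode, label = cfg$label, seed = seed,
              diag = list(mode_hours = mode_hours, targets_adopted = n_adopt,
                          giveups = n_giveup, maxtracks = n_maxtrack,
                          abandons = n_abandon, surfacings_tracked = n_surf_track,
                          surfacings_in_strip = n_surf_in_strip,
                          surf_dists = surf_dists))
  if (track)
    res$track <- data.frame(time = seq_len(n_steps) * dt, x = tk_x, y = tk_y,
                            mode = tk_mode, target = tk_tgt,
                            stringsAsFactors = FALSE)
  class(res) <- "amr_survey"
  res
}

#' @export
print.amr_survey <- function(x, ...) {
  cat(sprintf("<amr_survey> %s %s: %d encounters in %g h (%.4g /h; acoustic %.4g, visual %.4g)\n",
              x$label, x$survey_mode, nrow(x$encounters), x$total_hours,
              x$encounter_rate, x$acoustic_rate, x$visual_rate))
  if (x$survey_mode == "AMR") cat(sprintf("  buoys used: %d\n", x$buoys_used))
  invisible(x)
}

#' @export
summary.amr_survey <- function(object, ...) {
  cat(sprintf("%s survey (%s), %g h at seed %s\n", object$survey_mode,
              object$label, object$total_hours,
              if (is.null(object$seed)) "<none>" else object$seed))
  cat(sprintf("  groups simulated: %d; encounters: %d (%d acoustic-track, %d incidental)\n",
              object$n_groups, nrow(object$encounters),
              sum(object$encounters$source == "acoustic_track"),
              sum(object$encounters$source == "incidental_visual")))
  cat(sprintf("  rates (/h): total %.4g = acoustic %.4g + visual %.4g\n",
              object$encounter_rate, object$acoustic_rate, object$visual_rate))
  cat(sprintf("  on-effort visual hours: %.1f; sonobuoys used: %d\n",
              object$on_effort_visual_hours, object$buoys_used))
  mh <- object$diag$mode_hours
  cat("  mode hours:", paste(sprintf("%s %.1f", names(mh), mh), collapse = ", "),
      "\n")
  invisible(object)
}

#' Simulate a sequence of independent survey days
#'
#' Each day is an independent replicate with a freshly drawn population (the
#' group count is redrawn, e.g. from its Normal distribution) and its own
#' derived seed; rates are per day of `cfg$duration` hours.
#'
#' @param cfg An [survey_config()] object (its `duration` is one day's effort).
#' @param n_days Number of days.
#' @param seed Root integer seed.
#' @return Data frame with one row per day: `day, seed, n_groups, encounters,
#'   acoustic, visual, hours, buoys_used, rate, acoustic_rate, visual_rate`.
#' @export
run_day_sequence <- function(cfg, n_days, seed = 1) {
  stopifnot(n_days >= 1)
  day <- seq_len(n_days)
  seeds <- vapply(day, function(d) derive_seed(seed, 0L, d), integer(1))
  ng <- enc <- ac <- vis <- bu <- integer(n_days)
  for (d in day) {
    r <- run_survey(cfg, seeds[d])
    ng[d] <- r$n_groups
    enc[d] <- nrow(r$encounters)
    ac[d] <- sum(r$encounters$source == "acoustic_track")
    vis[d] <- enc[d] - ac[d]
    bu[d] <- r$buoys_used
  }
  data.frame(day = day, seed = seeds, n_groups = ng, encounters = enc,
             acoustic = ac, visual = vis, hours = cfg$duration,
             buoys_used = bu, rate = enc / cfg$duration,
             acoustic_rate = ac / cfg$duration,
             visual_rate = vis / cfg$duration)
}
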