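# Synthetic session generator with planted ground truth.
#
# Generates head-fixed linear-track sessions whose statistical structure
# mirrors what is reported for the dentate gyrus: sparse granule-cell onsets
# (~1 event/min/cell), immobility-locked synchronous network events recruiting
# ~5-7% of cells, correlated sub-ensembles recruited across events, a minority
# of place- and speed-tuned cells, bulk MPP transients leading network events,
# and pupil constriction at network events. Every planted feature is returned
# as ground truth so detection stages can be validated end to end.

#' Generator parameters
#'
#' Defaults encode the study conditions: 20-minute sessions at 15 Hz on a
#' 150 cm belt, ~1 background event/min/cell, 30 planted network events of
#' mean size 11 cells (~5.7% of 200 cells), four sub-ensembles of 7 cells,
#' 5% place cells and 2% speed cells, MPP transients leading network events
#' by 2 frames, and pupil dips at network events.
#'
#' @param n_cells number of granule cells.
#' @param duration_s session length in seconds (default 1200).
#' @param frame_rate imaging rate in Hz (default 15).
#' @param belt_length belt length in cm (default 150).
#' @param baseline_rate background onset rate, events/min/cell (default 1).
#' @param run_bout_mean_s,rest_bout_mean_s mean bout durations (s).
#' @param run_speed_range plateau running speed range (cm/s), above the 4 cm/s
#'   locomotion threshold.
#' @param n_planted_nes number of planted network events.
#' @param ne_size_mean,ne_size_sd planted event size distribution (cells).
#' @param ne_jitter onset jitter around the event frame (frames each side).
#' @param n_clusters,cluster_size planted sub-ensemble count and size.
#' @param ne_member_p probability that a pool member joins its event.
#' @param place_frac,place_kappa,place_extra_rate place-cell fraction, field
#'   concentration (von Mises kappa), and extra in-field onset rate
#'   (events/min during running).
#' @param speed_frac,speed_slope speed-cell fraction and dF/F slope per cm/s.
#' @param replay_strength coupling of sub-ensembles to shared run-epoch
#'   activity (0 disables; 1 default). Nonzero coupling adds a common
#'   field-modulated dF/F drive to each sub-ensemble during locomotion, so
#'   that network-event covariance aligns with locomotion covariance.
#' @param replay_dff_amp peak amplitude of the shared drive (dF/F units).
#' @param replay_kappa concentration of the shared cluster field.
#' @param mpp_lead_frames frames by which the bulk MPP transient leads each
#'   network event.
#' @param mpp_run_rate,mpp_rest_rate small-transient rates (events/s).
#' @param pupil_dip pupil constriction amplitude at network events
#'   (normalized units).
#' @param tau calcium decay time constant in seconds (default 1.5,
#'   GCaMP6s-like).
#' @param amplitude single-event dF/F amplitude.
#' @param noise_sd additive dF/F noise standard deviation.
#' @param blink_prob per-frame blink probability of the pupil channel.
#' @return list of class `dg_params`.
#' @export
generator_params <- function(n_cells = 200L, duration_s = 1200, frame_rate = 15,
                             belt_length = 150, baseline_rate = 1.0,
                             run_bout_mean_s = 8, rest_bout_mean_s = 20,
                             run_speed_range = c(8, 14),
                             n_planted_nes = 30L, ne_size_mean = 11,
                             ne_size_sd = 1.5, ne_jitter = 1L,
                             n_clusters = 4L, cluster_size = 7L,
                             ne_member_p = 0.9,
                             place_frac = 0.05, place_kappa = 4,
                             place_extra_rate = 3,
                             speed_frac = 0.02, speed_slope = 0.03,
                             replay_strength = 1, replay_dff_amp = 0.5,
                             replay_kappa = 4,
                             mpp_lead_frames = 2L, mpp_run_rate = 0.8,
                             mpp_rest_rate = 0.2,
                             pupil_dip = 0.15, tau = 1.5, amplitude = 1,
                             noise_sd = 0.05, blink_prob = 0.003) {
  p <- as.list(environment())
  stopifnot(p$n_cells >= 1, p$duration_s > 0, p$frame_rate > 0,
            p$belt_length > 0, p$baseline_rate >= 0,
            p$place_frac >= 0, p$place_frac <= 1,
            p$speed_frac >= 0, p$speed_frac <= 1, p$tau > 0)
  structure(p, class = "dg_params")
}

#' Generate treadmill behavior
#'
#' Alternating rest and run bouts (gamma-distributed durations). During run
#' bouts the speed ramps smoothly between just above the 4 cm/s locomotion
#' threshold and a per-bout plateau; during rest the animal is completely
#' immobile (speed exactly 0). Position integrates speed modulo the belt
#' length.
#'
#' @param p a `dg_params`.
#' @param seed integer seed.
#' @return list with `speed`, `position`, and `epochs` (run/rest data.frame).
#' @export
generate_behavior <- function(p, seed = 1L) {
  set.seed(seed)
  nf <- round(p$duration_s * p$frame_rate)
  speed <- numeric(nf)
  ep <- NULL
  t <- 1L
  running <- FALSE                  # sessions start at rest
  while (t <= nf) {
    if (running && p$run_bout_mean_s > 0) {
      dur <- max(3.5, stats::rgamma(1L, shape = 4,
                                    scale = p$run_bout_mean_s / 4))
      len <- min(round(dur * p$frame_rate), nf - t + 1L)
      if (len >= ceiling(2.5 * p$frame_rate)) {
        plateau <- stats::runif(1L, p$run_speed_range[1L],
                                p$run_speed_range[2L])
        ramp <- min(round(0.5 * p$frame_rate), floor(len / 3))
        prof <- rep(plateau, len)
        if (ramp > 0) {
          prof[seq_len(ramp)] <- seq(4.5, plateau, length.out = ramp)
          prof[(len - ramp + 1L):len] <- seq(plateau, 4.5, length.out = ramp)
        }
        prof <- prof + 0.3 * sin(seq_len(len) / 3)
        speed[t:(t + len - 1L)] <- pmax(prof, 4.2)
        ep <- rbind(ep, data.frame(start = t, end = t + len - 1L,
                                   state = "run"))
        t <- t + len
      }
    } else {
      dur <- max(2, stats::rgamma(1L, shape = 2, scale = p$rest_bout_mean_s / 2))
      len <- min(round(dur * p$frame_rate), nf - t + 1L)
      ep <- rbind(ep, data.frame(start = t, end = t + len - 1L,
                                 state = "rest"))
      t <- t + len
    }
    running <- !running
  }
  # merge adjacent rest rows (appear when a run bout was skipped as too short)
  ep <- ep[order(ep$start), , drop = FALSE]
  merged <- ep[1L, , drop = FALSE]
  for (i in seq_len(nrow(ep))[-1L]) {
    j <- nrow(merged)
    if (ep$state[i] == merged$state[j] && ep$start[i] == merged$end[j] + 1L)
      merged$end[j] <- ep$end[i]
    else merged <- rbind(merged, ep[i, , drop = FALSE])
  }
  rownames(merged) <- NULL
  position <- (cumsum(speed) / p$frame_rate) %% p$belt_length
  list(speed = speed, position = position, epochs = merged)
}

#' @keywords internal
#' @noRd
vonmises_rate <- function(theta, mu, kappa) {
  # rate modulation with unit mean over a uniform angle
  exp(kappa * cos(theta - mu)) / besselI(kappa, 0)
}

#' Plant an event-onset raster with ground truth
#'
#' Background onsets are Poisson at `baseline_rate` per cell. Planted network
#' events are placed at immobility frames (minimum 3 s separation, away from
#' epoch edges); each event recruits one designated sub-ensemble (cyclically)
#' plus random filler cells up to the drawn event size, with onsets jittered
#' within `ne_jitter` frames. Place cells receive extra run-epoch onsets with
#' circular von Mises tuning; sub-ensemble cells receive shared-field extra
#' onsets scaled by `replay_strength`; speed cells receive a rate scaling
#' linear in speed.
#'
#' @param p a `dg_params`.
#' @param behavior output of [generate_behavior()].
#' @param seed integer seed.
#' @return list with `raster` (binary matrix) and `truth` (class
#'   `dg_truth`): planted `ne_frames`, `ne_members`, `cluster_members`,
#'   `place_cells` (cell, center_cm, kappa), `speed_cells` (cell, slope),
#'   `params_used`, `seed`.
#' @export
plant_raster <- function(p, behavior, seed = 1L) {
  set.seed(seed)
  nf <- length(behavior$speed)
  ncl <- p$n_cells
  epochs <- behavior$epochs
  run_f <- frames_in_epochs(epochs, "run")
  rest_f <- frames_in_epochs(epochs, "rest")

  # cell role assignment: sub-ensemble pools, then place, then speed cells
  ids <- seq_len(ncl)
  n_pool <- p$n_clusters * p$cluster_size
  if (n_pool > ncl) stop("cluster pools exceed the number of cells")
  pool_ids <- if (n_pool > 0L) sample(ids, n_pool) else integer(0)
  cluster_members <- if (p$n_clusters > 0L)
    split(pool_ids, rep(seq_len(p$n_clusters), each = p$cluster_size))
  else list()
  rest_ids <- setdiff(ids, pool_ids)
  n_place <- round(p$place_frac * ncl)
  place_ids <- if (n_place > 0L) sort(sample(rest_ids, n_place)) else integer(0)
  rest_ids <- setdiff(rest_ids, place_ids)
  n_speed <- round(p$speed_frac * ncl)
  speed_ids <- if (n_speed > 0L) sort(sample(rest_ids, n_speed)) else integer(0)

  # per-frame background intensity (events per frame)
  base_pf <- p$baseline_rate / 60 / p$frame_rate
  lambda <- matrix(base_pf, ncl, nf)
  theta <- 2 * pi * behavior$position / p$belt_length
  place_centers <- stats::runif(n_place, 0, p$belt_length)
  if (n_place > 0L) {
    extra_pf <- p$place_extra_rate / 60 / p$frame_rate
    for (j in seq_len(n_place)) {
      mu <- 2 * pi * place_centers[j] / p$belt_length
      add <- numeric(nf)
      add[run_f] <- extra_pf * vonmises_rate(theta[run_f], mu, p$place_kappa)
      lambda[place_ids[j], ] <- lambda[place_ids[j], ] + add
    }
  }
  if (n_speed > 0L) {
    mult <- 1 + behavior$speed / 20       # mild rate scaling with speed
    lambda[speed_ids, ] <- lambda[speed_ids, , drop = FALSE] *
      matrix(mult, n_speed, nf, byrow = TRUE)
  }
  raster <- matrix(as.numeric(stats::runif(ncl * nf) < lambda), ncl, nf)
  cluster_centers <- stats::runif(max(p$n_clusters, 0L), 0, p$belt_length)

  # planted network events at immobility frames
  ne_frames <- integer(0); ne_members <- list()
  if (p$n_planted_nes > 0L) {
    margin <- p$ne_jitter + 1L
    rest_ok <- rest_f[rest_f > margin & rest_f <= nf - margin]
    # respect a 3 s minimum separation via greedy thinning of a random draw
    cand <- sort(sample(rest_ok, min(length(rest_ok), 20L * p$n_planted_nes)))
    sel <- integer(0)
    min_sep <- 3 * p$frame_rate
    for (f in cand) {
      if (length(sel) == p$n_planted_nes) break
      if (length(sel) == 0L || f - sel[length(sel)] >= min_sep)
        sel <- c(sel, f)
    }
    if (length(sel) < p$n_planted_nes)
      warning("placed only ", length(sel), " of ", p$n_planted_nes,
              " network events (not enough immobility)")
    for (e in seq_along(sel)) {
      f <- sel[e]
      size <- max(2L, min(ncl, round(stats::rnorm(1L, p$ne_size_mean,
                                                  p$ne_size_sd))))
      if (size > ncl) stop("network-event size exceeds the number of cells")
      members <- integer(0)
      if (p$n_clusters > 0L) {
        pool <- cluster_members[[(e - 1L) %% p$n_clusters + 1L]]
        members <- pool[stats::runif(length(pool)) < p$ne_member_p]
      }
      fill <- setdiff(ids, members)
      extra <- max(0L, size - length(members))
      if (extra > 0L)
        members <- c(members, sample(fill, min(extra, length(fill))))
      members <- sort(members)
      jit <- sample((-p$ne_jitter):p$ne_jitter, length(members),
                    replace = TRUE)
      raster[cbind(members, f + jit)] <- 1
      ne_frames <- c(ne_frames, f)
      ne_members <- c(ne_members, list(members))
    }
  }
  truth <- structure(list(
    ne_frames = ne_frames, ne_members = ne_members,
    cluster_members = cluster_members,
    cluster_centers_cm = cluster_centers,
    place_cells = data.frame(cell = place_ids, center_cm = place_centers,
                             kappa = rep(p$place_kappa, n_place)),
    speed_cells = data.frame(cell = speed_ids,
                             slope = rep(p$speed_slope, n_speed)),
    mpp_event_frames = integer(0),
    params_used = p, seed = seed), class = "dg_truth")
  list(raster = raster, truth = truth)
}

#' Forward model: onset raster to dF/F traces
#'
#' Each onset adds a calcium kernel with instantaneous rise and exponential
#' decay exp(-t/tau); kernels superpose linearly; Gaussian noise is added.
#'
#' @param raster binary onset matrix (cells x frames).
#' @param frame_rate Hz.
#' @param tau decay constant (s).
#' @param amplitude kernel peak (dF/F units).
#' @param noise_sd additive noise sd.
#' @param seed integer seed.
#' @return dF/F matrix of the raster's dimensions.
#' @export
events_to_dff <- function(raster, frame_rate, tau = 1.5, amplitude = 1,
                          noise_sd = 0.05, seed = 1L) {
  stopifnot(tau > 0)
  set.seed(seed)
  g <- exp(-1 / (frame_rate * tau))
  dff <- t(apply(raster * amplitude, 1L, function(x)
    as.numeric(stats::filter(x, g, method = "recursive"))))
  if (noise_sd > 0)
    dff <- dff + matrix(stats::rnorm(length(dff), 0, noise_sd),
                        nrow(dff), ncol(dff))
  dff
}

#' Generate bulk MPP and pupil channels
#'
#' The bulk MPP trace is a positive baseline with slow drift, frequent small
#' transients during locomotion, sparse small transients during immobility,
#' and a large transient leading each network event by `mpp_lead_frames`.
#' The pupil dilates during locomotion (first-order dynamics), shows a
#' transient constriction centered on each network event, and contains
#' occasional blink-masked frames.
#'
#' @param p a `dg_params`.
#' @param behavior output of [generate_behavior()].
#' @param ne_frames planted network-event frames.
#' @param seed integer seed.
#' @return list with `mpp`, `pupil`, `blink`, and `mpp_event_frames` (onset
#'   frames of the planted large transients).
#' @export
generate_mpp_pupil <- function(p, behavior, ne_frames, seed = 1L) {
  set.seed(seed)
  nf <- length(behavior$speed)
  fr <- p$frame_rate
  is_run <- behavior$speed >= 4
  g <- exp(-1 / (fr * p$tau))
  kernelize <- function(impulses) {
    as.numeric(stats::filter(impulses, g, method = "recursive"))
  }
  # small transients: frequent in run, sparse in rest
  rate <- ifelse(is_run, p$mpp_run_rate, p$mpp_rest_rate) / fr
  imp <- numeric(nf)
  small <- which(stats::runif(nf) < rate)
  imp[small] <- stats::rgamma(length(small), shape = 2, scale = 0.4)
  # large transients leading each network event
  mpp_ev <- pmax(1L, ne_frames - p$mpp_lead_frames)
  imp[mpp_ev] <- imp[mpp_ev] + 5 + stats::rexp(length(mpp_ev), 1)
  drift <- 2 * sin(2 * pi * seq_len(nf) / nf)
  mpp <- 100 + drift + 3 * kernelize(imp) + stats::rnorm(nf, 0, 0.2)

  # pupil: first-order relaxation toward a state-dependent target
  target <- ifelse(is_run, 1.25, 1.0)
  pupil <- numeric(nf)
  pupil[1L] <- target[1L]
  a <- exp(-1 / (fr * 2))                     # 2 s time constant
  for (t in 2:nf) pupil[t] <- a * pupil[t - 1L] + (1 - a) * target[t]
  if (length(ne_frames)) {
    w <- round(0.4 * fr)
    kern <- exp(-0.5 * ((-w:w) / (0.2 * fr))^2)
    for (f in ne_frames) {
      idx <- (f - w):(f + w)
      ok <- idx >= 1L & idx <= nf
      pupil[idx[ok]] <- pupil[idx[ok]] - p$pupil_dip * kern[ok]
    }
  }
  pupil <- pupil + stats::rnorm(nf, 0, 0.01)
  blink <- as.numeric(stats::runif(nf) < p$blink_prob)
  pupil[blink == 1] <- 0                       # dropout at blink frames
  list(mpp = mpp, pupil = pupil, blink = blink, mpp_event_frames = mpp_ev)
}

#' Generate a complete synthetic session
#'
#' Composes behavior, raster, dF/F, bulk MPP, and pupil generation into a
#' validated session with full ground truth. Deterministic given
#' `(p, seed)`.
#'
#' @param p a `dg_params` (default [generator_params()]).
#' @param seed integer master seed; per-stage seeds are derived from it.
#' @return list with `session` (a `dg_session`) and `truth` (a `dg_truth`).
#' @export
generate_session <- function(p = generator_params(), seed = 1L) {
  behavior <- generate_behavior(p, derive_seed(seed, 1L))
  pr <- plant_raster(p, behavior, derive_seed(seed, 2L))
  dff <- events_to_dff(pr$raster, p$frame_rate, p$tau, p$amplitude,
                       p$noise_sd, derive_seed(seed, 3L))
  tr <- pr$truth
  # sub-ensemble run drive: shared field-modulated dF/F added to every pool
  # member during locomotion, aligning run covariance with NE covariance
  if (p$replay_strength > 0 && length(tr$cluster_members)) {
    run_mask <- behavior$speed >= 4
    theta <- 2 * pi * behavior$position / p$belt_length
    for (cc in seq_along(tr$cluster_members)) {
      mu <- 2 * pi * tr$cluster_centers_cm[cc] / p$belt_length
      bump <- p$replay_strength * p$replay_dff_amp *
        exp(p$replay_kappa * (cos(theta - mu) - 1)) * run_mask
      for (i in tr$cluster_members[[cc]])
        dff[i, ] <- dff[i, ] + bump
    }
  }
  # speed cells: linear dF/F coupling to running speed (slope per cm/s)
  if (nrow(tr$speed_cells)) {
    for (j in seq_len(nrow(tr$speed_cells))) {
      i <- tr$speed_cells$cell[j]
      dff[i, ] <- dff[i, ] + tr$speed_cells$slope[j] * behavior$speed
    }
  }
  mp <- generate_mpp_pupil(p, behavior, tr$ne_frames, derive_seed(seed, 4L))
  tr$mpp_event_frames <- mp$mpp_event_frames
  s <- new_session(pr$raster, dff, behavior$speed, behavior$position,
                   frame_rate = p$frame_rate, belt_length = p$belt_length,
                   mpp = mp$mpp, pupil = mp$pupil, blink = mp$blink,
                   session_id = sprintf("synthetic-%d", seed))
  list(session = s, truth = tr, epochs = behavior$epochs)
}
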