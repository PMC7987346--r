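# Place-cell identification by spatial tuning vector with shuffle
# significance, and speed-cell identification by binned linear correlation
# with circular-shift significance; incorporation of tuned cells into
# network events.

#' Spatial tuning vector of a cell
#'
#' The belt is mapped to the unit circle (theta = 2*pi*pos/belt_length). Each
#' run-epoch event onset contributes a unit vector at the animal's position,
#' weighted by the reciprocal of the occupancy time of its spatial bin;
#' weights are normalized to sum 1, so a perfectly concentrated cell yields
#' length 1 under any occupancy. The analysis is restricted to running
#' epochs.
#'
#' @param onsets integer frames of the cell's event onsets.
#' @param position per-frame belt position (cm).
#' @param epochs run/rest epochs; only run frames are used.
#' @param belt_length belt length (cm).
#' @param n_bins occupancy bins along the belt (default 50, i.e. 3 cm bins on
#'   a 150 cm belt).
#' @return list with `length` (resultant vector length in `[0, 1]`), `angle`
#'   (radians in `[0, 2*pi)`), `preferred_cm`, and `n_onsets` (run-epoch
#'   onsets used). Length and angle are NA when there is no run onset.
#' @export
spatial_tuning_vector <- function(onsets, position, epochs, belt_length,
                                  n_bins = 50L) {
  run_f <- frames_in_epochs(epochs, "run")
  onsets <- intersect(as.integer(onsets), run_f)
  n <- length(onsets)
  if (n == 0L)
    return(list(length = NA_real_, angle = NA_real_,
                preferred_cm = NA_real_, n_onsets = 0L))
  breaks <- seq(0, belt_length, length.out = n_bins + 1L)
  binned <- function(p) pmin(findInterval(p, breaks, rightmost.closed = TRUE),
                             n_bins)
  occ <- tabulate(binned(position[run_f]), nbins = n_bins)  # frames per bin
  b <- binned(position[onsets])
  w <- 1 / occ[b]                 # onset implies presence: occ[b] >= 1
  w <- w / sum(w)
  theta <- 2 * pi * position[onsets] / belt_length
  vx <- sum(w * cos(theta)); vy <- sum(w * sin(theta))
  ang <- atan2(vy, vx) %% (2 * pi)
  list(length = sqrt(vx^2 + vy^2), angle = ang,
       preferred_cm = ang / (2 * pi) * belt_length, n_onsets = n)
}

#' Place-cell significance test
#'
#' Cells with fewer than `min_onsets` run-epoch onsets are excluded. The
#' observed tuning-vector length is compared with a null built by redrawing
#' the same number of onset frames uniformly over run-epoch frames and
#' recomputing the vector; p is the fraction of null lengths larger than the
#' observed one.
#'
#' @inheritParams spatial_tuning_vector
#' @param n_shuffles number of onset-time shuffles (default 1000).
#' @param alpha significance level (default 0.05).
#' @param min_onsets minimum run-epoch onsets to test (default 4).
#' @param seed integer seed.
#' @return list with the tuning-vector fields plus `p`, `is_place`, and
#'   `tested` (FALSE with reason `"too_few_onsets"` when excluded).
#' @export
place_cell_test <- function(onsets, position, epochs, belt_length,
                            n_bins = 50L, n_shuffles = 1000L, alpha = 0.05,
                            min_onsets = 4L, seed = 1L) {
  obs <- spatial_tuning_vector(onsets, position, epochs, belt_length, n_bins)
  if (obs$n_onsets < min_onsets)
    return(c(obs, list(p = NA_real_, is_place = FALSE, tested = FALSE,
                       reason = "too_few_onsets")))
  run_f <- frames_in_epochs(epochs, "run")
  set.seed(seed)
  null_len <- vapply(seq_len(n_shuffles), function(b) {
    sh <- run_f[sample.int(length(run_f), obs$n_onsets)]
    spatial_tuning_vector(sh, position, epochs, belt_length, n_bins)$length
  }, numeric(1L))
  p <- mean(null_len > obs$length)
  c(obs, list(p = p, is_place = p < alpha, tested = TRUE, reason = NA_character_))
}

#' Binned speed tuning of a cell
#'
#' Speed values are divided into `n_bins` equal-width bins between 0 and the
#' maximum speed; the mean dF/F over all frames in each bin is correlated
#' (Pearson) with the bin centers. Empty bins are excluded from the
#' correlation.
#'
#' @param dff_cell the cell's dF/F trace.
#' @param speed per-frame running speed (cm/s).
#' @param n_bins number of speed bins (default 20).
#' @param running_only when TRUE, restrict the binning to frames above
#'   `run_threshold`; the default (FALSE) bins all frames, so the lowest bin
#'   contains immobility frames.
#' @param run_threshold cm/s, used only when `running_only` is TRUE.
#' @return list with `bin_centers`, `bin_means`, `n_per_bin`, and `r`
#'   (NA when fewer than 3 non-empty bins or zero variance).
#' @export
speed_tuning <- function(dff_cell, speed, n_bins = 20L, running_only = FALSE,
                         run_threshold = 4) {
  keep <- if (running_only) speed >= run_threshold else rep(TRUE, length(speed))
  sp <- speed[keep]; y <- dff_cell[keep]
  vmax <- max(sp)
  if (vmax <= 0) stop("speed range is zero")
  breaks <- seq(0, vmax, length.out = n_bins + 1L)
  b <- pmin(findInterval(sp, breaks, rightmost.closed = TRUE), n_bins)
  means <- tapply(y, factor(b, levels = seq_len(n_bins)), mean)
  nper <- tabulate(b, nbins = n_bins)
  centers <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  ok <- nper > 0
  r <- if (sum(ok) < 3L || stats::sd(means[ok]) == 0) NA_real_
       else stats::cor(centers[ok], as.numeric(means[ok]))
  list(bin_centers = centers, bin_means = as.numeric(means),
       n_per_bin = nper, r = r)
}

#' Speed-cell significance test
#'
#' A cell is a candidate speed coder when its binned speed correlation is at
#' least `r_min` (default 0.9). Significance requires that circularly
#' time-shifting the dF/F trace against the (fixed) behavior yields a lower r
#' in at least `pass_frac` (default 95%) of shuffles.
#'
#' @inheritParams speed_tuning
#' @param n_shuffles number of circular shifts (default 1000).
#' @param r_min candidacy threshold on Pearson r (default 0.9).
#' @param pass_frac required fraction of shuffles below the observed r
#'   (default 0.95).
#' @param min_shift_s minimum shift magnitude in seconds (default 5).
#' @param frame_rate Hz, used for the minimum shift.
#' @param seed integer seed.
#' @return list with `r`, `shuffle_pass_frac`, `is_speed`, and the tuning
#'   curve fields.
#' @export
speed_cell_test <- function(dff_cell, speed, n_bins = 20L, n_shuffles = 1000L,
                            r_min = 0.9, pass_frac = 0.95, min_shift_s = 5,
                            frame_rate = 15, running_only = FALSE,
                            run_threshold = 4, seed = 1L) {
  nf <- length(dff_cell)
  min_shift <- ceiling(min_shift_s * frame_rate)
  if (nf <= 2L * min_shift) stop("trace shorter than twice the minimum shift")
  obs <- speed_tuning(dff_cell, speed, n_bins, running_only, run_threshold)
  if (is.na(obs$r) || obs$r < r_min)
    return(c(obs, list(shuffle_pass_frac = NA_real_, is_speed = FALSE)))
  set.seed(seed)
  shifts <- sample(min_shift:(nf - min_shift), n_shuffles, replace = TRUE)
  null_r <- vapply(shifts, function(sh) {
    shifted <- dff_cell[c((nf - sh + 1L):nf, 1L:(nf - sh))]
    speed_tuning(shifted, speed, n_bins, running_only, run_threshold)$r
  }, numeric(1L))
  pass <- mean(null_r < obs$r, na.rm = TRUE)
  c(obs, list(shuffle_pass_frac = pass, is_speed = pass >= pass_frac))
}

#' Incorporation of tuned cells into network events
#'
#' Fractions of place and speed cells that participate in at least one
#' network event, and the fraction of network events containing at least one
#' place (or speed) cell.
#'
#' @param place_ids integer ids of place cells.
#' @param speed_ids integer ids of speed cells.
#' @param P participation matrix (cells x events).
#' @return list with `frac_place_in_ne`, `frac_speed_in_ne` (NA when the
#'   respective tuned set is empty), `frac_ne_with_place`,
#'   `frac_ne_with_speed`.
#' @export
tuning_ne_incorporation <- function(place_ids, speed_ids, P) {
  part <- rowSums(P) > 0
  frac_cells <- function(ids) {
    if (length(ids) == 0L) return(NA_real_)
    mean(part[ids])
  }
  frac_ne <- function(ids) {
    if (ncol(P) == 0L) return(NA_real_)
    if (length(ids) == 0L) return(0)
    mean(colSums(P[ids, , drop = FALSE]) > 0)
  }
  list(frac_place_in_ne = frac_cells(place_ids),
       frac_speed_in_ne = frac_cells(speed_ids),
       frac_ne_with_place = frac_ne(place_ids),
       frac_ne_with_speed = frac_ne(speed_ids))
}
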