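# Orchestration: run every analysis stage over one session from a single
# configuration with deterministic seeding, and contrast two condition
# reports.

#' Pipeline configuration
#'
#' Collects all stage parameters with their defaults. Shuffle counts default
#' to 1000 as in the individual stages; `n_shuffles` lowers them jointly for
#' faster exploratory runs.
#'
#' @param seed master seed; per-stage seeds are derived deterministically, so
#'   stages can be re-run in isolation.
#' @param n_shuffles shuffle count used by every permutation test.
#' @param alpha_ne chance-fraction criterion for the NE size threshold.
#' @param alpha_place place-cell significance level.
#' @param window_frames NE window (frames).
#' @param ne_window_s window around events for the subspace comparison (s).
#' @param run_threshold,min_run_s locomotion segmentation parameters.
#' @param stages character vector of stages to run; any of
#'   `"network_events"`, `"ensembles"`, `"tuning"`, `"mpp"`, `"pupil"`,
#'   `"geometry"`.
#' @param tau bulk deconvolution decay constant (s).
#' @param max_lag_s cross-correlogram lag range (s).
#' @return list of class `dg_config`.
#' @export
pipeline_config <- function(seed = 1L, n_shuffles = 1000L, alpha_ne = 0.001,
                            alpha_place = 0.05, window_frames = 3L,
                            ne_window_s = 2, run_threshold = 4,
                            min_run_s = 2.5,
                            stages = c("network_events", "ensembles",
                                       "tuning", "mpp", "pupil", "geometry"),
                            tau = 1.5, max_lag_s = 2) {
  stopifnot(alpha_ne > 0, alpha_ne < 1, alpha_place > 0, alpha_place < 1)
  structure(as.list(environment()), class = "dg_config")
}

#' Run the full analysis pipeline on one session
#'
#' Segments behavior, detects network events against the shuffle null, and
#' runs the enabled downstream stages. Stage failures are caught and
#' reported in `$errors`; stages depending on a failed stage are skipped.
#'
#' @param session a `dg_session`.
#' @param config a `dg_config` from [pipeline_config()].
#' @return an object of class `dg_report`: a list of per-stage results plus
#'   a `summary` data.frame of headline numbers and a `log` of parameters.
#' @export
run_pipeline <- function(session, config = pipeline_config()) {
  stopifnot(inherits(session, "dg_session"))
  v <- validate_session(session)
  if (length(v)) stop("invalid session: ", v[1L])
  cfg <- config
  rep_ <- list(config = cfg, session_id = session$session_id,
               errors = character(0))
  fail <- function(stage, e) {
    rep_$errors <<- c(rep_$errors, sprintf("%s: %s", stage,
                                           conditionMessage(e)))
    NULL
  }
  fr <- session$frame_rate
  epochs <- segment_locomotion(session$speed, fr, cfg$run_threshold,
                               cfg$min_run_s)
  rep_$epochs <- epochs

  ne <- NULL
  if ("network_events" %in% cfg$stages) {
    ne <- tryCatch({
      thr <- size_threshold(session$raster, epochs,
                            n_shuffles = cfg$n_shuffles,
                            alpha = cfg$alpha_ne,
                            window_frames = cfg$window_frames,
                            seed = derive_seed(cfg$seed, 11L))
      set_ <- detect_network_events(session$raster, thr$threshold,
                                    cfg$window_frames)
      stats_ <- ne_state_stats(set_, epochs, fr,
                               seed = derive_seed(cfg$seed, 12L))
      list(threshold = thr, set = set_, state_stats = stats_)
    }, error = function(e) fail("network_events", e))
    rep_$network_events <- ne
  }

  if ("ensembles" %in% cfg$stages && !is.null(ne)) {
    rep_$ensembles <- tryCatch({
      P <- participation_matrix(ne$set)
      orth <- orthogonal_fraction_test(P, cfg$n_shuffles,
                                       seed = derive_seed(cfg$seed, 21L))
      thr <- cluster_threshold_null(P, cfg$n_shuffles,
                                    seed = derive_seed(cfg$seed, 22L))
      cl <- hierarchical_clusters(P, thr$r_threshold)
      list(P = P, orthogonality = orth, r_threshold = thr$r_threshold,
           clusters = cl)
    }, error = function(e) fail("ensembles", e))
  }

  if ("tuning" %in% cfg$stages) {
    rep_$tuning <- tryCatch({
      onsets <- apply(session$raster, 1L, function(x) which(x > 0),
                      simplify = FALSE)
      place <- lapply(seq_len(n_cells(session)), function(i)
        place_cell_test(onsets[[i]], session$position, epochs,
                        session$belt_length, n_shuffles = cfg$n_shuffles,
                        alpha = cfg$alpha_place,
                        seed = derive_seed(cfg$seed, 31L + i)))
      speed <- lapply(seq_len(n_cells(session)), function(i)
        speed_cell_test(session$dff[i, ], session$speed,
                        n_shuffles = cfg$n_shuffles, frame_rate = fr,
                        seed = derive_seed(cfg$seed, 5031L + i)))
      place_ids <- which(vapply(place, `[[`, logical(1L), "is_place"))
      speed_ids <- which(vapply(speed, `[[`, logical(1L), "is_speed"))
      running_active <- which(vapply(onsets, function(o)
        length(intersect(o, frames_in_epochs(epochs, "run"))) > 0,
        logical(1L)))
      inc <- if (!is.null(rep_$ensembles))
        tuning_ne_incorporation(place_ids, speed_ids, rep_$ensembles$P)
      else NULL
      overlap <- if (!is.null(rep_$ensembles))
        cluster_tuning_overlap(rep_$ensembles$clusters, place_ids, speed_ids)
      else NULL
      list(place = place, speed = speed, place_ids = place_ids,
           speed_ids = speed_ids, running_active = running_active,
           frac_place_all = length(place_ids) / n_cells(session),
           frac_place_running = if (length(running_active))
             length(intersect(place_ids, running_active)) /
               length(running_active) else NA_real_,
           incorporation = inc, cluster_overlap = overlap)
    }, error = function(e) fail("tuning", e))
  }

  if ("mpp" %in% cfg$stages) {
    rep_$mpp <- tryCatch({
      if (is.null(session$mpp)) stop("mpp channel is absent")
      dff <- bulk_dff(session$mpp, fr)
      ev <- deconvolve_bulk(dff, fr, tau = cfg$tau)
      st <- bulk_event_state_stats(ev, epochs, fr)
      gc_sum <- colSums(session$raster)
      cc <- mpp_gc_crosscorr(dff, gc_sum, epochs, cfg$max_lag_s, fr)
      gr <- tryCatch(granger_test(dff[frames_in_epochs(epochs, "rest")],
                                  gc_sum[frames_in_epochs(epochs, "rest")]),
                     error = function(e) NULL)
      delay <- if (!is.null(ne) && length(ne$set$ne_frames))
        ne_mpp_delay(ne$set$ne_frames, ev, fr) else numeric(0)
      list(dff = dff, events = ev, state_stats = st, crosscorr = cc,
           granger = gr, ne_delay_s = delay)
    }, error = function(e) fail("mpp", e))
  }

  if ("pupil" %in% cfg$stages) {
    rep_$pupil <- tryCatch({
      if (is.null(session$pupil)) stop("pupil channel is absent")
      pp <- preprocess_pupil(session$pupil, session$blink, native_rate = fr,
                             target_rate = fr)
      ne_f <- if (!is.null(ne)) ne$set$ne_frames else integer(0)
      st <- pupil_state_stats(pp, epochs, ne_f, fr,
                              gc_activity = colSums(session$raster))
      eta <- if (length(ne_f))
        tryCatch(event_triggered_average(pp, ne_f, round(2 * fr)),
                 error = function(e) NULL)
      else NULL
      list(trace = pp, state_stats = st, ne_triggered = eta)
    }, error = function(e) fail("pupil", e))
  }

  if ("geometry" %in% cfg$stages && !is.null(ne) &&
      length(ne$set$ne_frames) >= 3L) {
    rep_$geometry <- tryCatch({
      X <- zscore_rows(session$dff)
      res <- lapply(c("time_shift", "within_ne_identity",
                      "per_cell_ne_reassign"), function(m)
        geometry_shuffle_test(X, epochs, ne$set$ne_frames, fr, method = m,
                              n_shuffles = cfg$n_shuffles,
                              ne_window_s = cfg$ne_window_s,
                              seed = derive_seed(cfg$seed, 41L)))
      names(res) <- c("time_shift", "within_ne_identity",
                      "per_cell_ne_reassign")
      lap <- laps_from_position(session$position, session$belt_length)
      run_f <- frames_in_epochs(epochs, "run")
      run_pca <- pca_basis(X[, run_f, drop = FALSE])
      auto <- tryCatch(
        weight_lap_autocorr(run_pca$W, session$position[run_f],
                            lap$lap[run_f], session$belt_length),
        error = function(e) NULL)
      list(similarity = res, lap_autocorr = auto)
    }, error = function(e) fail("geometry", e))
  }

  rep_$summary <- pipeline_summary(rep_)
  class(rep_) <- "dg_report"
  rep_
}

#' @keywords internal
#' @noRd
pipeline_summary <- function(rep_) {
  num <- function(x) if (is.null(x) || length(x) == 0L) NA_real_ else as.numeric(x[1L])
  ne <- rep_$network_events; en <- rep_$ensembles; tu <- rep_$tuning
  ge <- rep_$geometry
  sim <- function(meas, meth) {
    if (is.null(ge)) return(NA_real_)
    num(ge$similarity[[meth]][[meas]])
  }
  simp <- function(meas, meth) {
    if (is.null(ge)) return(NA_real_)
    num(ge$similarity[[meth]]$p[meas])
  }
  data.frame(
    metric = c("ne_count", "ne_threshold", "ne_freq_rest_per_min",
               "ne_freq_run_per_min", "ne_frac_rest",
               "orthogonal_fraction", "orthogonal_p",
               "n_clusters", "mean_cluster_size",
               "frac_place_all", "frac_place_running",
               "n_speed_cells",
               "proj_var_ratio", "p_time_shift", "p_within_ne_identity",
               "p_per_cell_ne_reassign", "lap_autocorr_peak"),
    value = c(num(length(ne$set$ne_frames)), num(ne$threshold$threshold),
              num(ne$state_stats$freq_per_min["rest"]),
              num(ne$state_stats$freq_per_min["run"]),
              num(ne$state_stats$frac_rest),
              num(en$orthogonality$observed), num(en$orthogonality$p),
              num(length(en$clusters$clusters)),
              if (is.null(en) || length(en$clusters$clusters) == 0L)
                NA_real_ else mean(lengths(en$clusters$clusters)),
              num(tu$frac_place_all), num(tu$frac_place_running),
              num(length(tu$speed_ids)),
              sim("projected_variance_ratio", "time_shift"),
              simp("projected_variance_ratio", "time_shift"),
              simp("projected_variance_ratio", "within_ne_identity"),
              simp("projected_variance_ratio", "per_cell_ne_reassign"),
              if (is.null(ge) || is.null(ge$lap_autocorr)) NA_real_
              else ge$lap_autocorr$peak))
}

#' @export
print.dg_report <- function(x, ...) {
  cat(sprintf("<dg_report> session '%s'\n", x$session_id))
  print(x$summary, row.names = FALSE)
  if (length(x$errors)) cat("stage errors:", paste(x$errors, collapse = "; "),
                            "\n")
  invisible(x)
}

#' Contrast two condition reports
#'
#' Two-sample rank tests on network-event size and per-cell participation
#' distributions, and a proportion test on place-cell incorporation into
#' network events, between two pipeline reports (e.g. a baseline and a
#' cue-enriched session).
#'
#' @param report_a,report_b `dg_report` objects.
#' @return data.frame with one row per contrast: `contrast`, `stat`, `p`,
#'   `a`, `b` (condition summaries).
#' @export
compare_conditions <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "dg_report"), inherits(report_b, "dg_report"))
  if (!identical(report_a$config$n_shuffles, report_b$config$n_shuffles))
    warning("reports used different shuffle counts; contrasts computed anyway")
  out <- NULL
  sizes <- function(r) lengths(r$network_events$set$ne_members)
  part <- function(r) rowSums(r$ensembles$P)
  sa <- sizes(report_a); sb <- sizes(report_b)
  if (length(sa) && length(sb)) {
    wt <- stats::wilcox.test(sa, sb, exact = FALSE)
    out <- rbind(out, data.frame(contrast = "ne_size", stat = unname(wt$statistic),
                                 p = wt$p.value, a = mean(sa), b = mean(sb)))
  }
  pa <- tryCatch(part(report_a), error = function(e) NULL)
  pb <- tryCatch(part(report_b), error = function(e) NULL)
  if (!is.null(pa) && !is.null(pb)) {
    wt <- stats::wilcox.test(pa, pb, exact = FALSE)
    out <- rbind(out, data.frame(contrast = "cell_participation",
                                 stat = unname(wt$statistic), p = wt$p.value,
                                 a = mean(pa), b = mean(pb)))
  }
  inc <- function(r) {
    tu <- r$tuning
    if (is.null(tu) || is.null(tu$incorporation)) return(NULL)
    k <- length(tu$place_ids)
    if (k == 0L) return(NULL)
    c(in_ne = round(tu$incorporation$frac_place_in_ne * k), n = k)
  }
  ia <- inc(report_a); ib <- inc(report_b)
  if (!is.null(ia) && !is.null(ib)) {
    pt <- suppressWarnings(stats::prop.test(c(ia["in_ne"], ib["in_ne"]),
                                            c(ia["n"], ib["n"])))
    out <- rbind(out, data.frame(contrast = "place_cell_incorporation",
                                 stat = unname(pt$statistic), p = pt$p.value,
                                 a = ia["in_ne"] / ia["n"],
                                 b = ib["in_ne"] / ib["n"]))
  }
  rownames(out) <- NULL
  out
}
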