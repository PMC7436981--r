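# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# `seed` is forced first: if the caller computes it from its own RNG stream,
# that draw must happen before the state snapshot or it would be rolled back.
local_seed <- function(seed, code) {
  seed <- as.integer(seed)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Behavioural profile for the CoP simulator
#'
#' Bundles the parameters that shape a simulated participant. The two
#' presets qualitatively emulate the behaviours reported for the two
#' fear-of-falling groups: `"low_fof_like"` subjects reach quickly and
#' accurately and therefore dwell mostly in the inner functional area, while
#' `"high_fof_like"` subjects are slower, noisier, fail more targets (and
#' then hover mid-range, in the 33-67% band) and have reduced peripheral
#' mobility. The presets are documented constants chosen to be plausible for
#' quiet-standing posturography, not fits to any patient cohort.
#'
#' @param label `"low_fof_like"` or `"high_fof_like"`.
#' @param ... Named overrides of any profile field: `reach_speed` (mm/s),
#'   `reach_accuracy` (sd of endpoint error, mm), `tremor_amplitude` (sd,
#'   mm), `tremor_band` (Hz, length 2), `dwell_fractions` (p1, p2, p3,
#'   p_out; sums to 1; used by the dwell-mode generator),
#'   `hit_probability`, `max_excursion_means` (named mm per cardinal
#'   direction), `calib_noise_cv` (attempt-to-attempt CV).
#' @return A list of class `sim_profile`.
#' @export
sim_profile <- function(label = c("low_fof_like", "high_fof_like"), ...) {
  label <- match.arg(label)
  base <- if (label == "low_fof_like") {
    list(reach_speed = 80, reach_accuracy = 2, tremor_amplitude = 0.6,
         tremor_band = c(4, 7),
         dwell_fractions = c(0.65, 0.20, 0.12, 0.03),
         hit_probability = 0.97,
         max_excursion_means = c(forward = 40, backward = 35, left = 30, right = 30),
         calib_noise_cv = 0.05)
  } else {
    list(reach_speed = 30, reach_accuracy = 6, tremor_amplitude = 1.2,
         tremor_band = c(4, 7),
         dwell_fractions = c(0.40, 0.45, 0.12, 0.03),
         hit_probability = 0.60,
         max_excursion_means = c(forward = 32, backward = 28, left = 24, right = 24),
         calib_noise_cv = 0.05)
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown) > 0L)
    abort(paste0("unknown profile field(s): ", paste(unknown, collapse = ", ")),
          class = "ftrcop_parameter_error")
  base[names(over)] <- over
  p <- c(list(label = label), base)
  if (abs(sum(p$dwell_fractions) - 1) > 1e-12 || any(p$dwell_fractions < 0))
    abort("dwell_fractions must be nonnegative and sum to 1",
          class = "ftrcop_parameter_error")
  if (p$reach_speed <= 0 || p$tremor_amplitude < 0 || p$reach_accuracy < 0)
    abort("speeds and amplitudes must be positive", class = "ftrcop_parameter_error")
  structure(p, class = "sim_profile")
}

#' Simulate calibration attempts
#'
#' Draws the per-direction maximal-excursion attempts (3 per direction)
#' around the profile's mean excursions with multiplicative Gaussian noise.
#'
#' @param profile A [sim_profile()].
#' @param seed Integer seed.
#' @param n_attempts Attempts per direction (default 3).
#' @return A named list (`forward`, `backward`, `left`, `right`) of attempt
#'   vectors in mm, ready for [compute_calibration()].
#' @export
simulate_calibration <- function(profile, seed, n_attempts = 3L) {
  mu <- profile$max_excursion_means
  cv <- profile$calib_noise_cv
  local_seed(seed, {
    purrr::map(as.list(mu[.cardinals]), function(m)
      pmax(0.2 * m, m * (1 + rnorm(n_attempts, 0, cv))))
  })
}

# Band-limited tremor: white noise band-passed to `band` Hz, scaled to sd `amp`.
.make_tremor <- function(n, fs, band, amp) {
  if (amp <= 0) return(matrix(0, n, 2L))
  bw <- signal::butter(2, band / (fs / 2), type = "pass")
  out <- vapply(1:2, function(i) {
    z <- .filtfilt_reflect(bw$b, bw$a, rnorm(n), padlen = 9L)
    z / max(sd(z), 1e-12) * amp
  }, numeric(n))
  out
}

# Critically damped second-order point-mass reach from `from` toward `to`:
# x(t) = to + (from - to)(1 + wt)exp(-wt), with w set so the peak speed
# matches `speed`.
.reach_path <- function(from, to, speed, n, fs) {
  d <- sqrt(sum((to - from)^2))
  tt <- seq_len(n) / fs
  if (d < 1e-9) return(matrix(rep(to, each = n), n, 2L))
  w <- exp(1) * speed / d
  g <- (1 + w * tt) * exp(-w * tt)
  cbind(to[1] + (from[1] - to[1]) * g, to[2] + (from[2] - to[2]) * g)
}

# Clip 2-D rows radially about `center` to radius `r`.
.clip_radial <- function(xy, center, r) {
  dx <- xy[, 1L] - center[1L]; dy <- xy[, 2L] - center[2L]
  dd <- sqrt(dx^2 + dy^2)
  f <- ifelse(dd > r, r / dd, 1)
  cbind(center[1L] + dx * f, center[2L] + dy * f)
}

#' Simulate one limit-of-stability trial
#'
#' Generates 5 s of quiet stance followed by the 8 target phases: a
#' goal-directed reach modelled as critically damped second-order point-mass
#' motion toward an aim point (the target, with small endpoint error, when
#' the per-target Bernoulli succeeds; a mid-range shortfall point
#' otherwise), plus band-limited tremor. Hits are determined geometrically
#' from the generated trajectory with the same rule the scorer uses; after a
#' hit or the 10-s timeout the subject returns home and holds. The event log
#' records the ground-truth timeline.
#'
#' @param profile A [sim_profile()].
#' @param layout A [place_targets()] layout.
#' @param seed Integer seed (the trial is a pure function of arguments + seed).
#' @param fs Sampling rate in Hz (default 100).
#' @param timeout,hold,quiet_stance_s Protocol constants (10 s, 5 s, 5 s).
#' @param order Optional explicit target order; default random under `seed`.
#' @return A list of class `sim_trial`: `traj` (raw [cop_trajectory]
#'   including quiet stance), `event_log` (tibble), `order`, `true_score`,
#'   `true_region_dwell` (named fractions over task samples).
#' @export
simulate_los_trial <- function(profile, layout, seed, fs = 100,
                               timeout = 10, hold = 5, quiet_stance_s = 5,
                               order = NULL) {
  home <- attr(layout, "home")
  radius <- attr(layout, "target_radius")
  local_seed(seed, {
    if (is.null(order)) order <- sample(.directions8)
    n_max <- ceiling((quiet_stance_s + 8 * (timeout + timeout + hold + 3)) * fs)
    tremor <- .make_tremor(n_max, fs, profile$tremor_band, profile$tremor_amplitude)
    cursor <- 0L
    take_tremor <- function(n) {
      sl <- tremor[(cursor + 1L):(cursor + n), , drop = FALSE]
      cursor <<- cursor + n
      sl
    }

    chunks <- list()
    events <- list()
    push <- function(xy) chunks[[length(chunks) + 1L]] <<- xy

    # quiet stance: small sway about home
    n0 <- round(quiet_stance_s * fs)
    quiet <- cbind(home[1L], home[2L]) [rep(1L, n0), , drop = FALSE] +
      0.5 * take_tremor(n0)
    push(quiet)
    pos <- quiet[n0, ]
    t_task0 <- n0 / fs
    sample_count <- n0
    hits <- 0L

    n_hold_gen <- round((hold + 1.0) * fs)   # 1 s of slack beyond the required hold
    for (k in seq_len(8L)) {
      tgt <- unlist(layout[layout$direction == order[k], c("x", "y")])
      d_ht <- sqrt(sum((tgt - home)^2))
      onset_s <- sample_count / fs
      intend <- runif(1) < profile$hit_probability
      aim <- if (intend) {
        dev <- rnorm(2) * profile$reach_accuracy
        dn <- sqrt(sum(dev^2))
        if (dn > 0.4 * radius) dev <- dev * 0.4 * radius / dn
        tgt + dev
      } else {
        frac <- runif(1, 0.45, 0.52)
        dev <- rnorm(2) * profile$reach_accuracy
        dn <- sqrt(sum(dev^2))
        if (dn > 0.05 * d_ht) dev <- dev * 0.05 * d_ht / dn
        home + frac * (tgt - home) + dev
      }
      n_t <- round(timeout * fs) + 1L
      path <- .reach_path(pos, aim, profile$reach_speed, n_t, fs) + take_tremor(n_t)
      d_tgt <- sqrt((path[, 1L] - tgt[1L])^2 + (path[, 2L] - tgt[2L])^2)
      hit_at <- which(d_tgt <= radius)[1L]
      if (!is.na(hit_at)) {
        # keep sinking toward the aim point for a short dwell after the first
        # boundary touch, so the hit survives low-pass filtering downstream
        hit_end <- min(nrow(path), hit_at + round(0.4 * fs))
        path <- path[seq_len(hit_end), , drop = FALSE]
        hits <- hits + 1L
      }
      push(path)
      pos <- path[nrow(path), ]
      sample_count <- sample_count + nrow(path)
      events[[length(events) + 1L]] <- tibble::tibble(
        phase = k, type = "target", direction = order[k],
        onset_s = onset_s, hit = !is.na(hit_at),
        time_to_hit = if (!is.na(hit_at)) hit_at / fs else NA_real_)

      # home phase: reach back, then hold with tremor clipped inside the radius
      home_onset <- sample_count / fs
      dev <- rnorm(2) * min(profile$reach_accuracy, 0.3 * radius)
      dn <- sqrt(sum(dev^2))
      if (dn > 0.3 * radius) dev <- dev * 0.3 * radius / dn
      aim_home <- home + dev
      n_r <- round(timeout * fs)
      back <- .reach_path(pos, aim_home, profile$reach_speed, n_r, fs) + take_tremor(n_r)
      d_home <- sqrt((back[, 1L] - home[1L])^2 + (back[, 2L] - home[2L])^2)
      in_at <- which(d_home <= radius)[1L]
      if (is.na(in_at)) in_at <- n_r   # pathological profile; clamp below anyway
      back <- back[seq_len(in_at), , drop = FALSE]
      back[in_at, ] <- .clip_radial(back[in_at, , drop = FALSE], home, 0.7 * radius)
      push(back)
      # attenuated tremor and a conservative clip: the subject stabilises at
      # home, and the margin absorbs filter overshoot at clip transitions
      holdxy <- cbind(aim_home[1L], aim_home[2L])[rep(1L, n_hold_gen), , drop = FALSE] +
        0.6 * take_tremor(n_hold_gen)
      holdxy <- .clip_radial(holdxy, home, 0.7 * radius)
      push(holdxy)
      pos <- holdxy[n_hold_gen, ]
      sample_count <- sample_count + in_at + n_hold_gen
      events[[length(events) + 1L]] <- tibble::tibble(
        phase = k, type = "home", direction = NA_character_,
        onset_s = home_onset, hit = NA, time_to_hit = NA_real_)
    }

    xy <- do.call(rbind, chunks)
    n <- nrow(xy)
    traj <- cop_trajectory((0:(n - 1L)) / fs, xy[, 1L], xy[, 2L], fs = fs)

    # ground-truth dwell over the task samples, in RFAs centred on their median
    task <- traj[traj$t >= t_task0 - 1e-9, ]
    d <- attr(layout, "distances")
    calib <- new_calibration(names(d), unname(d) / 0.75)
    rfas <- build_rfas(calib, task)
    dwell <- table(classify_samples(task, rfas)) / nrow(task)

    structure(list(traj = traj,
                   event_log = dplyr::bind_rows(events),
                   order = order,
                   true_score = hits,
                   true_region_dwell = setNames(as.numeric(dwell), names(dwell))),
              class = "sim_trial")
  })
}

# Uniform draws strictly inside an rfa band. `inner`/`outer` are column names
# of the rfa_set ("b33"/"b67"/"b100") or NULL; `expand` widens the outer box
# (used for the outside region).
.sample_band <- function(n, rfas, inner, outer, expand = 1, margin_frac = 1e-6) {
  ctr <- attr(rfas, "center")
  bo <- if (is.null(outer)) rfa_level(rfas, "b100") * expand else rfa_level(rfas, outer)
  m <- margin_frac * max(bo)
  draw <- function(nn) {
    cbind(runif(nn, -bo[["left"]] + m, bo[["right"]] - m),
          runif(nn, -bo[["backward"]] + m, bo[["forward"]] - m))
  }
  keep <- matrix(numeric(0), 0L, 2L)
  while (nrow(keep) < n) {
    cand <- draw(max(2L * n, 16L))
    if (!is.null(inner)) {
      bi <- rfa_level(rfas, inner)
      inside <- cand[, 1L] <= bi[["right"]] + m & -cand[, 1L] <= bi[["left"]] + m &
        cand[, 2L] <= bi[["forward"]] + m & -cand[, 2L] <= bi[["backward"]] + m
      cand <- cand[!inside, , drop = FALSE]
    }
    keep <- rbind(keep, cand)
  }
  keep <- keep[seq_len(n), , drop = FALSE]
  cbind(ctr[["x"]] + keep[, 1L], ctr[["y"]] + keep[, 2L])
}

#' Simulate a dwell-mode trajectory with forced region occupancy
#'
#' The direct test harness for the time-ratio statistic: emits exactly
#' `round(p_i * n_samples)` samples uniformly inside region i of the given
#' RFA set (and beyond the outermost rectangle for `p_out`), shuffled in
#' time. When the resulting trajectory is evaluated against the same RFA set
#' (fixed-centre mode) the region percentages are forced up to rounding; if
#' the RFAs are instead re-centred on the trajectory median downstream, the
#' recovered values shift slightly with the median.
#'
#' @param fractions Numeric (p1, p2, p3, p_out), nonnegative, summing to 1.
#' @param rfas An [build_rfas()] RFA set (provides geometry and centre).
#' @param n_samples Total sample budget (>= 4).
#' @param seed Integer seed.
#' @param fs Sampling rate for the emitted timestamps (default 100).
#' @return A [cop_trajectory].
#' @export
simulate_dwell_trajectory <- function(fractions, rfas, n_samples, seed, fs = 100) {
  if (length(fractions) != 4L || any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    abort("fractions must be 4 nonnegative numbers summing to 1",
          class = "ftrcop_parameter_error")
  if (n_samples < 4L)
    abort("n_samples must be at least 4", class = "ftrcop_data_error")
  counts <- round(fractions * n_samples)
  if (sum(counts) < 2L)
    abort("fractions and n_samples yield fewer than 2 samples",
          class = "ftrcop_data_error")
  local_seed(seed, {
    pts <- rbind(
      if (counts[1L] > 0L) .sample_band(counts[1L], rfas, NULL, "b33") else NULL,
      if (counts[2L] > 0L) .sample_band(counts[2L], rfas, "b33", "b67") else NULL,
      if (counts[3L] > 0L) .sample_band(counts[3L], rfas, "b67", "b100") else NULL,
      if (counts[4L] > 0L) .sample_band(counts[4L], rfas, "b100", NULL, expand = 1.5) else NULL)
    pts <- pts[sample(nrow(pts)), , drop = FALSE]
    cop_trajectory((0:(nrow(pts) - 1L)) / fs, pts[, 1L], pts[, 2L], fs = fs)
  })
}

#' Simulate a whole cohort of LoS sessions
#'
#' Generates `n_low + n_high` sessions. Each subject gets a FES-I score
#' drawn within their group's range (16-22 low, 23-64 high),
#' group-consistent clinical scores, a simulated calibration, and 3
#' repetitions at each of the three height levels using the group's
#' behavioural profile. At the raised heights both groups stiffen slightly
#' (slower reaches; the high-FoF group also fails more targets),
#' strengthening at 40 cm the contrast the classifier exploits. The cohort
#' is a pure function of the arguments and `seed`.
#'
#' @param n_low,n_high Group sizes (either may be 0).
#' @param seed Integer seed.
#' @param fs Sampling rate (default 100 Hz).
#' @param low_profile,high_profile [sim_profile()] objects (defaults are the
#'   two presets).
#' @param heights Height levels to record (default all three).
#' @param reps Repetitions per height (default 3).
#' @return A list of [los_session()] objects, each carrying the simulated
#'   event logs and layouts in its trials.
#' @export
make_cohort <- function(n_low, n_high, seed, fs = 100,
                        low_profile = sim_profile("low_fof_like"),
                        high_profile = sim_profile("high_fof_like"),
                        heights = c("ground", "h20cm", "h40cm"), reps = 3L) {
  n_total <- n_low + n_high
  if (n_total == 0L) return(list())
  height_speed <- c(ground = 1, h20cm = 0.9, h40cm = 0.8)
  height_hit <- c(ground = 1, h20cm = 0.95, h40cm = 0.85)
  local_seed(seed, {
    purrr::map(seq_len(n_total), function(i) {
      is_low <- i <= n_low
      prof <- if (is_low) low_profile else high_profile
      fes <- if (is_low) sample(16:22, 1L) else sample(23:64, 1L)
      subj <- subject_record(
        subject_id = sprintf("S%02d", i), fes_i = fes,
        pt = if (is_low) sample(0:1, 1L) else sample(1:3, 1L),
        bbs = if (is_low) sample(50:56, 1L) else sample(40:52, 1L),
        tug = round(runif(1, if (is_low) 6 else 8, if (is_low) 9 else 14), 2),
        hy_stage = if (is_low) sample(c(1, 1.5, 2), 1L) else sample(c(2, 2.5, 3), 1L))
      attempts <- simulate_calibration(prof, seed = sample.int(2147483646L, 1L))
      calib <- compute_calibration(attempts)
      home <- tibble::tibble(x = 0, y = 0)
      layout <- place_targets(calib, home)
      trials <- purrr::flatten(purrr::map(heights, function(h) {
        hprof <- prof
        hprof$reach_speed <- prof$reach_speed * height_speed[[h]]
        hprof$hit_probability <- prof$hit_probability * height_hit[[h]]
        purrr::map(seq_len(reps), function(r) {
          sim <- simulate_los_trial(hprof, layout, seed = sample.int(2147483646L, 1L),
                                    fs = fs)
          list(height_level = h, repetition_index = r,
               traj = sim$traj,
               event_log = list(order = sim$order, true_score = sim$true_score,
                                phases = sim$event_log))
        })
      }))
      los_session(subj, calib, trials)
    })
  })
}
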