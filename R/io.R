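#' Read a CoP trajectory from CSV
#'
#' The on-disk dialect is a plain comma-separated file with a
#' `time_s,cop_x_mm,cop_y_mm` header and optional `#`-prefixed metadata lines
#' of the form `# key: value` (recognised keys: `fs`, `units`, `subject_id`,
#' `height_level`, `repetition_index`). Values are converted to millimetres
#' from the declared unit (`mm`, `cm` or `m`; default `mm`). When no `fs`
#' metadata is present the sampling rate is inferred as `1 / median(diff(t))`.
#'
#' @param path Path to a CSV file.
#' @return A [cop_trajectory] tibble. Metadata other than `fs`/`units` is
#'   attached as the `meta` attribute (a named character vector).
#' @seealso [write_cop_csv()]
#' @export
read_cop_csv <- function(path) {
  if (!file.exists(path))
    abort(paste0("file not found: ", path), class = "ftrcop_io_error")
  hdr <- readr::read_lines(path, n_max = 50L)
  meta_lines <- grep("^#", hdr, value = TRUE)
  meta <- character(0)
  if (length(meta_lines) > 0L) {
    kv <- regmatches(meta_lines, regexec("^#\\s*([A-Za-z_0-9.]+)\\s*:\\s*(.*?)\\s*$", meta_lines))
    kv <- kv[lengths(kv) == 3L]
    meta <- setNames(vapply(kv, `[`, "", 3L), vapply(kv, `[`, "", 2L))
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  for (col in c("time_s", "cop_x_mm", "cop_y_mm")) {
    if (!col %in% names(df))
      abort(paste0("missing required column '", col, "' in ", path),
            class = "ftrcop_format_error")
  }
  unit <- tolower(meta[["units"]] %||% "mm")
  scale <- switch(unit, mm = 1, cm = 10, m = 1000,
                  abort(paste0("unknown unit '", unit, "'"), class = "ftrcop_format_error"))
  fs <- if ("fs" %in% names(meta)) as.numeric(meta[["fs"]]) else NULL
  traj <- cop_trajectory(df$time_s, df$cop_x_mm * scale, df$cop_y_mm * scale, fs = fs)
  attr(traj, "meta") <- meta[setdiff(names(meta), c("fs", "units"))]
  traj
}

#' Write a CoP trajectory to CSV
#'
#' Serialises with 10 significant digits so that a read/write round trip is
#' lossless well below 1e-9 mm.
#'
#' @param traj A [cop_trajectory].
#' @param path Output file path.
#' @param meta Optional named character vector of extra metadata lines
#'   (e.g. `c(subject_id = "S01", height_level = "ground")`).
#' @return `path`, invisibly.
#' @export
write_cop_csv <- function(traj, path, meta = NULL) {
  traj <- as_cop_trajectory(traj)
  lines <- c(
    sprintf("# fs: %.10g", cop_fs(traj)),
    "# units: mm",
    if (length(meta) > 0L) sprintf("# %s: %s", names(meta), as.character(meta)),
    "time_s,cop_x_mm,cop_y_mm",
    sprintf("%.12g,%.12g,%.12g", traj$t, traj$x, traj$y)
  )
  tryCatch(readr::write_lines(lines, path),
           error = function(e) abort(paste0("cannot write ", path, ": ", conditionMessage(e)),
                                     class = "ftrcop_io_error"))
  invisible(path)
}

#' Construct a subject record
#'
#' Clinical metadata for one participant. `fes_i` is the Falls Efficacy
#' Scale-International total (16-64); the fear-of-falling group is derived
#' from it with [fesi_group()] unless supplied explicitly.
#'
#' @param subject_id Character identifier.
#' @param fes_i FES-I total score, integer in 16..64.
#' @param pt Pull Test grade 0..4 (optional).
#' @param bbs Berg Balance Scale 0..56 (optional).
#' @param tug Timed Up and Go, seconds > 0 (optional).
#' @param hy_stage Hoehn and Yahr stage, one of 1, 1.5, 2, 2.5, 3 (optional).
#' @param moca,hads_anxiety,hads_depression Optional integer scores.
#' @param fof_group `"low"` or `"high"`; defaults to `fesi_group(fes_i)`.
#' @return A one-row tibble of class `subject_record`.
#' @export
subject_record <- function(subject_id, fes_i, pt = NA_integer_, bbs = NA_integer_,
                           tug = NA_real_, hy_stage = NA_real_,
                           moca = NA_integer_, hads_anxiety = NA_integer_,
                           hads_depression = NA_integer_, fof_group = NULL) {
  fes_i <- as.integer(fes_i)
  if (is.na(fes_i) || fes_i < 16L || fes_i > 64L)
    abort("fes_i must be an integer in 16..64", class = "ftrcop_data_error")
  if (!is.na(pt) && !(pt %in% 0:4))
    abort("pt must be in 0..4", class = "ftrcop_data_error")
  if (!is.na(bbs) && !(bbs %in% 0:56))
    abort("bbs must be in 0..56", class = "ftrcop_data_error")
  if (!is.na(tug) && tug <= 0)
    abort("tug must be > 0 seconds", class = "ftrcop_data_error")
  if (!is.na(hy_stage) && !(hy_stage %in% c(1, 1.5, 2, 2.5, 3)))
    abort("hy_stage must be one of 1, 1.5, 2, 2.5, 3", class = "ftrcop_data_error")
  fof_group <- fof_group %||% fesi_group(fes_i)
  out <- tibble::tibble(
    subject_id = as.character(subject_id), fes_i = fes_i,
    pt = as.integer(pt), bbs = as.integer(bbs), tug = as.numeric(tug),
    hy_stage = as.numeric(hy_stage), moca = as.integer(moca),
    hads_anxiety = as.integer(hads_anxiety),
    hads_depression = as.integer(hads_depression),
    fof_group = match.arg(fof_group, c("low", "high"))
  )
  class(out) <- c("subject_record", class(out))
  out
}

#' Assemble a limit-of-stability session
#'
#' A session bundles one subject's record, their calibration profile, and the
#' recorded trials (up to 3 repetitions at each of the three support-surface
#' heights).
#'
#' @param subject A [subject_record()].
#' @param calibration A calibration profile from [compute_calibration()].
#' @param trials A list; each element is a list with fields `height_level`
#'   (`"ground"`, `"h20cm"` or `"h40cm"`), `repetition_index` (1..3), `traj`
#'   (a [cop_trajectory]) and optionally `event_log`.
#' @return A list of class `los_session`.
#' @export
los_session <- function(subject, calibration = NULL, trials = list()) {
  structure(list(subject = subject, calibration = calibration, trials = trials),
            class = "los_session")
}

#' Validate a session without raising
#'
#' Collects every invariant violation (missing calibration, more than 3
#' repetitions per height level, inconsistent sampling rates, a
#' fear-of-falling group label that contradicts the FES-I score) into a
#' report. An empty report means the session is valid.
#'
#' @param session A [los_session()].
#' @return A tibble with columns `field` and `message`; zero rows iff valid.
#' @export
validate_session <- function(session) {
  problems <- list()
  note <- function(field, message)
    problems[[length(problems) + 1L]] <<- tibble::tibble(field = field, message = message)

  if (is.null(session$calibration))
    note("calibration", "calibration profile missing; FTRs cannot be computed")
  subj <- session$subject
  if (!is.null(subj) && !is.na(subj$fes_i)) {
    expected <- fesi_group(subj$fes_i)
    if (!identical(subj$fof_group, expected))
      note("fof_group", sprintf("fof_group '%s' inconsistent with fes_i = %d (expected '%s')",
                                subj$fof_group, subj$fes_i, expected))
  }
  if (length(session$trials) > 0L) {
    levels_seen <- vapply(session$trials, function(tr) tr$height_level %||% NA_character_, "")
    reps <- vapply(session$trials,
                   function(tr) as.numeric(tr$repetition_index %||% NA_real_), 1.0)
    bad_level <- !levels_seen %in% c("ground", "h20cm", "h40cm")
    if (any(bad_level))
      note("height_level", paste0("unknown height level(s): ",
                                  paste(unique(levels_seen[bad_level]), collapse = ", ")))
    bad_rep <- !(reps %in% 1:3)
    if (any(bad_rep))
      note("repetition_index", "repetition_index outside 1..3")
    counts <- table(levels_seen[!bad_level])
    over <- names(counts)[counts > 3L]
    for (lv in over)
      note("trials", sprintf("repetitions > 3 at height level '%s' (%d recorded)",
                             lv, counts[[lv]]))
    fss <- vapply(session$trials, function(tr) cop_fs(tr$traj), 1.0)
    if (length(unique(round(fss, 6))) > 1L)
      note("fs", paste0("sampling rate differs across trials: ",
                        paste(unique(round(fss, 6)), collapse = ", "), " Hz"))
  }
  if (length(problems) == 0L)
    return(tibble::tibble(field = character(0), message = character(0)))
  dplyr::bind_rows(problems)
}

#' Write a session to a directory as manifest + CSVs
#'
#' Writes `manifest.json` (subject record, calibration, per-trial file list
#' with condition labels) plus one CoP CSV per trial.
#'
#' @param session A [los_session()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trial_entries <- purrr::imap(session$trials, function(tr, i) {
    fname <- sprintf("trial_%s_rep%d.csv", tr$height_level, tr$repetition_index)
    write_cop_csv(tr$traj, file.path(dir, fname),
                  meta = c(height_level = tr$height_level,
                           repetition_index = as.character(tr$repetition_index)))
    list(path = fname, height_level = tr$height_level,
         repetition_index = tr$repetition_index,
         event_log = tr$event_log)
  })
  manifest <- list(
    schema = "ftrcop-session/1",
    subject = as.list(session$subject[1L, ]),
    calibration = if (!is.null(session$calibration))
      list(direction = session$calibration$direction,
           max_excursion_mm = session$calibration$max_excursion_mm,
           n_attempts = attr(session$calibration, "n_attempts")),
    trials = trial_entries
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a session from a manifest directory
#'
#' @param path Path to a `manifest.json` written by [write_session()], or to
#'   the directory containing it.
#' @return A [los_session()].
#' @export
read_session <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  if (!file.exists(path))
    abort(paste0("manifest not found: ", path), class = "ftrcop_io_error")
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- dirname(path)
  subj <- do.call(subject_record, m$subject[!vapply(m$subject, is.null, TRUE)])
  calib <- NULL
  if (!is.null(m$calibration)) {
    calib <- new_calibration(
      direction = unlist(m$calibration$direction),
      max_excursion_mm = unlist(m$calibration$max_excursion_mm),
      n_attempts = m$calibration$n_attempts %||% NA_integer_)
  }
  trials <- purrr::map(m$trials, function(tr) {
    list(height_level = tr$height_level,
         repetition_index = as.integer(tr$repetition_index),
         traj = read_cop_csv(file.path(base, tr$path)),
         event_log = tr$event_log)
  })
  los_session(subj, calib, trials)
}
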