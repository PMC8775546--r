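# Channel vocabulary. Joint-angle channels follow the wearable-IMU export
# convention <side>_<joint>_<measure>; only anatomically meaningful
# combinations are accepted.
kin_joints <- c("elbow", "hip", "knee")
kin_measures <- c("flexion", "abduction", "rotation")
kin_sides <- c("left", "right")
kin_groups <- c("PD", "OA")
kin_dances <- c("tango", "waltz", "foxtrot", "line", "rumba", "swing")

valid_joint_measures <- function() {
  rbind(
    data.frame(joint = "elbow", measure = "flexion"),
    data.frame(joint = "hip", measure = c("flexion", "abduction", "rotation")),
    data.frame(joint = "knee", measure = "flexion")
  )
}

# Lower-limb channels analysed by default; the elbow is recorded but not
# analysed unless explicitly allowed.
#' Default channel allow-list: the lower-limb joint measures
#' @return Character vector of `<joint>_<measure>` names.
#' @export
lower_limb_channels <- function() {
  c("hip_flexion", "hip_abduction", "hip_rotation", "knee_flexion")
}

channel_name <- function(side, joint, measure) paste(side, joint, measure, sep = "_")

parse_channel_name <- function(name) {
  parts <- strsplit(name, "_", fixed = TRUE)[[1]]
  if (length(parts) != 3L) return(NULL)
  side <- parts[1]; joint <- parts[2]; measure <- parts[3]
  vm <- valid_joint_measures()
  ok <- side %in% kin_sides &&
    any(vm$joint == joint & vm$measure == measure)
  if (!ok) return(NULL)
  list(side = side, joint = joint, measure = measure)
}

#' One channel of joint-angle samples
#'
#' @param values numeric vector of joint angles in degrees.
#' @param fs sampling frequency in Hz; default 100.
#' @param joint one of `"elbow"`, `"hip"`, `"knee"`.
#' @param measure one of `"flexion"`, `"abduction"`, `"rotation"`; the elbow
#'   and knee admit flexion only.
#' @param side `"left"` or `"right"`.
#' @param recording_id identifier of the recording this channel belongs to.
#' @return An object of class `joint_series` with fields as above plus `n`
#'   and `duration_s`.
#' @export
joint_series <- function(values, fs = 100, joint, measure, side,
                         recording_id = NA_character_) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) {
    kin_abort("kin_error_argument", "joint_series values must be finite")
  }
  if (!is.numeric(fs) || fs <= 0) kin_abort("kin_error_argument", "fs must be > 0")
  joint <- match.arg(joint, kin_joints)
  measure <- match.arg(measure, kin_measures)
  side <- match.arg(side, kin_sides)
  vm <- valid_joint_measures()
  if (!any(vm$joint == joint & vm$measure == measure)) {
    kin_abort("kin_error_argument",
              sprintf("invalid joint/measure combination: %s %s", joint, measure))
  }
  structure(
    list(values = values, n = length(values), fs = fs, joint = joint,
         measure = measure, side = side, recording_id = recording_id,
         duration_s = length(values) / fs),
    class = "joint_series"
  )
}

#' @export
print.joint_series <- function(x, ...) {
  cat(sprintf("<joint_series> %s (%s): %d samples @ %g Hz (%.1f s)\n",
              channel_name(x$side, x$joint, x$measure), x$recording_id,
              x$n, x$fs, x$duration_s))
  invisible(x)
}

#' A motion-capture recording: a set of synchronised joint-angle channels
#'
#' @param recording_id unique identifier within a cohort.
#' @param participant_id participant identifier.
#' @param group `"PD"` or `"OA"`.
#' @param dance one of tango, waltz, foxtrot, line, rumba, swing.
#' @param channels list of [`joint_series`][joint_series], all sharing `fs`
#'   and length.
#' @param fs sampling frequency; defaults to the channels' common value.
#' @return An object of class `recording`.
#' @export
recording <- function(recording_id, participant_id, group, dance, channels,
                      fs = NULL) {
  group <- match.arg(group, kin_groups)
  dance <- match.arg(dance, kin_dances)
  if (length(channels) == 0L) {
    kin_abort("kin_error_validation", "recording must contain at least one channel")
  }
  if (!all(vapply(channels, inherits, logical(1), "joint_series"))) {
    kin_abort("kin_error_argument", "channels must be joint_series objects")
  }
  fss <- vapply(channels, function(ch) ch$fs, numeric(1))
  ns <- vapply(channels, function(ch) ch$n, numeric(1))
  if (length(unique(fss)) != 1L || length(unique(ns)) != 1L) {
    kin_abort("kin_error_validation",
              "all channels of a recording must share fs and length")
  }
  if (is.null(fs)) fs <- fss[1]
  names(channels) <- vapply(
    channels, function(ch) channel_name(ch$side, ch$joint, ch$measure),
    character(1)
  )
  structure(
    list(recording_id = recording_id, participant_id = participant_id,
         group = group, dance = dance, channels = channels, fs = fs,
         n = ns[1], duration_min = ns[1] / fs / 60),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: participant %s (%s, %s), %d channels, %.2f min @ %g Hz\n",
              x$recording_id, x$participant_id, x$group, x$dance,
              length(x$channels), x$duration_min, x$fs))
  invisible(x)
}

# Canonical channel column order: left before right, proximal joints before
# distal, flexion/abduction/rotation within a joint.
canonical_channel_order <- function() {
  vm <- valid_joint_measures()
  out <- character(0)
  for (side in kin_sides) {
    for (joint in kin_joints) {
      for (measure in kin_measures) {
        if (any(vm$joint == joint & vm$measure == measure)) {
          out <- c(out, channel_name(side, joint, measure))
        }
      }
    }
  }
  out
}

#' Read a recording from a wide-format CSV
#'
#' Expects a header row with first column `time_s` (uniform step `1/fs`,
#' checked to 1% relative tolerance) and channel columns named
#' `<side>_<joint>_<measure>` (e.g. `left_knee_flexion`), values in degrees.
#' Unrecognised columns are ignored with a warning. The sampling frequency
#' is inferred from the time column and, when the manifest entry carries an
#' `fs`, checked against it.
#'
#' @param path CSV file path.
#' @param meta manifest entry: list or one-row data frame with
#'   `participant_id`, `group`, `dance`, `recording_id` and optionally `fs`.
#' @return A [`recording`][recording].
#' @export
read_recording_csv <- function(path, meta) {
  if (!file.exists(path)) {
    kin_abort("kin_error_io", sprintf("file not found: %s", path))
  }
  meta <- as.list(meta)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = NA,
                        stringsAsFactors = FALSE)
  if (!"time_s" %in% names(df)) {
    kin_abort("kin_error_format",
              sprintf("%s: missing required column 'time_s'", path))
  }
  for (col in names(df)) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      kin_abort("kin_error_format",
                sprintf("%s: non-numeric value in column '%s' at data row %d",
                        path, col, if (is.na(bad)) 1L else bad))
    }
    if (anyNA(v)) {
      kin_abort("kin_error_format",
                sprintf("%s: missing value in column '%s' at data row %d",
                        path, col, which(is.na(v))[1]))
    }
  }
  tt <- df$time_s
  if (length(tt) < 2L) {
    kin_abort("kin_error_format", sprintf("%s: fewer than 2 samples", path))
  }
  steps <- diff(tt)
  step <- stats::median(steps)
  if (step <= 0 || any(abs(steps - step) > 0.01 * step)) {
    kin_abort("kin_error_format",
              sprintf("%s: non-uniform sampling (time step varies by more than 1%%)",
                      path))
  }
  fs <- 1 / step
  if (!is.null(meta$fs) && !is.na(meta$fs) &&
      abs(fs - meta$fs) > 0.01 * meta$fs) {
    kin_abort("kin_error_format",
              sprintf("%s: inferred fs %.3f Hz disagrees with manifest fs %.3f Hz",
                      path, fs, meta$fs))
  }
  chan_cols <- setdiff(names(df), "time_s")
  channels <- list()
  unknown <- character(0)
  for (col in chan_cols) {
    p <- parse_channel_name(col)
    if (is.null(p)) {
      unknown <- c(unknown, col)
      next
    }
    channels[[col]] <- joint_series(df[[col]], fs = fs, joint = p$joint,
                                    measure = p$measure, side = p$side,
                                    recording_id = meta$recording_id)
  }
  if (length(unknown)) {
    warning(sprintf("%s: ignoring unrecognised column(s): %s",
                    path, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (length(channels) == 0L) {
    kin_abort("kin_error_format",
              sprintf("%s: no valid channel columns (need <side>_<joint>_<measure>)",
                      path))
  }
  recording(recording_id = meta$recording_id,
            participant_id = meta$participant_id,
            group = meta$group, dance = meta$dance,
            channels = channels, fs = fs)
}

#' Write a recording to the CSV dialect read by [read_recording_csv()]
#'
#' Columns are emitted in a deterministic order (time, then left-to-right,
#' proximal-to-distal, flexion/abduction/rotation) at 17 significant digits,
#' so writing the same recording twice yields byte-identical files and a
#' write/read round trip is lossless.
#'
#' @param rec a [`recording`][recording].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  if (!inherits(rec, "recording")) {
    kin_abort("kin_error_argument", "rec must be a recording")
  }
  if (length(rec$channels) == 0L) {
    kin_abort("kin_error_validation", "refusing to write a recording with no channels")
  }
  ord <- intersect(canonical_channel_order(), names(rec$channels))
  n <- rec$n
  cols <- c("time_s", ord)
  num_fmt <- function(v) sprintf("%.17g", v)
  mat <- cbind(
    num_fmt((seq_len(n) - 1L) / rec$fs),
    do.call(cbind, lapply(ord, function(cn) num_fmt(rec$channels[[cn]]$values)))
  )
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    kin_abort("kin_error_io", sprintf("cannot open %s for writing", path))
  })
  on.exit(close(con))
  writeLines(c(paste(cols, collapse = ","),
               apply(mat, 1L, paste, collapse = ",")),
             con, sep = "\n")
  invisible(path)
}

#' Write a cohort manifest CSV
#'
#' @param entries data frame with columns `file`, `participant_id`, `group`,
#'   `dance`, `recording_id`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest_csv <- function(entries, path) {
  need <- c("file", "participant_id", "group", "dance", "recording_id")
  if (!all(need %in% names(entries))) {
    kin_abort("kin_error_format",
              sprintf("manifest must have columns: %s", paste(need, collapse = ", ")))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(need, collapse = ","),
               apply(as.matrix(entries[, need]), 1L, paste, collapse = ",")),
             con, sep = "\n")
  invisible(path)
}

#' Load a cohort of recordings from a manifest
#'
#' The manifest is a flat CSV with columns `file`, `participant_id`,
#' `group`, `dance`, `recording_id` (paths relative to the manifest's
#' directory). Entries whose files fail validation are excluded and reported
#' — never silently dropped — mirroring per-participant exclusion of invalid
#' time series in field studies. Duplicate recording ids or zero loadable
#' recordings are fatal.
#'
#' @param manifest_path path to the manifest CSV.
#' @return An object of class `cohort`: list with `recordings` (list of
#'   [`recording`][recording]) and `exclusions` (data frame `file`, `reason`).
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    kin_abort("kin_error_io", sprintf("manifest not found: %s", manifest_path))
  }
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("file", "participant_id", "group", "dance", "recording_id")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols)) {
    kin_abort("kin_error_format",
              sprintf("manifest missing column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(man$recording_id)) {
    kin_abort("kin_error_manifest",
              sprintf("duplicate recording_id in manifest: %s",
                      paste(unique(man$recording_id[duplicated(man$recording_id)]),
                            collapse = ", ")))
  }
  if (anyDuplicated(man[, c("participant_id", "recording_id")])) {
    kin_abort("kin_error_manifest", "duplicate (participant_id, recording_id) pair")
  }
  base_dir <- dirname(normalizePath(manifest_path, mustWork = TRUE))
  recs <- list()
  excl <- data.frame(file = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(man))) {
    entry <- as.list(man[i, ])
    entry$recording_id <- as.character(entry$recording_id)
    entry$participant_id <- as.character(entry$participant_id)
    fp <- entry$file
    if (!file.exists(fp)) fp <- file.path(base_dir, entry$file)
    rec <- tryCatch(read_recording_csv(fp, entry), kinentropy_error = function(e) e)
    if (inherits(rec, "kinentropy_error")) {
      excl <- rbind(excl, data.frame(file = entry$file,
                                     reason = conditionMessage(rec),
                                     stringsAsFactors = FALSE))
    } else {
      recs[[entry$recording_id]] <- rec
    }
  }
  if (length(recs) == 0L) {
    kin_abort("kin_error_fatal",
              sprintf("no loadable recordings (%d excluded)", nrow(excl)))
  }
  if (nrow(excl)) {
    message(sprintf("excluded %d recording(s): %s", nrow(excl),
                    paste(sprintf("%s (%s)", excl$file, excl$reason),
                          collapse = "; ")))
  }
  cohort(recs, exclusions = excl)
}

#' Assemble a cohort object from recordings
#'
#' @param recordings list of [`recording`][recording] objects.
#' @param exclusions optional data frame of excluded entries (`file`, `reason`).
#' @return An object of class `cohort`.
#' @export
cohort <- function(recordings, exclusions = NULL) {
  if (length(recordings) == 0L) {
    kin_abort("kin_error_fatal", "a cohort needs at least one recording")
  }
  ids <- vapply(recordings, function(r) as.character(r$recording_id), character(1))
  if (anyDuplicated(ids)) {
    kin_abort("kin_error_manifest", "duplicate recording_id in cohort")
  }
  names(recordings) <- ids
  if (is.null(exclusions)) {
    exclusions <- data.frame(file = character(0), reason = character(0),
                             stringsAsFactors = FALSE)
  }
  structure(list(recordings = recordings, exclusions = exclusions),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  groups <- table(vapply(x$recordings, function(r) r$group, character(1)))
  cat(sprintf("<cohort> %d recordings (%s); %d excluded\n",
              length(x$recordings),
              paste(sprintf("%s: %d", names(groups), groups), collapse = ", "),
              nrow(x$exclusions)))
  invisible(x)
}
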