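#' Stylus pressure range of the tablet (device units)
#'
#' The tablet OS reports pen-tip pressure in a custom unit ranging from 0 to
#' 4.166667. Recordings keep this scale unchanged so the maximum-pressure
#' feature is directly comparable across devices of the same family.
#' @export
PRESSURE_MAX <- 4.166667

VALID_LABELS <- c("non-CTS", "CTS", "unknown")

#' Construct a stylus drawing recording
#'
#' A recording is one subject's uniformly sampled stylus time series: frame
#' index, time (s), position (cm, screen-fixed frame with the origin at the
#' spiral centre, y up) and pen pressure (device units, 0 to
#' \code{PRESSURE_MAX}). A recording is a single continuous stroke; gaps in
#' the frame index are rejected.
#'
#' @param samples data.frame with columns \code{frame}, \code{t}, \code{x},
#'   \code{y}, \code{pressure}. \code{t} may be omitted; it is derived as
#'   \code{frame / sampling_rate}.
#' @param subject_id character scalar.
#' @param label one of \code{"non-CTS"}, \code{"CTS"}, \code{"unknown"}.
#' @param sampling_rate sampling frequency in Hz (tablet frame rate).
#' @param severity_grade optional integer 1-6 (Bland grade), \code{NA} if
#'   unknown.
#' @return an object of class \code{drawing_recording}.
#' @export
drawing_recording <- function(samples, subject_id, label = "unknown",
                              sampling_rate = 120, severity_grade = NA_integer_) {
  stopifnot(is.data.frame(samples), is.character(subject_id),
            length(subject_id) == 1L)
  label <- match.arg(label, VALID_LABELS)
  need <- c("frame", "x", "y", "pressure")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("recording samples missing column(s): ", paste(miss, collapse = ", "))
  if (!"t" %in% names(samples))
    samples$t <- samples$frame / sampling_rate
  samples <- samples[, c("frame", "t", "x", "y", "pressure")]
  rec <- structure(
    list(subject_id = subject_id, label = label,
         severity_grade = as.integer(severity_grade),
         sampling_rate = sampling_rate, samples = samples),
    class = "drawing_recording")
  validate_recording(rec)
  rec
}

#' Validate a drawing recording
#'
#' Enforces the recording invariants: pressure within \code{[0, PRESSURE_MAX]},
#' strictly increasing contiguous frame indices (uniform sampling, single
#' stroke), and \code{t = frame / sampling_rate} to within 1e-9 s. Errors name
#' the first offending row.
#'
#' @param rec a \code{drawing_recording}.
#' @return \code{rec}, invisibly.
#' @export
validate_recording <- function(rec) {
  s <- rec$samples
  n <- nrow(s)
  if (n == 0L) return(invisible(rec))
  bad <- which(s$pressure < 0 | s$pressure > PRESSURE_MAX + 1e-9)
  if (length(bad))
    stop(sprintf("pressure out of range [0, %s] at row %d (value %g)",
                 format(PRESSURE_MAX), bad[1], s$pressure[bad[1]]))
  if (n > 1L) {
    d <- diff(s$frame)
    if (any(d <= 0))
      stop("frame indices not strictly increasing at row ",
           which(d <= 0)[1] + 1L)
    if (any(d != 1L))
      stop("gap in frame indices at row ", which(d != 1L)[1] + 1L,
           " (multi-stroke recordings are not supported)")
  }
  if (any(s$frame < 0)) stop("negative frame index at row ",
                             which(s$frame < 0)[1])
  terr <- abs(s$t - s$frame / rec$sampling_rate)
  if (any(terr > 1e-9))
    stop("t inconsistent with frame/sampling_rate at row ",
         which(terr > 1e-9)[1])
  invisible(rec)
}

#' @export
print.drawing_recording <- function(x, ...) {
  cat(sprintf("<drawing_recording> subject %s  label %s  %d samples (%.2f s @ %g Hz)\n",
              x$subject_id, x$label, nrow(x$samples),
              nrow(x$samples) / x$sampling_rate, x$sampling_rate))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a \code{drawing_recording}.
#' @return duration \code{n_samples / sampling_rate} in seconds.
#' @export
recording_duration <- function(rec) nrow(rec$samples) / rec$sampling_rate

fmt_num <- function(x) {
  # full double precision, deterministic ASCII; integers without exponent
  ifelse(is.finite(x) & x == round(x) & abs(x) < 2^53,
         sprintf("%.0f", x), sprintf("%.17g", x))
}

#' Write a recording to CSV
#'
#' One file per subject: a commented header block (\code{# subject_id=...},
#' \code{# label=...}, \code{# sampling_rate=...}, \code{# severity_grade=...})
#' followed by \code{frame,t,x,y,pressure} rows at full double precision.
#' Output bytes are deterministic for identical input.
#'
#' @param rec a \code{drawing_recording}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  s <- rec$samples
  hdr <- c(sprintf("# subject_id=%s", rec$subject_id),
           sprintf("# label=%s", rec$label),
           sprintf("# sampling_rate=%s", fmt_num(rec$sampling_rate)),
           sprintf("# severity_grade=%s",
                   if (is.na(rec$severity_grade)) "NA" else rec$severity_grade),
           "frame,t,x,y,pressure")
  rows <- if (nrow(s)) paste(fmt_num(s$frame), fmt_num(s$t), fmt_num(s$x),
                             fmt_num(s$y), fmt_num(s$pressure), sep = ",")
          else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, rows), con, sep = "\n")
  invisible(path)
}

#' Read a recording from CSV
#'
#' Parses the commented header block for subject metadata, then the
#' \code{frame,t,x,y,pressure} table, and validates all recording invariants.
#'
#' @param path file written by \code{\link{write_recording}} (or any CSV in
#'   the same layout).
#' @return a validated \code{drawing_recording}.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list(subject_id = "unknown", label = "unknown",
               sampling_rate = "120", severity_grade = "NA")
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substring(kv, eq + 1)
  }
  body <- lines[!grepl("^#", lines)]
  if (!length(body)) stop("format error: no header row in ", path)
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  need <- c("frame", "t", "x", "y", "pressure")
  if (!all(need %in% header))
    stop("format error: missing column(s) ",
         paste(setdiff(need, header), collapse = ", "), " in ", path)
  if (length(body) > 1L) {
    df <- utils::read.csv(text = body, colClasses = "numeric")
  } else {
    df <- as.data.frame(matrix(numeric(0), 0, length(header),
                               dimnames = list(NULL, header)))
  }
  drawing_recording(df[, need],
                    subject_id = meta$subject_id, label = meta$label,
                    sampling_rate = as.numeric(meta$sampling_rate),
                    severity_grade = if (identical(meta$severity_grade, "NA"))
                      NA_integer_ else as.integer(meta$severity_grade))
}

#' Feature extraction configuration
#'
#' Holds the windowing constants of the jerk-spectral featurization: the
#' analysis window is the first \code{window_frames} jerk values, split into
#' \code{n_chunks} consecutive chunks of \code{chunk_frames} frames; each
#' chunk is Hanning-windowed and Fourier-transformed and only components at
#' or below \code{max_retained_freq} (excluding DC) are kept.
#'
#' @param window_frames analysis window length in frames (default 512).
#' @param n_chunks number of chunks (default 16).
#' @param chunk_frames frames per chunk (default 32).
#' @param sampling_rate Hz (default 120).
#' @param max_retained_freq highest retained frequency, Hz (default 60, the
#'   Nyquist frequency at 120 Hz).
#' @return an object of class \code{feature_config}.
#' @export
feature_config <- function(window_frames = 512L, n_chunks = 16L,
                           chunk_frames = 32L, sampling_rate = 120,
                           max_retained_freq = 60) {
  if (window_frames != n_chunks * chunk_frames)
    stop("window_frames must equal n_chunks * chunk_frames")
  if (max_retained_freq > sampling_rate / 2)
    stop("max_retained_freq exceeds the Nyquist frequency")
  structure(list(window_frames = as.integer(window_frames),
                 n_chunks = as.integer(n_chunks),
                 chunk_frames = as.integer(chunk_frames),
                 sampling_rate = sampling_rate,
                 max_retained_freq = max_retained_freq),
            class = "feature_config")
}

#' Per-subject feature bundle
#'
#' Container for the four training-data sets of the screening pipeline:
#' \enumerate{
#'   \item \code{spectral_pressure}: jerk-of-pressure spectrogram (256-vector
#'     under defaults),
#'   \item \code{spectral_trajectory}: jerk-of-trajectory spectrogram
#'     (256-vector),
#'   \item \code{rmse}: spiral tracing error vs the guide spiral (cm),
#'   \item \code{max_pressure}: maximum pen pressure (device units).
#' }
#'
#' @param subject_id character scalar.
#' @param spectral_pressure,spectral_trajectory numeric feature vectors.
#' @param rmse non-negative scalar (cm).
#' @param max_pressure scalar in \code{[0, PRESSURE_MAX]}.
#' @param label class label.
#' @return an object of class \code{feature_bundle}.
#' @export
feature_bundle <- function(subject_id, spectral_pressure, spectral_trajectory,
                           rmse, max_pressure, label = "unknown") {
  label <- match.arg(label, VALID_LABELS)
  stopifnot(rmse >= 0, max_pressure >= 0,
            max_pressure <= PRESSURE_MAX + 1e-9,
            length(spectral_pressure) == length(spectral_trajectory),
            all(is.finite(spectral_pressure)), all(is.finite(spectral_trajectory)))
  structure(list(subject_id = subject_id,
                 spectral_pressure = as.numeric(spectral_pressure),
                 spectral_trajectory = as.numeric(spectral_trajectory),
                 rmse = rmse, max_pressure = max_pressure, label = label),
            class = "feature_bundle")
}

# canonical order and dimensions of the four training-data sets
bundle_set_names <- c("spectral_pressure", "spectral_trajectory",
                      "rmse", "max_pressure")

normalize_selection <- function(selection) {
  if (is.numeric(selection)) {
    if (!all(selection %in% 1:4)) stop("set selection must be within 1..4")
    sel <- sort(unique(as.integer(selection)))
  } else {
    idx <- match(selection, bundle_set_names)
    if (anyNA(idx)) stop("unknown set name(s): ",
                         paste(selection[is.na(idx)], collapse = ", "))
    sel <- sort(unique(idx))
  }
  if (!length(sel)) stop("selection must name at least one feature set")
  sel
}

#' Stack feature bundles into a design matrix
#'
#' Builds the SVM design matrix for a selection of the four training-data
#' sets. Columns are ordered by set index (pressure spectrum, trajectory
#' spectrum, RMSE, max pressure), each spectral set contributing its full
#' vector in chunk-major order, so e.g. sets 2+3 give 257 columns.
#'
#' @param bundles list of \code{feature_bundle}.
#' @param selection subset of \code{1:4} or of the set names
#'   \code{c("spectral_pressure", "spectral_trajectory", "rmse",
#'   "max_pressure")}.
#' @return list with \code{x} (n-by-d numeric matrix, row names = subject
#'   ids) and \code{labels} (factor with levels \code{non-CTS}, \code{CTS}).
#' @export
bundle_to_matrix <- function(bundles, selection = 1:4) {
  sel <- normalize_selection(selection)
  stopifnot(length(bundles) >= 1L)
  rows <- lapply(bundles, function(b) {
    unlist(lapply(bundle_set_names[sel], function(nm) b[[nm]]),
           use.names = FALSE)
  })
  d <- unique(lengths(rows))
  if (length(d) != 1L) stop("bundles have inconsistent feature dimensions")
  x <- do.call(rbind, rows)
  rownames(x) <- vapply(bundles, `[[`, "", "subject_id")
  cn <- unlist(lapply(sel, function(i) {
    nm <- bundle_set_names[i]
    k <- length(bundles[[1]][[nm]])
    if (k == 1L) nm else sprintf("%s_%03d", nm, seq_len(k))
  }))
  colnames(x) <- cn
  labels <- factor(vapply(bundles, `[[`, "", "label"),
                   levels = c("non-CTS", "CTS"))
  list(x = x, labels = labels)
}

#' Write feature bundles to CSV (one row per subject)
#'
#' @param bundles list of \code{feature_bundle}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bundles <- function(bundles, path) {
  k <- length(bundles[[1]]$spectral_pressure)
  header <- c("subject_id", "label",
              sprintf("press_%03d", seq_len(k)),
              sprintf("traj_%03d", seq_len(k)),
              "rmse", "max_pressure")
  rows <- vapply(bundles, function(b) {
    paste(c(b$subject_id, b$label, fmt_num(b$spectral_pressure),
            fmt_num(b$spectral_trajectory), fmt_num(b$rmse),
            fmt_num(b$max_pressure)), collapse = ",")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = ","), rows), con, sep = "\n")
  invisible(path)
}

#' Read feature bundles from CSV
#' @param path file written by \code{\link{write_bundles}}.
#' @return list of \code{feature_bundle}.
#' @export
read_bundles <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  pcols <- grep("^press_", names(df)); tcols <- grep("^traj_", names(df))
  if (!length(pcols) || !length(tcols) ||
      !all(c("subject_id", "label", "rmse", "max_pressure") %in% names(df)))
    stop("format error: not a feature-bundle CSV: ", path)
  lapply(seq_len(nrow(df)), function(i) {
    feature_bundle(df$subject_id[i],
                   as.numeric(df[i, pcols]), as.numeric(df[i, tcols]),
                   df$rmse[i], df$max_pressure[i], df$label[i])
  })
}
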