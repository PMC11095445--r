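# Track and angle-series containers and their flat-file formats.

hk_roles <- c("zooid_gut", "reference_particle", "off_axis_marker",
              "siphon", "jet_trace")

#' Construct a landmark track
#'
#' A landmark track is one digitized 3D point followed through a recording:
#' a zooid gut, a passive reference particle, an off-axis marker (e.g. an
#' unreleased fecal pellet on a zooid edge), a siphon, or a digitized jet
#' trace. Coordinates are in mm, time in seconds.
#'
#' @param landmark_id Character id, unique within a recording.
#' @param role One of `"zooid_gut"`, `"reference_particle"`,
#'   `"off_axis_marker"`, `"siphon"`, `"jet_trace"`.
#' @param samples Data frame with columns `frame` (integer, strictly
#'   increasing), `t` (seconds, strictly increasing), `x`, `y`, `z` (mm).
#' @param zooid_index Optional 1-based zooid position (1 = frontal zooid).
#' @return An object of class `landmark_track`.
#' @export
landmark_track <- function(landmark_id, role, samples, zooid_index = NA_integer_) {
  if (!role %in% hk_roles)
    hk_stop(sprintf("unknown role '%s'", role), "hk_format_error")
  samples <- as.data.frame(samples)
  need <- c("frame", "t", "x", "y", "z")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    hk_stop(paste("samples missing column(s):", paste(miss, collapse = ", ")),
            "hk_format_error")
  samples <- samples[, need]
  rownames(samples) <- NULL
  samples$frame <- as.integer(samples$frame)
  if (anyDuplicated(samples$frame))
    hk_stop(sprintf("duplicate frames in track '%s'", landmark_id),
            "hk_duplicate_sample")
  if (is.unsorted(samples$frame, strictly = TRUE))
    hk_stop(sprintf("frames not strictly increasing in track '%s'", landmark_id),
            "hk_ordering_error")
  if (is.unsorted(samples$t, strictly = TRUE))
    hk_stop(sprintf("times not strictly increasing in track '%s'", landmark_id),
            "hk_ordering_error")
  if (!all(is.finite(as.matrix(samples[, c("x", "y", "z")]))))
    hk_stop(sprintf("non-finite coordinates in track '%s'", landmark_id),
            "hk_format_error")
  structure(list(landmark_id = as.character(landmark_id), role = role,
                 zooid_index = as.integer(zooid_index), samples = samples),
            class = "landmark_track")
}

#' @export
print.landmark_track <- function(x, ...) {
  cat(sprintf("<landmark_track> '%s' (%s%s): %d samples, t in [%g, %g] s\n",
              x$landmark_id, x$role,
              if (is.na(x$zooid_index)) "" else paste0(", zooid ", x$zooid_index),
              nrow(x$samples), min(x$samples$t), max(x$samples$t)))
  invisible(x)
}

#' Construct a colony recording
#'
#' Bundles all landmark tracks digitized from one salp chain together with
#' the colony metadata used downstream (frame rate, zooid count and sizes).
#'
#' @param colony_id Character id.
#' @param tracks List of [landmark_track()] objects.
#' @param frame_rate Frames per second used to digitize the recording.
#' @param zooid_count Number of zooids in the chain (>= 1).
#' @param chain_length,zooid_length Optional lengths in mm.
#' @param metadata Optional named list (site, date, ...).
#' @return An object of class `colony_recording`.
#' @export
colony_recording <- function(colony_id, tracks, frame_rate,
                             zooid_count = 1L, chain_length = NA_real_,
                             zooid_length = NA_real_, metadata = list()) {
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0)
    hk_stop("frame_rate must be a single positive number", "hk_parameter_error")
  if (zooid_count < 1)
    hk_stop("zooid_count must be >= 1", "hk_parameter_error")
  if (!length(tracks)) tracks <- list()
  ids <- vapply(tracks, function(tr) tr$landmark_id, character(1))
  if (anyDuplicated(ids))
    hk_stop("duplicate landmark ids", "hk_duplicate_sample")
  names(tracks) <- ids
  roles <- vapply(tracks, function(tr) tr$role, character(1))
  if (sum(roles == "reference_particle") > 1)
    hk_stop("at most one reference_particle track is allowed", "hk_format_error")
  for (tr in tracks) {
    if (max(abs(tr$samples$t - tr$samples$frame / frame_rate)) > 1e-6)
      hk_stop(sprintf("track '%s': t inconsistent with frame/frame_rate",
                      tr$landmark_id), "hk_format_error")
  }
  if (length(tracks) > 1) {
    shared <- Reduce(intersect, lapply(tracks, function(tr) tr$samples$frame))
    if (!length(shared))
      hk_stop("tracks share no common frames", "hk_alignment_error")
  }
  structure(list(colony_id = as.character(colony_id), frame_rate = frame_rate,
                 zooid_count = as.integer(zooid_count),
                 chain_length = chain_length, zooid_length = zooid_length,
                 tracks = tracks, metadata = metadata),
            class = "colony_recording")
}

#' @export
print.colony_recording <- function(x, ...) {
  cat(sprintf("<colony_recording> '%s': %d tracks, %g fps, %d zooids\n",
              x$colony_id, length(x$tracks), x$frame_rate, x$zooid_count))
  for (tr in x$tracks)
    cat(sprintf("  %-12s %-18s %d samples\n", tr$landmark_id, tr$role,
                nrow(tr$samples)))
  invisible(x)
}

#' Extract tracks from a recording
#'
#' `get_track` returns one track by id; `zooid_tracks` the zooid-gut tracks
#' ordered by `zooid_index`; `reference_track` the (single) passive reference
#' particle, or `NULL` when absent.
#'
#' @param rec A [colony_recording()].
#' @param id Landmark id.
#' @return A [landmark_track()], a list of them, or `NULL`.
#' @export
get_track <- function(rec, id) {
  tr <- rec$tracks[[id]]
  if (is.null(tr)) hk_stop(sprintf("no track '%s'", id), "hk_format_error")
  tr
}

#' @rdname get_track
#' @export
zooid_tracks <- function(rec) {
  zs <- Filter(function(tr) tr$role == "zooid_gut", rec$tracks)
  idx <- vapply(zs, function(tr) tr$zooid_index, integer(1))
  zs[order(idx)]
}

#' @rdname get_track
#' @export
reference_track <- function(rec) {
  rs <- Filter(function(tr) tr$role == "reference_particle", rec$tracks)
  if (!length(rs)) NULL else rs[[1]]
}

#' Read digitized landmark tracks from CSV
#'
#' The file is a flat CSV with one row per (landmark, frame) and columns
#' `landmark_id, role, zooid_index, frame, x, y, z` (a `t` column is optional
#' and recomputed as `frame / frame_rate` when absent). A JSON sidecar
#' `<path>.meta.json`, written by [write_tracks()], supplies colony metadata;
#' without a sidecar, `frame_rate` must be given.
#'
#' @param path CSV file path.
#' @param frame_rate Frames per second; overrides any sidecar value.
#' @param colony_id Id used when no sidecar is present.
#' @return A validated [colony_recording()].
#' @export
read_tracks <- function(path, frame_rate = NULL, colony_id = NULL) {
  if (!file.exists(path))
    hk_stop(sprintf("file not found: %s", path), "hk_io_error")
  meta <- list()
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar))
    meta <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
  frame_rate <- frame_rate %||% meta$frame_rate
  if (is.null(frame_rate))
    hk_stop("frame_rate not given and no metadata sidecar found",
            "hk_parameter_error")
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("landmark_id", "role", "zooid_index", "frame", "x", "y", "z")
  for (col in need)
    if (!col %in% names(df))
      hk_stop(sprintf("missing column '%s'", col), "hk_format_error")
  if (anyDuplicated(df[, c("landmark_id", "frame")]))
    hk_stop("duplicate (landmark_id, frame) rows", "hk_duplicate_sample")
  df <- df[order(df$landmark_id, df$frame), ]
  if (!"t" %in% names(df)) df$t <- df$frame / frame_rate
  tracks <- lapply(split(df, df$landmark_id), function(d) {
    role <- unique(d$role)
    if (length(role) != 1)
      hk_stop(sprintf("track '%s' has multiple roles", d$landmark_id[1]),
              "hk_format_error")
    zi <- unique(d$zooid_index)
    landmark_track(d$landmark_id[1], role,
                   d[, c("frame", "t", "x", "y", "z")],
                   zooid_index = if (all(is.na(zi))) NA_integer_ else zi[!is.na(zi)][1])
  })
  zooids <- sum(vapply(tracks, function(tr) tr$role == "zooid_gut", logical(1)))
  colony_recording(
    colony_id = colony_id %||% meta$colony_id %||%
      sub("\\.csv$", "", basename(path)),
    tracks = unname(tracks), frame_rate = frame_rate,
    zooid_count = meta$zooid_count %||% max(1L, zooids),
    chain_length = meta$chain_length %||% NA_real_,
    zooid_length = meta$zooid_length %||% NA_real_,
    metadata = meta$metadata %||% list())
}

#' Write a colony recording to CSV
#'
#' Writes the flat CSV read back by [read_tracks()] plus a JSON metadata
#' sidecar (`<path>.meta.json`). Coordinates and times are printed with 17
#' significant digits so the round trip is bit-exact.
#'
#' @param rec A [colony_recording()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_tracks <- function(rec, path) {
  rows <- lapply(rec$tracks, function(tr) {
    s <- tr$samples
    data.frame(landmark_id = tr$landmark_id, role = tr$role,
               zooid_index = tr$zooid_index, frame = s$frame,
               t = sprintf("%.17g", s$t), x = sprintf("%.17g", s$x),
               y = sprintf("%.17g", s$y), z = sprintf("%.17g", s$z),
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(landmark_id = character(), role = character(),
               zooid_index = integer(), frame = integer(), t = character(),
               x = character(), y = character(), z = character())
  ok <- tryCatch({ write.csv(df, path, row.names = FALSE, quote = FALSE); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) hk_stop(sprintf("cannot write '%s': %s", path,
                                   conditionMessage(ok)), "hk_io_error")
  jsonlite::write_json(
    list(colony_id = rec$colony_id, frame_rate = rec$frame_rate,
         zooid_count = rec$zooid_count, chain_length = rec$chain_length,
         zooid_length = rec$zooid_length, metadata = rec$metadata),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA, null = "null",
    na = "null")
  invisible(path)
}

#' Construct an angle series
#'
#' A time series of unsigned acute angles (degrees, in \[0, 90\]) measured
#' relative to the chain axis in a given 2D view, e.g. the time-varying
#' lateral siphon angle digitized from bright-field video.
#'
#' @param label Character label.
#' @param samples Data frame with columns `t` (s, strictly increasing) and
#'   `angle` (degrees).
#' @param plane `"lateral"` or `"dorsoventral"`.
#' @return An object of class `angle_series`.
#' @export
angle_series <- function(label, samples, plane = c("lateral", "dorsoventral")) {
  plane <- match.arg(plane)
  samples <- as.data.frame(samples)[, c("t", "angle")]
  if (is.unsorted(samples$t, strictly = TRUE))
    hk_stop("t not strictly increasing", "hk_ordering_error")
  if (any(samples$angle < 0 | samples$angle > 90))
    hk_stop("angles must lie in [0, 90] degrees", "hk_range_error")
  structure(list(label = as.character(label), plane = plane, samples = samples),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series> '%s' (%s): %d samples, %g-%g deg\n", x$label,
              x$plane, nrow(x$samples), min(x$samples$angle),
              max(x$samples$angle)))
  invisible(x)
}

#' Read an angle series from a two-column table
#'
#' Format: leading comment lines `# label: <label>` and `# plane: <plane>`,
#' then a CSV with header `t,angle_deg`.
#'
#' @param path File path.
#' @return An [angle_series()].
#' @export
read_angle_series <- function(path) {
  if (!file.exists(path))
    hk_stop(sprintf("file not found: %s", path), "hk_io_error")
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(sprintf("^#\\s*%s\\s*:", key), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    trimws(sub(sprintf("^#\\s*%s\\s*:", key), "", m[1]))
  }
  df <- read.csv(text = paste(grep("^#", lines, invert = TRUE, value = TRUE),
                              collapse = "\n"))
  if (!all(c("t", "angle_deg") %in% names(df)))
    hk_stop("expected columns 't' and 'angle_deg'", "hk_format_error")
  angle_series(label = get_meta("label") %||% basename(path),
               samples = data.frame(t = df$t, angle = df$angle_deg),
               plane = get_meta("plane") %||% "lateral")
}

#' Write an angle series
#'
#' @param series An [angle_series()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_angle_series <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# label: %s", series$label),
               sprintf("# plane: %s", series$plane), "t,angle_deg"), con)
  writeLines(sprintf("%.17g,%.17g", series$samples$t, series$samples$angle), con)
  invisible(path)
}
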