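#' Screen geometry for pixel-to-degree conversion
#'
#' Readers convert raw pixel coordinates to the package's internal frame:
#' degrees of visual angle from screen center, x positive rightward, y
#' positive upward. Screen pixel coordinates have the origin at the top-left
#' corner with y increasing downward, so y is flipped.
#'
#' The conversion is the small-angle linear approximation
#' `deg = (px - center_px) / px_per_deg`, which is the standard convention in
#' eye-movement pipelines and exactly invertible.
#'
#' @param width_px,height_px Display resolution in pixels.
#' @param px_per_deg Pixels per degree of visual angle.
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry(1024, 768, px_per_deg = 34)
#' px_to_deg(c(512, 384), geom)   # screen center -> (0, 0)
#' @export
screen_geometry <- function(width_px = 1024, height_px = 768, px_per_deg = 34) {
  stopifnot(width_px > 0, height_px > 0, px_per_deg > 0)
  structure(list(width_px = width_px, height_px = height_px,
                 px_per_deg = px_per_deg),
            class = "screen_geometry")
}

#' @rdname screen_geometry
#' @param xy Length-2 `(x, y)` point, or a 2-column matrix of points.
#' @param geom A [screen_geometry()].
#' @export
px_to_deg <- function(xy, geom) {
  xy <- rbind(xy)
  cx <- geom$width_px / 2
  cy <- geom$height_px / 2
  out <- cbind((xy[, 1] - cx) / geom$px_per_deg,
               (cy - xy[, 2]) / geom$px_per_deg)  # flip y to positive-up
  if (nrow(out) == 1) c(out) else out
}

#' @rdname screen_geometry
#' @export
deg_to_px <- function(xy, geom) {
  xy <- rbind(xy)
  cx <- geom$width_px / 2
  cy <- geom$height_px / 2
  out <- cbind(xy[, 1] * geom$px_per_deg + cx,
               cy - xy[, 2] * geom$px_per_deg)
  if (nrow(out) == 1) c(out) else out
}

# parse "k=v; k=v" metadata pairs from MSG lines into a named character vector
parse_kv <- function(fields) {
  kv <- strsplit(fields, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed key=value field: ", fields[bad][1])
  stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
}

meta_from_kv <- function(kv, trial_id) {
  need <- c("participant", "direction", "condition", "cue_onset",
            "fix_x", "fix_y")
  miss <- setdiff(need, names(kv))
  if (length(miss))
    stop("trial ", trial_id, " metadata is missing field(s): ",
         paste(miss, collapse = ", "))
  fix <- c(as.numeric(kv["fix_x"]), as.numeric(kv["fix_y"]))
  trial_meta(participant = kv[["participant"]],
             trial = trial_id,
             direction = kv[["direction"]],
             condition = kv[["condition"]],
             cue_onset = as.numeric(kv[["cue_onset"]]),
             fixation_pos = fix, target_pos = -fix,
             spatial_frequency =
               if ("sf" %in% names(kv)) as.numeric(kv[["sf"]]) else NA_real_)
}

#' Read raw eye-tracker samples
#'
#' Parses a raw sample stream into a list of trials, each a list with elements
#' `meta` (a [trial_meta()]) and `trace` (a [gaze_trace()]). Two dialects are
#' supported:
#'
#' \describe{
#' \item{`"csv"`}{A UTF-8 CSV with header
#'   `trial,t,x,y,p` (the `trial` column may be omitted for a single-trial
#'   file). `x` and `y` are already in degrees from screen center, y positive
#'   up; missing samples are empty fields or `NA`. Metadata travel in a
#'   companion CSV (see `meta_file`) with columns
#'   `trial,participant,direction,condition,cue_onset,fix_x,fix_y[,sf]`.}
#' \item{`"asc_like"`}{A documented subset of the EyeLink ASC text format.
#'   Sample lines are `<t> <x> <y> <p>` (whitespace-separated; `.` marks a
#'   missing coordinate), with positions in screen pixels (y positive down),
#'   converted to degrees via `geom`. Message lines delimit trials and carry
#'   metadata: `MSG <t> TRIALID <n>`, `MSG <t> VAR key=value`, and
#'   `MSG <t> TRIAL_END`. Pupil area 0 marks blinks.}
#' }
#'
#' @param source Path to the file to read.
#' @param dialect `"csv"` or `"asc_like"`.
#' @param geom A [screen_geometry()]; required for `"asc_like"`.
#' @param meta_file For `"csv"`: path to the trial-metadata CSV. If `NULL`,
#'   trials get placeholder metadata (participant `"unknown"`, rightward
#'   saccade from (-8.5, 0), cue at 0 ms).
#' @return A list of trials; each trial is `list(meta =, trace =)`.
#' @export
read_samples <- function(source, dialect = c("csv", "asc_like"), geom = NULL,
                         meta_file = NULL) {
  dialect <- match.arg(dialect)
  switch(dialect,
         csv = read_samples_csv(source, meta_file),
         asc_like = read_samples_asc(source, geom))
}

placeholder_meta <- function(trial_id) {
  trial_meta(participant = "unknown", trial = trial_id, direction = "right",
             condition = "part1", cue_onset = 0,
             fixation_pos = c(-8.5, 0), target_pos = c(8.5, 0))
}

read_samples_csv <- function(source, meta_file = NULL) {
  df <- utils::read.csv(source)
  need <- c("t", "x", "y", "p")
  if (!all(need %in% names(df)))
    stop("csv sample file must have columns t,x,y,p (optionally trial): ",
         source)
  for (col in need)
    if (!is.numeric(df[[col]]) && !all(is.na(df[[col]])))
      stop("non-numeric values in column '", col, "' of ", source)
  if (!"trial" %in% names(df)) df$trial <- 1L
  metas <- NULL
  if (!is.null(meta_file)) {
    md <- utils::read.csv(meta_file, colClasses = c(participant = "character"))
    metas <- lapply(seq_len(nrow(md)), function(i) {
      row <- md[i, ]
      trial_meta(participant = row$participant, trial = row$trial,
                 direction = row$direction, condition = row$condition,
                 cue_onset = row$cue_onset,
                 fixation_pos = c(row$fix_x, row$fix_y),
                 target_pos = c(-row$fix_x, -row$fix_y),
                 spatial_frequency =
                   if ("sf" %in% names(md)) row$sf else NA_real_)
    })
    names(metas) <- as.character(md$trial)
  }
  lapply(split(df, df$trial), function(d) {
    id <- d$trial[1]
    meta <- if (!is.null(metas)) {
      m <- metas[[as.character(id)]]
      if (is.null(m)) stop("no metadata for trial ", id)
      m
    } else placeholder_meta(id)
    list(meta = meta, trace = gaze_trace(d$t, d$x, d$y, d$p))
  })
}

read_samples_asc <- function(source, geom) {
  if (is.null(geom))
    stop("asc_like dialect needs a screen_geometry for pixel-to-degree conversion")
  lines <- readLines(source)
  trials <- list()
  cur <- NULL   # accumulator for the open trial
  num_or_na <- function(s) ifelse(s == ".", NA_real_, suppressWarnings(as.numeric(s)))
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    fields <- strsplit(line, "[ \t]+")[[1]]
    if (fields[1] == "MSG") {
      if (length(fields) < 3)
        stop("malformed MSG line ", i, " in ", source, ": ", line)
      kind <- fields[3]
      if (kind == "TRIALID") {
        if (!is.null(cur)) stop("line ", i, ": TRIALID before previous TRIAL_END")
        cur <- list(id = as.integer(fields[4]), kv = character(),
                    t = numeric(), x = numeric(), y = numeric(), p = numeric())
      } else if (kind == "VAR") {
        if (is.null(cur)) stop("line ", i, ": VAR outside a trial")
        cur$kv <- c(cur$kv, parse_kv(fields[-(1:3)]))
      } else if (kind == "TRIAL_END") {
        if (is.null(cur)) stop("line ", i, ": TRIAL_END outside a trial")
        xy <- px_to_deg(cbind(cur$x, cur$y), geom)
        trials[[length(trials) + 1L]] <-
          list(meta = meta_from_kv(cur$kv, cur$id),
               trace = gaze_trace(cur$t - cur$t[1], xy[, 1], xy[, 2], cur$p))
        cur <- NULL
      }  # other MSG kinds are ignored, as EyeLink files carry many
    } else {
      ok <- length(fields) == 4 &&
        !is.na(suppressWarnings(as.numeric(fields[1])))
      if (!ok)
        stop("malformed sample line ", i, " in ", source, ": ", line)
      if (is.null(cur)) next  # samples outside trials are discarded
      cur$t <- c(cur$t, as.numeric(fields[1]))
      cur$x <- c(cur$x, num_or_na(fields[2]))
      cur$y <- c(cur$y, num_or_na(fields[3]))
      cur$p <- c(cur$p, num_or_na(fields[4]))
    }
  }
  if (!is.null(cur)) stop("unterminated trial ", cur$id, " at end of ", source)
  trials
}

#' Write samples to the native CSV dialect
#'
#' Writes trials to a samples CSV (`trial,t,x,y,p`, degrees from center, y
#' positive up, missing = `NA`) and, optionally, the companion metadata CSV.
#' `read_samples(dialect = "csv")` on the outputs reproduces the input
#' exactly.
#'
#' @param trials A list of trials as returned by [read_samples()].
#' @param file Output path for the samples CSV.
#' @param meta_file Optional output path for the metadata CSV.
#' @return `file`, invisibly.
#' @export
write_samples <- function(trials, file, meta_file = NULL) {
  dfs <- lapply(trials, function(tr)
    cbind(trial = tr$meta$trial, as.data.frame(tr$trace)))
  df <- do.call(rbind, dfs)
  if (is.null(df)) df <- data.frame(trial = integer(), t = integer(),
                                    x = numeric(), y = numeric(), p = numeric())
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE, na = "NA")
  if (!is.null(meta_file)) {
    md <- do.call(rbind, lapply(trials, function(tr) {
      m <- tr$meta
      data.frame(trial = m$trial, participant = m$participant,
                 direction = m$direction, condition = m$condition,
                 cue_onset = m$cue_onset,
                 fix_x = m$fixation_pos[1], fix_y = m$fixation_pos[2],
                 sf = m$spatial_frequency)
    }))
    utils::write.csv(md, meta_file, row.names = FALSE, quote = FALSE, na = "NA")
  }
  invisible(file)
}

#' Write epoched pupil traces to a long-format CSV
#'
#' One row per epoch sample with columns
#' `participant,trial,condition,direction,t_ms,pupil` (`pupil` is
#' baseline-normalized; masked samples are `NA`). All epochs must share the
#' same time grid.
#'
#' @param epochs A list of [epoched_pupil] objects.
#' @param file Output path.
#' @return `file`, invisibly.
#' @seealso [read_epochs()]
#' @export
write_epochs <- function(epochs, file) {
  if (length(epochs)) {
    grids <- lapply(epochs, function(e) e$time)
    if (!all(vapply(grids, identical, TRUE, grids[[1]])))
      stop("epochs have mixed time grids; refusing to write")
  }
  dfs <- lapply(epochs, function(e)
    data.frame(participant = e$meta$participant, trial = e$meta$trial,
               condition = e$meta$condition, direction = e$meta$direction,
               t_ms = e$time, pupil = e$value))
  df <- do.call(rbind, dfs)
  if (is.null(df))
    df <- data.frame(participant = character(), trial = integer(),
                     condition = character(), direction = character(),
                     t_ms = integer(), pupil = numeric())
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(file)
}

#' Read an epochs CSV written by [write_epochs()]
#'
#' @param file Path to the epochs CSV.
#' @return A long-format data frame with columns
#'   `participant,trial,condition,direction,t_ms,pupil`.
#' @export
read_epochs <- function(file) {
  utils::read.csv(file, colClasses = c(participant = "character"))
}
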