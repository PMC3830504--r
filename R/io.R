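#' Read an EOG recording from delimited text or EDF
#'
#' Text input (`csv`/`tsv`) must have a header row with one column per
#' channel; samples are assumed to be in microvolts and the sampling rate
#' must be supplied via `fs`. EDF input takes the rate and physical scaling
#' from the file header. The channel map either names the two bipolar
#' channels (`eog_h`, `eog_v`) or the four monopolar electrodes (`right`,
#' `left`, `up`, `down`), which are combined with [derive_bipolar()].
#'
#' @param path Path to the input file.
#' @param format One of `"auto"`, `"csv"`, `"tsv"`, `"edf"`. `"auto"` picks
#'   by file extension.
#' @param fs Sampling rate in Hz; mandatory for text input, ignored for EDF.
#' @param channel_map Named character vector mapping the roles `eog_h`/`eog_v`
#'   (or `right`/`left`/`up`/`down`) to column names or EDF signal labels.
#'   Defaults to `c(eog_h = "eog_h", eog_v = "eog_v")`.
#'
#' @return An [eog_recording()].
#' @export
read_recording <- function(path, format = c("auto", "csv", "tsv", "edf"),
                           fs = NULL, channel_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", edf = "edf", "tsv")
  }
  if (is.null(channel_map)) {
    channel_map <- c(eog_h = "eog_h", eog_v = "eog_v")
  }
  monopolar <- all(c("right", "left", "up", "down") %in% names(channel_map))
  if (!monopolar && !all(c("eog_h", "eog_v") %in% names(channel_map))) {
    stop("channel_map must name either eog_h/eog_v or right/left/up/down",
         call. = FALSE)
  }

  if (format == "edf") {
    edf <- read_edf(path)
    get_chan <- function(role) {
      label <- channel_map[[role]]
      idx <- match(label, edf$labels)
      if (is.na(idx)) {
        stop("EDF file has no channel labelled '", label, "' (available: ",
             paste(edf$labels, collapse = ", "), ")", call. = FALSE)
      }
      idx
    }
    roles <- if (monopolar) c("right", "left", "up", "down")
             else c("eog_h", "eog_v")
    idx <- vapply(roles, get_chan, integer(1))
    rates <- edf$fs[idx]
    if (length(unique(rates)) != 1L) {
      stop("selected EDF channels have unequal sampling rates (",
           paste(rates, collapse = ", "), " Hz); resampling is not supported",
           call. = FALSE)
    }
    sig <- edf$signals[idx]
    fs <- rates[[1]]
    if (monopolar) {
      return(derive_bipolar(sig[[1]], sig[[2]], sig[[3]], sig[[4]], fs = fs,
                            meta = list(source = basename(path))))
    }
    return(eog_recording(sig[[1]], sig[[2]], fs = fs,
                         meta = list(source = basename(path))))
  }

  if (is.null(fs)) {
    stop("a sampling rate (fs) is mandatory for text input", call. = FALSE)
  }
  sep <- if (format == "csv") "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE)
  get_col <- function(role) {
    nm <- channel_map[[role]]
    if (!nm %in% names(tab)) {
      stop("column '", nm, "' (", role, ") not found in ", path,
           " (available: ", paste(names(tab), collapse = ", "), ")",
           call. = FALSE)
    }
    v <- tab[[nm]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      stop("channel '", nm, "' contains non-finite or non-numeric samples",
           call. = FALSE)
    }
    as.numeric(v)
  }
  if (monopolar) {
    derive_bipolar(get_col("right"), get_col("left"), get_col("up"),
                   get_col("down"), fs = fs,
                   meta = list(source = basename(path)))
  } else {
    eog_recording(get_col("eog_h"), get_col("eog_v"), fs = fs,
                  meta = list(source = basename(path)))
  }
}

#' Write an EOG recording to delimited text or EDF
#'
#' @param rec An [eog_recording()].
#' @param path Output path.
#' @param format `"tsv"`, `"csv"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("tsv", "csv", "edf")) {
  stopifnot(inherits(rec, "eog_recording"))
  format <- match.arg(format)
  if (format == "edf") {
    write_edf(list(eog_h = rec$eog_h, eog_v = rec$eog_v), fs = rec$fs,
              path = path)
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else "\t"
  tab <- data.frame(eog_h = signif(rec$eog_h, 9),
                    eog_v = signif(rec$eog_v, 9))
  utils::write.table(tab, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Columns always present in an event table, in output order.
event_table_columns <- function() {
  c("label", "onset_s", "offset_s", "peak_s", "duration_s",
    "peak_velocity_uv_s", "direction_sign")
}

optional_measure_columns <- function() {
  c("amplitude_uv", "closing_time_s", "opening_time_s",
    "acceleration_uv_s2", "deceleration_uv_s2", "peak_velocity_deg_s")
}

#' Write a classified event table to TSV
#'
#' Events are written one per row, sorted by onset, with times in seconds and
#' floats at 6 significant digits. Optional kinematic measure columns are
#' included when present.
#'
#' @param events An `eog_events` data frame (see [classify_events()]); its
#'   `fs` attribute converts sample indices to seconds.
#' @param path Output path.
#' @param fs Sampling rate in Hz; only needed if `events` lacks an `fs`
#'   attribute.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, fs = NULL) {
  fs <- fs %||% attr(events, "fs")
  if (is.null(fs)) stop("fs is required to express events in seconds",
                        call. = FALSE)
  ev <- as.data.frame(events)
  if (nrow(ev) > 0) {
    bad <- !ev$label %in% event_classes()
    if (any(bad)) stop("unknown event label(s): ",
                       paste(unique(ev$label[bad]), collapse = ", "),
                       call. = FALSE)
    ev <- ev[order(ev$onset), , drop = FALSE]
  }
  out <- data.frame(
    label = character(nrow(ev)), onset_s = numeric(nrow(ev)),
    offset_s = numeric(nrow(ev)), peak_s = numeric(nrow(ev)),
    duration_s = numeric(nrow(ev)), peak_velocity_uv_s = numeric(nrow(ev)),
    direction_sign = integer(nrow(ev)))
  if (nrow(ev) > 0) {
    out$label <- ev$label
    out$onset_s <- (ev$onset - 1) / fs
    out$offset_s <- (ev$offset - 1) / fs
    out$peak_s <- (ev$peak - 1) / fs
    out$duration_s <- if ("duration_s" %in% names(ev)) ev$duration_s
                      else (ev$offset - ev$onset) / fs
    out$peak_velocity_uv_s <-
      if ("peak_velocity_uv_s" %in% names(ev)) ev$peak_velocity_uv_s else NA_real_
    out$direction_sign <-
      if ("direction_sign" %in% names(ev)) ev$direction_sign else NA_integer_
  }
  for (m in optional_measure_columns()) {
    if (m %in% names(ev) && any(!is.na(ev[[m]]))) out[[m]] <- ev[[m]]
  }
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event table written by [write_events()]
#'
#' @param path Path to the TSV event table.
#' @param fs Sampling rate in Hz used to reconstruct sample indices.
#' @return An `eog_events` data frame with sample-index columns `onset`,
#'   `offset`, `peak` alongside the per-event measures.
#' @export
read_events <- function(path, fs) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  ev <- tab
  ev$onset <- as.integer(round(tab$onset_s * fs)) + 1L
  ev$offset <- as.integer(round(tab$offset_s * fs)) + 1L
  ev$peak <- as.integer(round(tab$peak_s * fs)) + 1L
  ev$label <- as.character(tab$label)
  attr(ev, "fs") <- fs
  class(ev) <- c("eog_events", "data.frame")
  ev
}

`%||%` <- function(a, b) if (is.null(a)) b else a
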