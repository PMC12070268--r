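# File interfaces: an epochs container (float64 binary + JSON sidecar),
# behavioural TSV tables, a BrainVision reader, and TSV/JSON result exports.

#' Write / read an epochs container
#'
#' Stores the voltage array as little-endian float64 binary (`<stem>.dat`,
#' sample-fastest order) next to a JSON sidecar (`<stem>.json`) with the
#' dimensions, channel table, sampling rate, time axis and condition
#' metadata.
#'
#' @param x An `eeg_epochs` object.
#' @param stem Path stem (without extension).
#' @return `write_epochs` returns `stem` invisibly; `read_epochs` returns the
#'   `eeg_epochs` object.
#' @export
write_epochs <- function(x, stem) {
  stopifnot(inherits(x, "eeg_epochs"))
  meta <- list(
    dims = dim(x$data), sfreq = x$sfreq, times = x$times,
    channels = x$channels, subject = x$subject, group = x$group,
    condition = x$condition, dtype = "float64-le", order = "sample-channel-trial"
  )
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(aperm(x$data, c(3, 2, 1))), con, size = 8, endian = "little")
  invisible(stem)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dims)
  con <- file(paste0(stem, ".dat"), "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n, size = 8, endian = "little")
  arr <- aperm(array(v, dim = rev(meta$dims)), c(3, 2, 1))
  eeg_epochs(arr, meta$sfreq, meta$times, as_tibble(meta$channels),
    subject = meta$subject, group = meta$group, condition = meta$condition
  )
}

#' Write / read a behavioural table as TSV
#'
#' Fixed column layout: `subject`, `group`, `overlap`, `hit_rate`, `rt_ms`,
#' `fa_rate` (additional columns are preserved).
#'
#' @param x A behavioural table.
#' @param path TSV path.
#' @return `write_behavior` returns `path` invisibly; `read_behavior` returns
#'   a tibble.
#' @export
write_behavior <- function(x, path) {
  need <- c("subject", "group", "overlap", "hit_rate", "rt_ms", "fa_rate")
  if (!all(need %in% names(x))) abort("behavioural table is missing required columns.")
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  class(out) <- c("behavioral_table", class(out))
  out
}

# minimal INI-section parser for BrainVision headers
parse_vhdr_ini <- function(lines) {
  lines <- lines[!grepl("^\\s*(;|$)", lines)]
  sec <- NULL
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      sec <- gsub("^\\[|\\]\\s*$", "", ln)
      out[[sec]] <- character(0)
    } else if (!is.null(sec) && grepl("=", ln, fixed = TRUE)) {
      kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
      out[[sec]][trimws(kv[1])] <- trimws(kv[2])
    }
  }
  out
}

#' Read a BrainVision recording
#'
#' Minimal reader for continuous BrainVision files (`.vhdr` header, binary
#' `.eeg` data in multiplexed IEEE float32 or signed int16, optional `.vmrk`
#' markers). Channel resolutions are applied, yielding microvolts.
#'
#' @param vhdr Path to the `.vhdr` header.
#' @return A list of class `eeg_raw`: `data` (channels x samples matrix,
#'   microvolts), `sfreq`, `channels` (tibble with `channel`), `markers`
#'   (tibble `type`, `description`, `position` or NULL).
#' @export
read_brainvision <- function(vhdr) {
  ini <- parse_vhdr_ini(readLines(vhdr, warn = FALSE))
  ci <- ini[["Common Infos"]]
  if (is.null(ci)) abort("not a BrainVision header (no [Common Infos] section).")
  if (toupper(ci["DataFormat"]) != "BINARY") abort("only BINARY BrainVision data are supported.")
  if (!is.na(ci["DataOrientation"]) && toupper(ci["DataOrientation"]) != "MULTIPLEXED") {
    abort("only MULTIPLEXED orientation is supported.")
  }
  nch <- as.integer(ci["NumberOfChannels"])
  sfreq <- 1e6 / as.numeric(ci["SamplingInterval"])
  fmt <- toupper(ini[["Binary Infos"]]["BinaryFormat"])

  chi <- ini[["Channel Infos"]]
  labels <- character(nch)
  res <- rep(1, nch)
  for (k in seq_len(nch)) {
    parts <- strsplit(chi[[sprintf("Ch%d", k)]], ",")[[1]]
    labels[k] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) res[k] <- as.numeric(parts[3])
  }

  eeg_path <- file.path(dirname(vhdr), ci["DataFile"])
  sz <- file.info(eeg_path)$size
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    v <- readBin(con, "double", n = sz / 4, size = 4, endian = "little")
  } else if (fmt == "INT_16") {
    v <- readBin(con, "integer", n = sz / 2, size = 2, signed = TRUE, endian = "little")
  } else {
    abort(sprintf("unsupported BinaryFormat '%s'.", fmt))
  }
  ns <- length(v) %/% nch
  data <- matrix(v[seq_len(ns * nch)], nrow = nch) * res
  rownames(data) <- labels

  markers <- NULL
  mf <- ci["MarkerFile"]
  if (!is.na(mf) && file.exists(file.path(dirname(vhdr), mf))) {
    mk <- parse_vhdr_ini(readLines(file.path(dirname(vhdr), mf), warn = FALSE))[["Marker Infos"]]
    if (!is.null(mk)) {
      parts <- strsplit(unname(mk), ",")
      markers <- tibble(
        type = vapply(parts, `[`, "", 1),
        description = vapply(parts, `[`, "", 2),
        position = as.integer(vapply(parts, `[`, "", 3))
      )
    }
  }
  structure(
    list(
      data = data, sfreq = sfreq,
      channels = tibble(channel = labels), markers = markers
    ),
    class = "eeg_raw"
  )
}

#' Epoch a continuous recording around stimulus events
#'
#' Cuts fixed windows around marker sample positions. Events whose window
#' exceeds the recording are dropped.
#'
#' @param raw An `eeg_raw` object (see [read_brainvision()]).
#' @param positions Integer sample indices of the stimulus events (1-based).
#' @param window Epoch window in seconds around each event (default
#'   `c(-2, 2)`).
#' @param channels Optional [make_sensor_array()] tibble with positions; by
#'   default unit positions are improvised (interpolation then unavailable).
#' @return An `eeg_epochs` object.
#' @export
epoch_raw <- function(raw, positions, window = c(-2, 2), channels = NULL) {
  check_window(window)
  pre <- round(window[1] * raw$sfreq)
  post <- round(window[2] * raw$sfreq)
  ns <- ncol(raw$data)
  keep <- positions + pre >= 1 & positions + post <= ns
  positions <- positions[keep]
  if (!length(positions)) abort("no event window fits inside the recording.")
  times <- (pre:post) / raw$sfreq
  nch <- nrow(raw$data)
  arr <- array(NA_real_, dim = c(length(positions), nch, length(times)))
  for (i in seq_along(positions)) {
    arr[i, , ] <- raw$data[, (positions[i] + pre):(positions[i] + post)]
  }
  if (is.null(channels)) {
    channels <- tibble(
      channel = raw$channels$channel,
      x = 0, y = 0, z = 1
    )
  }
  eeg_epochs(arr, raw$sfreq, times, channels)
}

#' Export a cluster set to JSON and TSV
#'
#' Writes the per-cluster summary (members, sign, T_sum, p) as JSON and a
#' flat TSV summary.
#'
#' @param x A `cluster_set`.
#' @param stem Path stem; writes `<stem>.json` and `<stem>.tsv`.
#' @return `stem`, invisibly.
#' @export
write_cluster_set <- function(x, stem) {
  lst <- lapply(seq_len(nrow(x)), function(i) {
    list(
      cluster = x$cluster[i], sign = x$sign[i], members = x$members[[i]],
      t_sum = x$t_sum[i], p = if ("p" %in% names(x)) x$p[i] else NULL
    )
  })
  jsonlite::write_json(
    list(
      clusters = lst, threshold = attr(x, "threshold"),
      R = attr(x, "R"), alpha = attr(x, "alpha"), design = attr(x, "design")
    ),
    paste0(stem, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  flat <- x[, setdiff(names(x), "members")]
  readr::write_tsv(as_tibble(flat), paste0(stem, ".tsv"))
  invisible(stem)
}
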