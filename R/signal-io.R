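#' Multichannel sampled signal container
#'
#' The carrier object for every processing stage: a channels-by-time matrix of
#' voltages in microvolts, with its sampling rate and channel labels.
#' Abdominal records use four channels (A1..A4) at 500 Hz; a direct
#' scalp-electrode fetal ECG is a single channel at 1 kHz.
#'
#' @param samples numeric matrix, channels in rows, samples in columns; a
#'   plain vector is treated as a single channel.
#' @param rate sampling frequency in Hz (positive).
#' @param labels character vector of unique channel names; defaults to
#'   `A1..An`.
#' @param origin dataset tag, one of `"B1"`, `"B2"`, `"synthetic"`.
#' @return an object of class `mcsignal`.
#' @export
mcsignal <- function(samples, rate, labels = NULL, origin = "synthetic") {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("`samples` must be a numeric matrix (channels x time)")
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    stop("`rate` must be a single positive number")
  nch <- nrow(samples)
  if (is.null(labels)) labels <- paste0("A", seq_len(nch))
  if (length(labels) != nch) stop("one label per channel required")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  origin <- match.arg(origin, c("B1", "B2", "synthetic"))
  rownames(samples) <- labels
  structure(list(samples = samples, rate = rate, labels = labels,
                 origin = origin),
            class = "mcsignal")
}

#' @export
print.mcsignal <- function(x, ...) {
  cat(sprintf("<mcsignal> %d channel(s) x %d samples @ %g Hz (%.1f s), origin %s\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate, x$origin))
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.mcsignal <- function(x) ncol(x$samples)

n_channels <- function(x) nrow(x$samples)

# Extract one channel as a bare numeric vector.
channel <- function(x, i) {
  stopifnot(inherits(x, "mcsignal"))
  as.numeric(x$samples[i, ])
}

#' R-wave beat annotations
#'
#' Ordered R-wave fiducial positions as 1-based sample indices, optionally
#' with a parallel 0/1 reliability flag (fetal references only: 0 marks a
#' beat whose position could not be verified because interference was too
#' high and which should be omitted from downstream statistics).
#'
#' @param locations strictly increasing 1-based sample indices.
#' @param flags optional 0/1 vector, same length as `locations`.
#' @param subject `"maternal"` or `"fetal"`.
#' @param rate sampling frequency (Hz) of the indexed signal.
#' @return an object of class `beat_ann`.
#' @export
beat_ann <- function(locations, flags = NULL, subject = "fetal", rate = 500) {
  locations <- as.numeric(locations)
  if (length(locations) && any(diff(locations) <= 0))
    stop("annotation locations must be strictly increasing")
  if (length(locations) && any(locations < 1))
    stop("annotation locations must be positive sample numbers")
  if (!is.null(flags)) {
    if (length(flags) != length(locations))
      stop("flags must parallel locations")
    if (length(flags) && !all(flags %in% c(0, 1)))
      stop("reliability flags must be 0 or 1")
    flags <- as.integer(flags)
  }
  subject <- match.arg(subject, c("maternal", "fetal"))
  structure(list(locations = locations, flags = flags, subject = subject,
                 rate = rate),
            class = "beat_ann")
}

#' @export
print.beat_ann <- function(x, ...) {
  cat(sprintf("<beat_ann> %d %s beats @ %g Hz", length(x$locations),
              x$subject, x$rate))
  if (!is.null(x$flags))
    cat(sprintf(", %d flagged unreliable", sum(x$flags == 0)))
  cat("\n")
  invisible(x)
}

#' @export
length.beat_ann <- function(x) length(x$locations)

#' Read a plain-text signal matrix
#'
#' Dataset signal files (`*_abSignals_X.txt`, `*_dFECG_X.txt`) are
#' whitespace-delimited numeric columns, one row per sample and one column
#' per channel. Values are loaded verbatim; no filtering or scaling is
#' applied.
#'
#' @param path file to read.
#' @param rate sampling frequency in Hz of the stored signal.
#' @param labels channel names, one per column; defaults to `A1..An`.
#' @param origin dataset tag passed to [mcsignal()].
#' @return an [mcsignal()].
#' @export
read_signal_text <- function(path, rate, labels = NULL, origin = "synthetic") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty signal file: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(toks)
  if (length(unique(ncols)) != 1)
    stop(sprintf("ragged rows in %s: line %d has %d columns, expected %d",
                 path, which(ncols != ncols[1])[1], ncols[ncols != ncols[1]][1],
                 ncols[1]))
  vals <- suppressWarnings(as.numeric(unlist(toks, use.names = FALSE)))
  if (anyNA(vals)) {
    bad_row <- ceiling(which(is.na(vals))[1] / ncols[1])
    stop(sprintf("non-numeric token in %s at line %d", path, bad_row))
  }
  m <- matrix(vals, ncol = ncols[1], byrow = TRUE)
  if (!is.null(labels) && length(labels) != ncol(m))
    stop(sprintf("%s has %d columns but %d labels were given",
                 path, ncol(m), length(labels)))
  mcsignal(t(m), rate = rate, labels = labels, origin = origin)
}

#' Write a signal matrix as plain text
#'
#' Inverse of [read_signal_text()]: one row per sample, one column per
#' channel, values formatted with 6 significant digits so a read/write
#' round trip reproduces the file token for token.
#'
#' @param x an [mcsignal()].
#' @param path output file.
#' @param digits significant digits used for formatting.
#' @return `path`, invisibly.
#' @export
write_signal_text <- function(x, path, digits = 6) {
  stopifnot(inherits(x, "mcsignal"))
  m <- t(x$samples)
  txt <- apply(m, 1, function(row)
    paste(formatC(row, digits = digits, format = "g"), collapse = "\t"))
  writeLines(txt, path)
  invisible(path)
}

#' Read an R-wave annotation file
#'
#' One beat per line, as a 1-based sample number. Fetal reference files may
#' carry a second column with the 0/1 reliability flag; single-column fetal
#' files get flags defaulting to 1.
#'
#' @param path file to read.
#' @param subject `"maternal"` or `"fetal"`.
#' @param rate sampling frequency (Hz) of the indexed signal.
#' @param one_based logical; set `FALSE` for files that index samples from 0
#'   (indices are shifted up by one on read).
#' @return a [beat_ann()].
#' @export
read_annotations <- function(path, subject = "fetal", rate = 500,
                             one_based = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(beat_ann(numeric(0), subject = subject, rate = rate))
  toks <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(toks)
  if (!all(ncols %in% c(1, 2)))
    stop("annotation files have one or two columns per line: ", path)
  locs <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", 1)))
  if (anyNA(locs))
    stop(sprintf("non-numeric annotation index in %s at line %d",
                 path, which(is.na(locs))[1]))
  if (!one_based) locs <- locs + 1
  flags <- NULL
  if (all(ncols == 2)) {
    flags <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", 2)))
    if (anyNA(flags) || !all(flags %in% c(0, 1)))
      stop("reliability flags must be 0 or 1: ", path)
  } else if (any(ncols == 2)) {
    stop("mixed one- and two-column annotation lines: ", path)
  } else if (subject == "fetal") {
    flags <- rep(1L, length(locs))
  }
  beat_ann(locs, flags = flags, subject = subject, rate = rate)
}

#' Write an R-wave annotation file
#'
#' Inverse of [read_annotations()]; indices are written as 1-based integers,
#' with the reliability flag as a second column when present.
#'
#' @param ann a [beat_ann()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "beat_ann"))
  locs <- format(round(ann$locations), scientific = FALSE, trim = TRUE)
  txt <- if (is.null(ann$flags)) locs else paste(locs, ann$flags)
  writeLines(txt, path)
  invisible(path)
}

#' Per-record bundle of signals and annotations
#'
#' Groups everything belonging to one record: the raw (pre-filtered)
#' abdominal signal, its MECG-suppressed twin, an optional direct fetal ECG,
#' and the maternal and fetal R-wave annotations. Lengths and rates are
#' cross-validated: every annotation index must fall inside the signal it
#' indexes.
#'
#' @param abdominal_raw,abdominal_fecg [mcsignal()] objects of equal shape
#'   (`abdominal_fecg` may be `NULL` before suppression has been run).
#' @param direct_fecg optional single-channel [mcsignal()] (labour records).
#' @param maternal_r,fetal_r [beat_ann()] objects at the abdominal rate.
#' @param meta list with at least `record` and `dataset` (`B1`, `B2` or
#'   `synthetic`); `gestational_age` (weeks) optional.
#' @return an object of class `record_bundle`.
#' @export
record_bundle <- function(abdominal_raw, abdominal_fecg = NULL,
                          direct_fecg = NULL, maternal_r = NULL,
                          fetal_r = NULL, meta = list()) {
  stopifnot(inherits(abdominal_raw, "mcsignal"))
  if (is.null(meta$dataset)) meta$dataset <- abdominal_raw$origin
  if (!meta$dataset %in% c("B1", "B2", "synthetic"))
    stop("meta$dataset must be B1, B2 or synthetic")
  if (!is.null(abdominal_fecg) &&
      !identical(dim(abdominal_fecg$samples), dim(abdominal_raw$samples)))
    stop("abdominal_fecg must have the same shape as abdominal_raw")
  nx <- length(abdominal_raw)
  for (ann in list(maternal_r, fetal_r)) {
    if (!is.null(ann) && length(ann$locations) &&
        max(ann$locations) > nx)
      stop("annotation index beyond abdominal signal end")
  }
  if (!is.null(direct_fecg)) stopifnot(inherits(direct_fecg, "mcsignal"))
  structure(list(abdominal_raw = abdominal_raw,
                 abdominal_fecg = abdominal_fecg,
                 direct_fecg = direct_fecg,
                 maternal_r = maternal_r, fetal_r = fetal_r, meta = meta),
            class = "record_bundle")
}

#' @export
print.record_bundle <- function(x, ...) {
  cat(sprintf("<record_bundle> %s (%s)\n",
              x$meta$record %||% "?", x$meta$dataset))
  print(x$abdominal_raw)
  if (!is.null(x$direct_fecg)) {
    cat("  direct FECG: "); print(x$direct_fecg)
  }
  if (!is.null(x$maternal_r)) { cat("  "); print(x$maternal_r) }
  if (!is.null(x$fetal_r)) { cat("  "); print(x$fetal_r) }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a record bundle from a directory
#'
#' Expects the dataset's text layout: `<id>_abSignals.txt` (4 columns,
#' 500 Hz), `<id>_Maternal_R.txt`, `<id>_Fetal_R.txt` (two columns:
#' index and reliability flag) and, for labour records, `<id>_dFECG.txt`
#' (one column, 1 kHz). A missing direct channel is not an error (pregnancy
#' records have none). An optional `<id>_FECG.txt` holds the
#' MECG-suppressed abdominal channels.
#'
#' @param directory directory containing the record files.
#' @param record_id file-name prefix, e.g. `"B2_Labour_01"`.
#' @param rate_abd,rate_direct sampling frequencies in Hz.
#' @return a [record_bundle()].
#' @export
load_record_bundle <- function(directory, record_id,
                               rate_abd = 500, rate_direct = 1000) {
  pth <- function(suffix) file.path(directory, paste0(record_id, suffix))
  need <- c("_abSignals.txt", "_Maternal_R.txt", "_Fetal_R.txt")
  missing <- need[!file.exists(vapply(need, pth, ""))]
  if (length(missing))
    stop("missing record files for ", record_id, ": ",
         paste(paste0(record_id, missing), collapse = ", "))
  dataset <- if (grepl("^B1", record_id)) "B1"
             else if (grepl("^B2", record_id)) "B2" else "synthetic"
  abd <- read_signal_text(pth("_abSignals.txt"), rate = rate_abd,
                          origin = dataset)
  fecg <- NULL
  if (file.exists(pth("_FECG.txt")))
    fecg <- read_signal_text(pth("_FECG.txt"), rate = rate_abd,
                             origin = dataset)
  direct <- NULL
  if (file.exists(pth("_dFECG.txt")))
    direct <- read_signal_text(pth("_dFECG.txt"), rate = rate_direct,
                               labels = "D", origin = dataset)
  m <- read_annotations(pth("_Maternal_R.txt"), subject = "maternal",
                        rate = rate_abd)
  f <- read_annotations(pth("_Fetal_R.txt"), subject = "fetal",
                        rate = rate_abd)
  record_bundle(abd, abdominal_fecg = fecg, direct_fecg = direct,
                maternal_r = m, fetal_r = f,
                meta = list(record = record_id, dataset = dataset))
}

#' Write a record bundle to a directory in the dataset text layout
#'
#' @param bundle a [record_bundle()].
#' @param directory output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_record_bundle <- function(bundle, directory) {
  stopifnot(inherits(bundle, "record_bundle"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  id <- bundle$meta$record %||% "record"
  pth <- function(suffix) file.path(directory, paste0(id, suffix))
  write_signal_text(bundle$abdominal_raw, pth("_abSignals.txt"))
  if (!is.null(bundle$abdominal_fecg))
    write_signal_text(bundle$abdominal_fecg, pth("_FECG.txt"))
  if (!is.null(bundle$direct_fecg))
    write_signal_text(bundle$direct_fecg, pth("_dFECG.txt"))
  if (!is.null(bundle$maternal_r))
    write_annotations(bundle$maternal_r, pth("_Maternal_R.txt"))
  if (!is.null(bundle$fetal_r))
    write_annotations(bundle$fetal_r, pth("_Fetal_R.txt"))
  invisible(directory)
}
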