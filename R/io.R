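#' Read a multichannel recording
#'
#' Delimited text (one channel per row, optional label column) or EDF
#' (European Data Format).  `format = "auto"` decides by file extension.
#'
#' @param path file path.
#' @param format `"auto"`, `"edf"` or `"delimited"`.
#' @param fs sampling rate in Hz for delimited input (EDF carries its own).
#' @param sep field separator for delimited input.
#' @param labels optional channel labels overriding those in the file.
#' @return A [Recording-class].
#' @export
readRecording <- function(path, format = c("auto", "edf", "delimited"),
                          fs = 256, sep = "\t", labels = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "delimited"
  if (format == "edf") return(readEdf(path))
  if (file.size(path) == 0)
    stop("parse error: ", path, " is empty", call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- strsplit(lines, sep, fixed = TRUE)
  firstNum <- suppressWarnings(as.numeric(rows[[1]][1]))
  hasLabels <- is.na(firstNum)
  parsed <- lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    vals <- suppressWarnings(as.numeric(if (hasLabels) r[-1] else r))
    if (anyNA(vals))
      stop("parse error in ", path, " at record ", i, call. = FALSE)
    vals
  })
  if (length(unique(lengths(parsed))) != 1)
    stop("parse error: ragged rows in ", path, call. = FALSE)
  X <- do.call(rbind, parsed)
  lab <- labels %||%
    (if (hasLabels) vapply(rows, `[`, "", 1)
     else defaultChannelLabels(nrow(X)))
  new("Recording", X = X, fs = fs, channelLabels = lab)
}

#' Write a recording
#'
#' @param rec a [Recording-class].
#' @param path output path.
#' @param format `"auto"`, `"edf"` or `"delimited"`.
#' @param sep field separator (delimited).
#' @param writeLabels include the channel label as first field (delimited).
#' @return Invisibly, `path`.
#' @export
writeRecording <- function(rec, path, format = c("auto", "edf", "delimited"),
                           sep = "\t", writeLabels = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "delimited"
  if (format == "edf") return(writeEdf(rec, path))
  X <- recData(rec)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(X))) {
    vals <- format(X[i, ], digits = 17, scientific = FALSE, trim = TRUE)
    if (writeLabels) vals <- c(channelLabels(rec)[i], vals)
    writeLines(paste(vals, collapse = sep), con)
  }
  invisible(path)
}

# ---- EDF (European Data Format): fixed 256-byte header + 256 bytes per
# signal, then data records of 16-bit little-endian integers. ----

padField <- function(x, width) {
  s <- substr(format(x, trim = TRUE), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording as EDF
#'
#' Minimal EDF writer: one data record per second, 16-bit samples scaled over
#' each channel's physical range.
#'
#' @param rec a [Recording-class] with integer samples-per-second rate.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeEdf <- function(rec, path) {
  X <- recData(rec)
  fs <- samplingRate(rec)
  if (fs != round(fs)) stop("EDF export needs an integer sampling rate",
                            call. = FALSE)
  ns <- nrow(X)
  spr <- as.integer(fs)               # samples per record (1 s records)
  nrec <- floor(ncol(X) / spr)
  if (nrec < 1) stop("recording shorter than one EDF record (1 s)",
                     call. = FALSE)
  physMin <- pmin(apply(X, 1, min), -1)
  physMax <- pmax(apply(X, 1, max), 1)
  con <- file(path, "wb")
  on.exit(close(con))
  wf <- function(x, width) writeChar(paste0(vapply(x, padField, "",
                                                   width = width),
                                            collapse = ""), con,
                                     eos = NULL)
  wf("0", 8); wf("anpca synthetic subject", 80); wf("anpca recording", 80)
  wf("01.01.00", 8); wf("00.00.00", 8)
  wf(as.character(256 * (1 + ns)), 8)
  wf("", 44)
  wf(as.character(nrec), 8); wf("1", 8); wf(as.character(ns), 4)
  wf(channelLabels(rec), 16)
  wf(rep("", ns), 80)                 # transducer
  wf(rep("uV", ns), 8)
  wf(sprintf("%.6g", physMin), 8); wf(sprintf("%.6g", physMax), 8)
  wf(rep("-32768", ns), 8); wf(rep("32767", ns), 8)
  wf(rep("", ns), 80)                 # prefiltering
  wf(rep(as.character(spr), ns), 8)
  wf(rep("", ns), 32)                 # reserved
  scale <- (physMax - physMin) / (32767 - (-32768))
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(ns)) {
      dig <- round((X[i, idx] - physMin[i]) / scale[i]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path EDF file path.
#' @return A [Recording-class].
#' @export
readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rf <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rf(8); rf(80); rf(80); rf(8); rf(8)
  rf(8)                                # header bytes
  rf(44)
  nrec <- as.integer(rf(8))
  recDur <- as.numeric(rf(8))
  ns <- as.integer(rf(4))
  if (is.na(ns) || ns < 1) stop("parse error: invalid EDF header",
                                call. = FALSE)
  labels <- vapply(seq_len(ns), function(i) rf(16), "")
  for (i in seq_len(ns)) rf(80)
  for (i in seq_len(ns)) rf(8)        # units
  physMin <- as.numeric(vapply(seq_len(ns), function(i) rf(8), ""))
  physMax <- as.numeric(vapply(seq_len(ns), function(i) rf(8), ""))
  digMin <- as.numeric(vapply(seq_len(ns), function(i) rf(8), ""))
  digMax <- as.numeric(vapply(seq_len(ns), function(i) rf(8), ""))
  for (i in seq_len(ns)) rf(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rf(8), ""))
  for (i in seq_len(ns)) rf(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-signal rates are not supported", call. = FALSE)
  scale <- (physMax - physMin) / (digMax - digMin)
  X <- matrix(0, ns, nrec * spr[1])
  for (r in seq_len(nrec)) for (i in seq_len(ns)) {
    dig <- readBin(con, "integer", n = spr[1], size = 2, endian = "little")
    X[i, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
      (dig - digMin[i]) * scale[i] + physMin[i]
  }
  new("Recording", X = X, fs = spr[1] / recDur, channelLabels = labels)
}

#' Write an event table
#'
#' Tab-separated table with header `onset stimulus block is_target`.
#'
#' @param events an [EventSequence-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeEvents <- function(events, path) {
  df <- data.frame(onset = onsets(events), stimulus = stimulusIds(events),
                   block = blockIds(events),
                   is_target = as.integer(isTarget(events)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an event table
#'
#' @param path tab-separated table written by [writeEvents()].
#' @param isi,flashDuration schedule timing; inferred from onsets when
#'   omitted.
#' @return An [EventSequence-class].
#' @export
readEvents <- function(path, isi = NULL, flashDuration = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  isi <- isi %||%
    (if (nrow(df) > 1) round(stats::median(diff(df$onset)), 6) else 0.350)
  tid <- unique(df$stimulus[df$is_target == 1])
  if (length(tid) != 1)
    stop("parse error: the event table must mark exactly one target stimulus",
         call. = FALSE)
  new("EventSequence", onsets = df$onset,
      stimulus = as.integer(df$stimulus), block = as.integer(df$block),
      targetId = as.integer(tid),
      flashDuration = flashDuration %||% (isi - 0.300), isi = isi)
}

#' Write ground truth for later scoring
#'
#' Sources, their kinds, and the mixing matrix, as plain-text files in a
#' directory (`S.tsv`, `A.tsv`, `meta.json`).
#'
#' @param srcs a [SourceSet-class].
#' @param model a [MixtureModel-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeGroundTruth <- function(srcs, model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(sources(srcs), file.path(dir, "S.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(mixingMatrix(model), file.path(dir, "A.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(kinds = sourceKinds(srcs), fs = samplingRate(srcs),
         noiseSigma = noiseSigma(model), seed = model@seed),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read ground truth written by [writeGroundTruth()]
#'
#' @param dir the directory.
#' @return A list with `sources` and `model`.
#' @export
readGroundTruth <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  S <- as.matrix(utils::read.table(file.path(dir, "S.tsv"), sep = "\t"))
  dimnames(S) <- NULL
  A <- as.matrix(utils::read.table(file.path(dir, "A.tsv"), sep = "\t"))
  dimnames(A) <- NULL
  list(sources = new("SourceSet", S = S, kinds = meta$kinds, fs = meta$fs),
       model = new("MixtureModel", A = A, noiseSigma = meta$noiseSigma,
                   seed = as.integer(meta$seed)))
}

#' Serialize a quality report
#'
#' JSON for the scalar fields and, optionally, the PI trajectory as CSV.
#'
#' @param report a [QualityReport-class].
#' @param path JSON output path.
#' @param trajectoryPath optional CSV path for the iteration-level PI curve.
#' @param provenance optional provenance list to embed.
#' @return Invisibly, `path`.
#' @export
writeReport <- function(report, path, trajectoryPath = NULL,
                        provenance = NULL) {
  obj <- list(pi = piValue(report), pi_db = piDecibel(report),
              converged = report@converged,
              converged_epoch = convergedEpoch(report),
              epoch_pi = report@epochPi,
              combined_system = report@C)
  if (!is.null(provenance)) obj$provenance <- provenance
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(trajectoryPath))
    utils::write.csv(piTrajectory(report), trajectoryPath,
                     row.names = FALSE)
  invisible(path)
}
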