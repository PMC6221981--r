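# Minimal BrainVision-style reader/writer: INI-style .vhdr text header,
# .vmrk marker file, multiplexed IEEE float32 little-endian .eeg binary.
# Covers the subset of the format this pipeline produces and consumes.

#' Write a recording as a BrainVision-style file triplet
#'
#' Produces \code{<basename>.vhdr} (text header), \code{<basename>.vmrk}
#' (markers; one \code{Stimulus,S<code>} entry per event) and
#' \code{<basename>.eeg} (multiplexed IEEE 32-bit float, little endian,
#' values in uV).
#'
#' @param rec An \code{eeg_recording}.
#' @param basename Path without extension.
#' @return \code{basename}, invisibly.
#' @export
write_brainvision <- function(rec, basename) {
  stopifnot(inherits(rec, "eeg_recording"))
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg <- paste0(basename, ".eeg")
  nm <- basename(basename)
  n_ch <- nrow(rec$samples)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "", "[Common Infos]",
    sprintf("DataFile=%s.eeg", nm),
    sprintf("MarkerFile=%s.vmrk", nm),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", n_ch),
    sprintf("SamplingInterval=%.6f", 1e6 / rec$fs),
    "", "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "", "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(n_ch), rec$channel_names)
  )
  writeLines(hdr, vhdr, useBytes = TRUE)
  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "", "[Common Infos]",
    sprintf("DataFile=%s.eeg", nm),
    "", "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000",
    if (nrow(rec$markers))
      sprintf("Mk%d=Stimulus,S%3d,%d,1,0", seq_len(nrow(rec$markers)) + 1L,
              rec$markers$code, rec$markers$sample)
  )
  writeLines(mk, vmrk)
  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$samples), con, size = 4L, endian = "little")
  invisible(basename)
}

parse_ini <- function(lines) {
  lines <- lines[!startsWith(lines, ";")]
  kv <- lines[grepl("=", lines, fixed = TRUE)]
  pos <- regexpr("=", kv, fixed = TRUE)
  stats::setNames(substring(kv, pos + 1L), substring(kv, 1L, pos - 1L))
}

#' Read a BrainVision-style file triplet
#'
#' Supports the subset written by \code{\link{write_brainvision}}:
#' multiplexed binary data in IEEE float32 or 16-bit signed integer (with
#' per-channel resolution), with \code{Stimulus,S<code>} markers.
#'
#' @param vhdr_path Path to the \code{.vhdr} header.
#' @return An \code{eeg_recording}.
#' @export
read_brainvision <- function(vhdr_path) {
  stopifnot(file.exists(vhdr_path))
  dir <- dirname(vhdr_path)
  ini <- parse_ini(readLines(vhdr_path, warn = FALSE))
  if (!identical(ini[["DataOrientation"]], "MULTIPLEXED"))
    stop("only MULTIPLEXED orientation is supported")
  n_ch <- as.integer(ini[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(ini[["SamplingInterval"]])
  ch_keys <- sprintf("Ch%d", seq_len(n_ch))
  ch_info <- strsplit(unname(ini[ch_keys]), ",")
  ch_names <- vapply(ch_info, `[`, character(1), 1)
  resolution <- vapply(ch_info, function(ci)
    if (length(ci) >= 3 && nzchar(ci[3])) as.numeric(ci[3]) else 1,
    numeric(1))
  fmt <- ini[["BinaryFormat"]]
  eeg_path <- file.path(dir, ini[["DataFile"]])
  sz <- file.info(eeg_path)$size
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  if (identical(fmt, "IEEE_FLOAT_32")) {
    raw <- readBin(con, "numeric", n = sz / 4, size = 4L, endian = "little")
  } else if (identical(fmt, "INT_16")) {
    raw <- readBin(con, "integer", n = sz / 2, size = 2L, signed = TRUE,
                   endian = "little")
    raw <- raw * rep(resolution, length.out = length(raw))
  } else stop("unsupported BinaryFormat: ", fmt)
  samples <- matrix(raw, nrow = n_ch,
                    dimnames = list(ch_names, NULL))
  markers <- data.frame(sample = integer(), code = integer())
  vmrk_path <- file.path(dir, ini[["MarkerFile"]])
  if (file.exists(vmrk_path)) {
    mk <- parse_ini(readLines(vmrk_path, warn = FALSE))
    mk <- mk[grepl("^Mk", names(mk))]
    parts <- strsplit(unname(mk), ",")
    stim <- vapply(parts, function(p) identical(p[1], "Stimulus"), logical(1))
    if (any(stim)) {
      parts <- parts[stim]
      markers <- data.frame(
        sample = vapply(parts, function(p) as.integer(p[3]), integer(1)),
        code = vapply(parts, function(p)
          as.integer(sub("^S\\s*", "", p[2])), integer(1)))
      markers <- markers[order(markers$sample), ]
    }
  }
  eeg_recording(samples, fs, markers, history = "read_brainvision")
}

#' Serialize an epoch set
#'
#' Epochs round-trip through R's native serialization (no HDF5 library is
#' assumed); the time axis, condition labels and kept mask travel with the
#' data array.
#'
#' @param epochs An \code{epoch_set}.
#' @param path Output path (conventionally \code{.rds}).
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  saveRDS(epochs, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  epochs <- readRDS(path)
  stopifnot(inherits(epochs, "epoch_set"))
  epochs
}
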