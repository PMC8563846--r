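# Minimal RIFF WAV support (mono, 32-bit IEEE float by default, 16-bit PCM
# read also accepted). Hand-rolled because no installed package provides WAV
# I/O; the format is trivial for this use.

#' Write a mono waveform as a RIFF WAV file
#'
#' 32-bit IEEE float samples at the given rate.
#' @param wave numeric waveform (full scale +-1).
#' @param path output path.
#' @param rate sampling rate in Hz.
#' @export
write_wav <- function(wave, path, rate = 44100) {
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- length(wave) * 4L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(4 + 26 + 12 + 8 + nbytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(18L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")            # IEEE float
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeBin(0L, con, size = 2, endian = "little")            # cbSize
  writeChar("fact", con, eos = NULL)
  writeBin(4L, con, size = 4, endian = "little")
  writeBin(length(wave), con, size = 4, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, size = 4, endian = "little")
  writeBin(as.numeric(wave), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a mono RIFF WAV file
#'
#' Supports 32-bit float and 16-bit PCM, mono.
#' @param path file path.
#' @return Numeric waveform with attribute `rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (!identical(hdr, "RIFF")) abort("not a RIFF file")
  readBin(con, integer(), size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) abort("not a WAVE file")
  fmt <- NULL; rate <- NULL; wave <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), size = 2, n = 2, endian = "little")
      rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      blk <- readBin(con, integer(), size = 2, n = 2, endian = "little")
      bits <- blk[2]
      if (sz > 16) readBin(con, raw(), n = sz - 16)
      if (fmt[2] != 1) abort("only mono WAV supported")
      attr(fmt, "bits") <- bits
    } else if (id == "data") {
      bits <- attr(fmt, "bits")
      if (fmt[1] == 3 && bits == 32) {
        wave <- readBin(con, numeric(), size = 4, n = sz / 4, endian = "little")
      } else if (fmt[1] == 1 && bits == 16) {
        wave <- readBin(con, integer(), size = 2, n = sz / 2, signed = TRUE,
                        endian = "little") / 32768
      } else {
        abort("unsupported WAV encoding (need float32 or PCM16)")
      }
    } else {
      readBin(con, raw(), n = sz + sz %% 2)
    }
    if (!is.null(wave)) break
  }
  if (is.null(wave)) abort("no data chunk found")
  attr(wave, "rate") <- rate
  wave
}

#' Write a corpus to disk (WAV files plus manifest CSV)
#'
#' @param corpus a corpus tibble with waveforms.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(corpus$excerpt_id, ".wav"))
  purrr::walk2(corpus$wave, paths, write_wav, rate = corpus$rate[1])
  manifest <- dplyr::mutate(
    dplyr::select(corpus, "excerpt_id", "domain", "speaker_id", "duration_s"),
    path = basename(paths))
  mp <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, mp)
  invisible(mp)
}

#' Read a corpus from a manifest CSV
#'
#' @param manifest_path path to a manifest written by [write_corpus()].
#' @return A corpus tibble with waveforms.
#' @export
read_corpus <- function(manifest_path) {
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE,
                              col_types = readr::cols(speaker_id = "c"))
  waves <- lapply(file.path(dirname(manifest_path), manifest$path), read_wav)
  dplyr::mutate(dplyr::select(manifest, -"path"),
                rate = vapply(waves, attr, numeric(1), "rate"),
                wave = lapply(waves, as.numeric))
}

#' Serialize and restore trial designs
#'
#' @param design a `session_design` tibble (or several bound together).
#' @param path CSV path.
#' @export
write_design_csv <- function(design, path) {
  readr::write_csv(as_tibble(design), path)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(speaker_id = "c",
                                                 session_id = "c"))
  class(out) <- c("session_design", class(out))
  out
}

#' Serialize and restore response tables
#'
#' @param responses a response tibble from [simulate_participants()].
#' @param path CSV path.
#' @export
write_responses_csv <- function(responses, path) {
  readr::write_csv(responses, path)
  invisible(path)
}

#' @rdname write_responses_csv
#' @export
read_responses_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(speaker_id = "c", session_id = "c",
                                          participant = "c"))
}

#' Write / read a transfer function as magnitude-phase CSV on an FFT grid
#'
#' Columns `freq_hz`, `magnitude_db`, `phase_unwrapped_rad` over the
#' nonnegative half of an `n_fft` grid.
#' @param tf a [transfer_function()].
#' @param path CSV path.
#' @param n_fft FFT grid length.
#' @export
write_transfer_function_csv <- function(tf, path, n_fft = 4096) {
  h <- tf_frequency_response(tf, n_fft)[seq_len(n_fft %/% 2 + 1)]
  readr::write_csv(tibble(
    freq_hz = (seq_len(n_fft %/% 2 + 1) - 1) * tf$rate / n_fft,
    magnitude_db = 20 * log10(Mod(h)),
    phase_unwrapped_rad = unwrap_phase(Arg(h))
  ), path)
  invisible(path)
}

#' @rdname write_transfer_function_csv
#' @param rate sampling rate of the stored grid.
#' @export
read_transfer_function_csv <- function(path, rate = 44100) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  nh <- nrow(d)
  n_fft <- (nh - 1) * 2
  hm <- 10^(d$magnitude_db / 20) * exp(1i * d$phase_unwrapped_rad)
  h <- complex(length.out = n_fft)
  h[seq_len(nh)] <- hm
  h[seq(n_fft, nh + 1)] <- Conj(hm[2:(nh - 1)])
  transfer_function(Re(stats::fft(h, inverse = TRUE)) / n_fft, rate)
}

#' Batch spectral-centroid extraction from a corpus manifest
#'
#' Reads a corpus manifest, computes the SC of every excerpt under the given
#' slope colorations and writes a CSV `excerpt_id`, `coloration`, `sc_hz`.
#' @param manifest_path corpus manifest CSV.
#' @param out_path output CSV.
#' @param slopes slope colorations (dB/oct); `NULL` for unprocessed only.
#' @export
sc_batch_csv <- function(manifest_path, out_path, slopes = NULL) {
  corpus <- read_corpus(manifest_path)
  tab <- sc_slope_table(corpus, slopes %||% numeric(0), include_raw = TRUE)
  readr::write_csv(tab, out_path)
  invisible(out_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
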