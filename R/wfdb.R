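#' Read a paired record from local WFDB files
#'
#' Minimal reader for the WFDB format used by PhysioNet waveform archives:
#' a text header (`<record>.hea`) plus a format-16 signal file
#' (little-endian 16-bit integers, samples interleaved across signals).
#' Channels are selected by their signal description (e.g. `"II"`,
#' `"PLETH"`); amplitudes are converted to physical units via the header's
#' gain and baseline.  This is a convenience path only - the package never
#' requires WFDB input, and the CSV route ([read_record_csv()]) is canonical.
#'
#' @param record_name Path to the record without extension (the reader
#'   appends `.hea` and reads the signal file named in the header).
#' @param ecg_channel,ppg_channel Signal descriptions to select.
#' @return A [new_record()] object with `fs` taken from the header.
#' @export
read_record_wfdb <- function(record_name, ecg_channel = "II",
                             ppg_channel = "PLETH") {
  hea_path <- paste0(record_name, ".hea")
  if (!file.exists(hea_path)) stop("WFDB header not found: ", hea_path)
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  head_tok <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  if (length(head_tok) < 4L) stop("malformed WFDB header line: ", lines[[1]])
  nsig <- as.integer(head_tok[2])
  fs <- as.numeric(head_tok[3])
  nsamp <- as.integer(head_tok[4])
  if (length(lines) < 1L + nsig) stop("WFDB header lists ", nsig,
                                      " signals but has too few lines")

  sig <- lapply(lines[1L + seq_len(nsig)], function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    gain_str <- tok[3]
    gain <- as.numeric(sub("\\(.*$", "", sub("/.*$", "", gain_str)))
    baseline <- if (grepl("\\(", gain_str)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_str))
    } else 0
    if (!is.finite(gain) || gain == 0) gain <- 200  # WFDB default gain
    list(file = tok[1], fmt = tok[2], gain = gain, baseline = baseline,
         desc = paste(tok[-seq_len(8)], collapse = " "))
  })
  descs <- vapply(sig, `[[`, character(1), "desc")
  pick <- function(ch) {
    i <- which(descs == ch)
    if (length(i) != 1L) {
      stop("channel '", ch, "' not found in WFDB record (available: ",
           paste(descs, collapse = ", "), ")")
    }
    i
  }
  i_ecg <- pick(ecg_channel)
  i_ppg <- pick(ppg_channel)
  if (any(vapply(sig, `[[`, character(1), "fmt") != "16")) {
    stop("only WFDB signal format 16 is supported")
  }

  dat_path <- file.path(dirname(hea_path), sig[[1]]$file)
  if (!file.exists(dat_path)) stop("WFDB signal file not found: ", dat_path)
  raw <- readBin(dat_path, what = "integer", size = 2L, signed = TRUE,
                 endian = "little", n = nsig * nsamp)
  if (length(raw) < nsig * nsamp) stop("WFDB signal file shorter than header declares")
  adc <- matrix(raw, nrow = nsig)
  phys <- function(i) (adc[i, ] - sig[[i]]$baseline) / sig[[i]]$gain
  new_record(phys(i_ecg), phys(i_ppg), fs = fs,
             record_id = basename(record_name))
}

# Write a record as a WFDB header + format-16 signal pair.  Used by the test
# suite (round-trip fixtures) and by the CLI when asked for WFDB output.
# Amplitudes are quantized with the given gain; not exported API.
write_record_wfdb <- function(record, record_name, ecg_channel = "II",
                              ppg_channel = "PLETH", gain = 1000) {
  stopifnot(inherits(record, "cardio_record"))
  n <- length(record$ecg)
  base <- basename(record_name)
  dat_file <- paste0(base, ".dat")
  hea <- c(
    sprintf("%s 2 %g %d", base, record$fs, n),
    sprintf("%s 16 %g(0)/mV 16 0 0 0 0 %s", dat_file, gain, ecg_channel),
    sprintf("%s 16 %g(0)/mV 16 0 0 0 0 %s", dat_file, gain, ppg_channel)
  )
  writeLines(hea, paste0(record_name, ".hea"))
  adc <- rbind(as.integer(round(record$ecg * gain)),
               as.integer(round(record$ppg * gain)))
  if (any(abs(adc) > 32767)) stop("amplitudes overflow 16-bit WFDB storage at gain ", gain)
  writeBin(as.integer(adc), file.path(dirname(record_name), dat_file),
           size = 2L, endian = "little")
  invisible(record_name)
}
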