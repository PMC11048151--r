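#' Paired ECG/PPG record
#'
#' A `cardio_record` bundles one single-channel ECG (lead II by convention)
#' with the simultaneously recorded PPG, both sampled at the same rate.
#' Amplitudes are in arbitrary units; downstream preprocessing min-max
#' normalizes them per record.  Optional `annotations` hold ground-truth
#' R-peak sample indices (1-based), as produced by [gen_record()].
#'
#' @param ecg,ppg Numeric vectors of equal length; all values finite.
#' @param fs Sampling rate in Hz (default 125).
#' @param record_id Character identifier.
#' @param annotations Optional integer vector of R-peak sample indices.
#' @return An object of class `cardio_record`: a list with elements
#'   `ecg`, `ppg`, `fs`, `record_id`, `annotations`.
#' @examples
#' r <- new_record(ecg = sin(1:100 / 5), ppg = cos(1:100 / 5), fs = 125)
#' r
#' @export
new_record <- function(ecg, ppg, fs = 125, record_id = "record",
                       annotations = NULL) {
  ecg <- as.numeric(ecg)
  ppg <- as.numeric(ppg)
  if (length(ecg) != length(ppg)) {
    stop("ecg and ppg must have equal length (got ", length(ecg), " and ",
         length(ppg), ")")
  }
  if (length(ecg) < 1L) stop("record must contain at least one sample")
  if (!all(is.finite(ecg)) || !all(is.finite(ppg))) {
    stop("all ecg and ppg samples must be finite")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number")
  }
  if (!is.null(annotations)) {
    annotations <- as.integer(annotations)
    if (any(annotations < 1L | annotations > length(ecg))) {
      stop("annotations must be sample indices within the record")
    }
  }
  structure(
    list(ecg = ecg, ppg = ppg, fs = fs,
         record_id = as.character(record_id), annotations = annotations),
    class = "cardio_record"
  )
}

#' @export
print.cardio_record <- function(x, ...) {
  cat(sprintf("<cardio_record '%s'>  %d samples @ %g Hz (%.1f s)%s\n",
              x$record_id, length(x$ecg), x$fs, length(x$ecg) / x$fs,
              if (is.null(x$annotations)) ""
              else sprintf(", %d annotated beats", length(x$annotations))))
  invisible(x)
}

#' @export
length.cardio_record <- function(x) length(x$ecg)

#' Read a paired record from a two-column CSV file
#'
#' The canonical interchange format is a CSV file with header `ecg,ppg`
#' and one numeric sample per row.  Row order is preserved.
#'
#' @param path Path to the CSV file.
#' @param fs Sampling rate in Hz to attach to the record (the CSV carries
#'   no rate information).
#' @param record_id Identifier; defaults to the file name without extension.
#' @return A [new_record()] object.
#' @seealso [write_record_csv()]
#' @export
read_record_csv <- function(path, fs = 125, record_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, header = TRUE, colClasses = "numeric"),
    error = function(e) stop("failed to parse '", path, "': ",
                             conditionMessage(e))
  )
  if (nrow(df) < 1L) stop("empty record file: ", path)
  if (!all(c("ecg", "ppg") %in% names(df))) {
    stop("CSV must have columns 'ecg' and 'ppg'; found: ",
         paste(names(df), collapse = ", "))
  }
  if (is.null(record_id)) {
    record_id <- sub("\\.[^.]*$", "", basename(path))
  }
  new_record(df$ecg, df$ppg, fs = fs, record_id = record_id)
}

#' Write a paired record to a two-column CSV file
#'
#' @param record A [new_record()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path) {
  stopifnot(inherits(record, "cardio_record"))
  df <- data.frame(ecg = record$ecg, ppg = record$ppg)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
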