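#' Write an epoch set to an HDF5 container + TSV metadata
#'
#' Stores the sample array and time axis as HDF5 datasets (`samples`,
#' `time_axis`, with a `sampling_rate` attribute and the channel labels)
#' next to a TSV metadata table with one row per epoch (columns `subject`,
#' `group`, `sequence`, `repetition`, `stimulus`, `fixation`). Requires the
#' `rhdf5` package.
#'
#' @param epochs An [epoch_set()].
#' @param h5_path Path of the HDF5 file (overwritten).
#' @param tsv_path Path of the metadata TSV; defaults to the HDF5 path with
#'   a `.tsv` extension.
#' @return `h5_path`, invisibly.
#' @export
write_epochs_h5 <- function(epochs, h5_path,
                            tsv_path = sub("\\.h5$", ".tsv", h5_path)) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("the rhdf5 package is required for HDF5 output", call. = FALSE)
  if (file.exists(h5_path)) unlink(h5_path)
  rhdf5::h5createFile(h5_path)
  rhdf5::h5write(epochs$samples, h5_path, "samples")
  rhdf5::h5write(epochs$time, h5_path, "time_axis")
  rhdf5::h5write(epochs$channels$channel, h5_path, "channels")
  rhdf5::h5write(epochs$channels$region, h5_path, "regions")
  fid <- rhdf5::H5Fopen(h5_path)
  rhdf5::h5writeAttribute(epochs$sampling_rate, fid, "sampling_rate")
  rhdf5::H5Fclose(fid)
  readr::write_tsv(epochs$metadata, tsv_path)
  invisible(h5_path)
}

#' Read an epoch set from an HDF5 container + TSV metadata
#'
#' @param h5_path Path of the HDF5 file written by [write_epochs_h5()] (or
#'   any container with the same schema: datasets `samples`
#'   (epoch x channel x time), `time_axis`, `channels`, `regions`, and a
#'   `sampling_rate` attribute).
#' @param tsv_path Path of the metadata TSV.
#' @return An [epoch_set()].
#' @export
read_epochs_h5 <- function(h5_path,
                           tsv_path = sub("\\.h5$", ".tsv", h5_path)) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("the rhdf5 package is required for HDF5 input", call. = FALSE)
  samples <- rhdf5::h5read(h5_path, "samples")
  time_axis <- as.vector(rhdf5::h5read(h5_path, "time_axis"))
  channels <- tibble::tibble(
    channel = as.vector(rhdf5::h5read(h5_path, "channels")),
    region = as.vector(rhdf5::h5read(h5_path, "regions")))
  fid <- rhdf5::H5Fopen(h5_path)
  fs <- as.vector(rhdf5::h5readAttributes(fid, "/")$sampling_rate)
  rhdf5::H5Fclose(fid)
  meta <- readr::read_tsv(tsv_path, show_col_types = FALSE)
  epoch_set(samples, time_axis, meta, fs, channels)
}

#' Write / read a tabular result as TSV
#'
#' TSV is the package's tabular interchange format: UTF-8, one header line,
#' `.` decimal separator. Doubles are written with a shortest round-trip
#' representation, so tables survive a write/read cycle losslessly.
#'
#' @param table A data frame.
#' @param path File path.
#' @return `write_table_tsv` returns `path` invisibly; `read_table_tsv`
#'   returns a tibble.
#' @export
write_table_tsv <- function(table, path) {
  drop <- vapply(table, is.list, logical(1))
  table <- table[!drop]
  # 17 significant digits round-trip IEEE doubles exactly
  dbl <- vapply(table, is.double, logical(1))
  table[dbl] <- lapply(table[dbl], function(x)
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x)))
  readr::write_tsv(table, path)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  # read as character and convert with base R's correctly rounded parser,
  # so the %.17g representations map back to the exact original doubles
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  tab[] <- lapply(tab, utils::type.convert, as.is = TRUE)
  tab
}
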