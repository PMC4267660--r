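TRACE_FORMAT_VERSION <- "1.0"

#' Write / read a photon trace
#'
#' The canonical on-disk dialect is a diff-able CSV with header
#' \code{bin_index,donor,acceptor} plus a JSON sidecar (\code{<path>.json})
#' holding the bin width, background rates, metadata and a format version
#' tag. The round trip is lossless for counts and metadata.
#'
#' @param trace a \code{"photon_trace"}.
#' @param path CSV file path; the sidecar is written next to it.
#' @return \code{write_trace} returns \code{path} invisibly;
#'   \code{read_trace} returns a \code{"photon_trace"}.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "photon_trace"))
  df <- data.frame(bin_index = seq_along(trace$donor),
                   donor = trace$donor, acceptor = trace$acceptor)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(version = TRACE_FORMAT_VERSION,
                  bin_width = trace$bin_width,
                  background_rate_donor = trace$background_rate_donor,
                  background_rate_acceptor = trace$background_rate_acceptor,
                  metadata = trace$metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such trace file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  required <- c("bin_index", "donor", "acceptor")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("trace file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(df$donor < 0 | df$acceptor < 0)
  if (length(bad) > 0) {
    stop(sprintf("negative photon count at row %d of %s", bad[1], path),
         call. = FALSE)
  }
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) {
    stop("missing sidecar file: ", side_path, call. = FALSE)
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  if (!identical(side$version, TRACE_FORMAT_VERSION)) {
    stop(sprintf("trace format version mismatch: file has '%s', reader expects '%s'",
                 side$version, TRACE_FORMAT_VERSION), call. = FALSE)
  }
  structure(
    list(donor = as.integer(df$donor), acceptor = as.integer(df$acceptor),
         bin_width = side$bin_width,
         background_rate_donor = side$background_rate_donor,
         background_rate_acceptor = side$background_rate_acceptor,
         metadata = side$metadata,
         truth = NULL),
    class = "photon_trace"
  )
}

#' Write / read a distance-measurement table
#'
#' CSV with header \code{sample_id,length_nt,condition,distance_nm,sigma_nm}
#' (and \code{cistron_class} when present), the exchange format between the
#' simulator / burst analysis and the trend fits.
#'
#' @param measurements data.frame as produced by [simulate_rna_dataset()].
#' @param path CSV path.
#' @export
write_measurements <- function(measurements, path) {
  stopifnot(is.data.frame(measurements))
  utils::write.csv(measurements, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  required <- c("sample_id", "length_nt", "condition", "distance_nm", "sigma_nm")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("measurement file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Sequence lengths from a FASTA file
#'
#' The pipeline uses RNA sequences only through their lengths; this reads a
#' (multi-record) FASTA — RNA or DNA alphabet, U and T both fine — and
#' returns the per-record nucleotide counts in file order.
#'
#' @param path FASTA file.
#' @return data.frame with columns \code{id} and \code{length_nt}.
#' @export
lengths_from_fasta <- function(path) {
  if (!file.exists(path)) stop("no such FASTA file: ", path, call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file contains no records: ", path,
                               call. = FALSE)
  widths <- Biostrings::width(seqs)
  if (any(widths == 0L)) {
    stop("FASTA record with empty sequence: ",
         names(seqs)[which(widths == 0L)[1]], call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  data.frame(id = ids, length_nt = as.integer(widths), row.names = NULL)
}
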