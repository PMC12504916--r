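#' Write an FID as two-column real/imaginary text
#'
#' Plain-text single-spectrum export in the spirit of the jMRUI text
#' format: `key: value` header lines carrying the acquisition metadata,
#' then one `re im` pair per line.
#'
#' @param fid a `fid` object
#' @param path output file path
#' @export
write_fid_txt <- function(fid, path) {
  stopifnot(inherits(fid, "fid"))
  hdr <- c(
    sprintf("PointsInDataset: %d", length(fid$samples)),
    sprintf("SamplingInterval: %.10g", fid$acq$dwell_time),
    sprintf("TransmitterFrequency: %.10g", fid$acq$reference_frequency),
    sprintf("CarrierOffsetPPM: %.10g", fid$acq$carrier_offset_ppm),
    sprintf("RepetitionTime: %.10g", fid$acq$tr),
    sprintf("FlipAngle: %.10g", fid$acq$flip_angle),
    "SignalAndHeader:")
  body <- sprintf("%.12e %.12e", Re(fid$samples), Im(fid$samples))
  writeLines(c(hdr, body), path)
}

#' Read an FID written by [write_fid_txt()]
#'
#' @param path input file path
#' @return a `fid` object
#' @export
read_fid_txt <- function(path) {
  lines <- readLines(path)
  split_at <- which(lines == "SignalAndHeader:")
  stopifnot(length(split_at) == 1)
  hdr <- lines[seq_len(split_at - 1)]
  get <- function(key) {
    v <- sub(paste0("^", key, ": "), "", hdr[startsWith(hdr, paste0(key, ":"))])
    as.numeric(v)
  }
  n <- as.integer(get("PointsInDataset"))
  dwell <- get("SamplingInterval")
  acq <- acq_params(n_points = n, bandwidth = 1 / dwell, dwell_time = dwell,
                    reference_frequency = get("TransmitterFrequency"),
                    tr = get("RepetitionTime"), flip_angle = get("FlipAngle"),
                    carrier_offset_ppm = get("CarrierOffsetPPM"))
  body <- utils::read.table(text = lines[-seq_len(split_at)])
  stopifnot(nrow(body) == n)
  new_fid(complex(real = body[[1]], imaginary = body[[2]]), acq)
}

#' Write a cohort ground-truth manifest as CSV
#'
#' @param cohort a [make_cohort()] result
#' @param path output CSV path
#' @export
write_manifest_csv <- function(cohort, path) {
  utils::write.csv(cohort$manifest, path, row.names = FALSE)
}
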