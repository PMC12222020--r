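# Lightweight serialisation: designs/choices/AU tables travel as CSV,
# EpochSet objects as RDS (no HDF5 dependency is assumed in this
# environment).

#' Read and write trial/choice/AU tables as CSV
#'
#' Plain CSV with documented column names (\code{subject},
#' \code{trial_index}, \code{identity}, \code{emotion}, \code{fnmes},
#' \code{repetition}, and \code{choice} / AU columns where present; AU
#' columns follow the OpenFace naming \code{AU12_r} etc.).
#'
#' @param x a design/choice/AU \code{data.frame}.
#' @param path file path.
#' @return \code{readTrialTable}: the \code{data.frame}.
#' @export
writeTrialTable <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrialTable
#' @export
readTrialTable <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Save and load EpochSet objects
#'
#' Single-file RDS serialisation of the whole container (data, design,
#' montage, time axis, provenance log).
#'
#' @param epochs an \code{\link{EpochSet}}.
#' @param path file path.
#' @return \code{readEpochSet}: the \code{EpochSet}.
#' @export
writeEpochSet <- function(epochs, path) {
  stopifnot(is(epochs, "EpochSet"))
  saveRDS(epochs, path)
  invisible(path)
}

#' @rdname writeEpochSet
#' @export
readEpochSet <- function(path) {
  x <- readRDS(path)
  stopifnot(is(x, "EpochSet"))
  validObject(x)
  x
}

#' Export a significance mask as run-length JSON-ready records
#'
#' Compacts a logical frequency x time mask into per-frequency runs of
#' significant time bins, a convenient text representation.
#'
#' @param mask logical matrix (rows = frequencies).
#' @param freqs,times axis values.
#' @return \code{data.frame} with columns \code{freq}, \code{t_start},
#'   \code{t_end} (inclusive run bounds in the time axis units).
#' @export
maskRuns <- function(mask, freqs = seq_len(nrow(mask)),
                     times = seq_len(ncol(mask))) {
  out <- list()
  for (i in seq_len(nrow(mask))) {
    r <- rle(as.logical(mask[i, ]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values))
      out[[length(out) + 1L]] <- data.frame(
        freq = freqs[i], t_start = times[starts[k]], t_end = times[ends[k]])
  }
  if (!length(out))
    return(data.frame(freq = numeric(0), t_start = numeric(0),
                      t_end = numeric(0)))
  do.call(rbind, out)
}
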