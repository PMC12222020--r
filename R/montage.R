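#' Standard 64-channel 10-20 montage template
#'
#' Returns the built-in 64-electrode montage in the extended international
#' 10-20 nomenclature, with schematic 2-D template coordinates used only for
#' neighbour definitions during channel interpolation (they are grid
#' positions on a flattened scalp, not digitised head coordinates).
#'
#' The montage contains every electrode the analyses reference: the 18
#' occipito-temporal N170 electrodes, the central ROI (Cz, C1-C4) and the
#' left / middle / right occipital ROIs.
#'
#' @return a \code{data.frame} with columns \code{channel}, \code{x}
#'   (lateral, negative = left) and \code{y} (anterior-posterior, positive =
#'   front), one row per electrode, 64 rows.
#' @examples
#' m <- standardMontage()
#' nrow(m)                      # 64
#' all(n170Electrodes() %in% m$channel)
#' @export
standardMontage <- function() {
  rows <- list(
    c("Fp1", "Fpz", "Fp2"),
    c("AF7", "AF3", "AFz", "AF4", "AF8"),
    c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
    c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
    c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
    c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
    c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
    c("PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8"),
    c("O1", "Oz", "O2"),
    "Iz")
  ys <- c(4, 3, 2, 1, 0, -1, -2, -3, -4, -5)
  lateral <- function(nm) {
    suffix <- sub("^[A-Za-z]+", "", nm)
    if (suffix == "z" || suffix == "") return(0)
    k <- as.numeric(suffix)
    side <- if (k %% 2 == 1) -1 else 1
    side * ceiling(k / 2)
  }
  out <- do.call(rbind, lapply(seq_along(rows), function(i) {
    nm <- rows[[i]]
    x <- vapply(nm, lateral, numeric(1))
    # T7/T8, FT7/FT8, TP7/TP8 sit on the outermost (10%) ring like P7/P8
    x[nm %in% c("T7", "FT7", "TP7")] <- -4
    x[nm %in% c("T8", "FT8", "TP8")] <- 4
    # AF electrodes are spread wider than their numeric index suggests
    x[nm == "AF3"] <- -1.5
    x[nm == "AF4"] <- 1.5
    x[nm == "AF7"] <- -3
    x[nm == "AF8"] <- 3
    data.frame(channel = nm, x = x, y = ys[i], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Electrode sets used by the analyses
#'
#' \code{n170Electrodes} returns the 18 occipito-temporal electrodes over
#' which trial-level N170 amplitude is averaged; \code{coherenceRois} the
#' central and left / middle / right occipital regions of interest used for
#' coherence analysis.
#'
#' @return \code{n170Electrodes}: character vector of 18 channel names.
#'   \code{coherenceRois}: named list with elements \code{central},
#'   \code{left}, \code{middle}, \code{right}.
#' @examples
#' length(n170Electrodes())     # 18
#' coherenceRois()$central      # Cz C1 C2 C3 C4
#' @export
n170Electrodes <- function() {
  c("P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8",
    "O1", "Oz", "O2")
}

#' @rdname n170Electrodes
#' @export
coherenceRois <- function() {
  list(central = c("Cz", "C1", "C2", "C3", "C4"),
       left = c("P1", "P3", "P5", "P7", "PO3", "PO5", "PO7"),
       middle = c("Pz", "POz", "Oz"),
       right = c("P2", "P4", "P6", "P8", "PO4", "PO6", "PO8"))
}

# Neighbour sets on the template grid: channels within `radius` grid units.
montageNeighbours <- function(montage = standardMontage(), radius = 1.6) {
  d <- as.matrix(dist(montage[, c("x", "y")]))
  nb <- lapply(seq_len(nrow(montage)), function(i) {
    montage$channel[d[i, ] > 0 & d[i, ] <= radius]
  })
  names(nb) <- montage$channel
  nb
}
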