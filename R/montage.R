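#' Idealized EEG montages on the extended 10-20 layout
#'
#' Builds a flat (disc-projected) electrode layout for the 63-channel extended
#' 10-20 cap used in concurrent TMS-EEG recordings (ground Fpz and reference
#' FCz are not data channels), or a reduced 8-channel parieto-occipital
#' montage for fast simulations. Coordinates are schematic - rows from
#' frontopolar (y = +4) to occipital (y = -4), lateral positions at unit
#' steps - which is sufficient for the two things the package needs a layout
#' for: a channel adjacency graph and a distance-based gain map around the
#' stimulated right-occipital site (near O2/PO4).
#'
#' @param n_channels Either 63 (full cap) or 8 (parieto-occipital subset).
#' @return A tibble with columns `channel`, `x`, `y`.
#' @examples
#' montage_1020(8)
#' @export
montage_1020 <- function(n_channels = 63) {
  rows <- list(
    Fp = list(y = 4,  ch = c("Fp1", "Fp2")),
    AF = list(y = 3,  ch = c("AF7", "AF3", "AFz", "AF4", "AF8")),
    F  = list(y = 2,  ch = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8")),
    FC = list(y = 1,  ch = c("FT9", "FT7", "FC5", "FC3", "FC1", "FC2", "FC4", "FC6", "FT8", "FT10")),
    C  = list(y = 0,  ch = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8")),
    CP = list(y = -1, ch = c("TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10")),
    P  = list(y = -2, ch = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8")),
    PO = list(y = -3, ch = c("PO7", "PO3", "POz", "PO4", "PO8")),
    O  = list(y = -4, ch = c("O1", "Oz", "O2"))
  )
  lay <- dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(channel = r$ch, x = vapply(r$ch, ch_lateral, 0.0), y = r$y)
  }))
  if (n_channels == 63) {
    return(lay)
  }
  if (n_channels == 8) {
    keep <- c("PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2")
    return(lay[match(keep, lay$channel), ])
  }
  stop_bad_arg("n_channels must be 63 or 8")
}

# lateral coordinate from the 10-20 site number: odd = left (negative),
# even = right; z-line = 0; 1/2 -> 1, 3/4 -> 2, 5/6 -> 3, 7/8 -> 4, 9/10 -> 5
ch_lateral <- function(label) {
  if (grepl("z$", label)) return(0)
  k <- as.integer(sub("^[A-Za-z]+", "", label))
  dist <- ceiling(k / 2)
  if (k %% 2 == 1) -dist else dist
}

#' Channel adjacency graph from an electrode layout
#'
#' Channels are adjacent when their planar distance is below
#' `scale` times the median nearest-neighbour distance of the layout.
#'
#' @param layout Tibble from [montage_1020()].
#' @param scale Multiplier on the median nearest-neighbour distance
#'   (default 1.3).
#' @return Symmetric logical adjacency matrix with channel dimnames.
#' @export
channel_adjacency <- function(layout, scale = 1.3) {
  d <- as.matrix(stats::dist(layout[, c("x", "y")]))
  dimnames(d) <- list(layout$channel, layout$channel)
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  adj <- d < scale * median(nn)
  diag(adj) <- FALSE
  adj | t(adj)
}

#' Right-occipital source gain map
#'
#' Distance-based falloff from a virtual source placed between O2 and PO4
#' (the scalp sites closest to the stimulated right V1/V2 locus). The gain is
#' `exp(-d^2 / (2 * sigma^2))`, maximal and equal at O2 and PO4 by
#' construction.
#'
#' @param layout Tibble from [montage_1020()].
#' @param sigma Spatial falloff constant in layout units (default 2).
#' @return Named numeric vector of gains in (0, 1], one per channel.
#' @export
occipital_gain <- function(layout, sigma = 2) {
  src <- c(
    x = mean(layout$x[layout$channel %in% c("O2", "PO4")]),
    y = mean(layout$y[layout$channel %in% c("O2", "PO4")])
  )
  d2 <- (layout$x - src["x"])^2 + (layout$y - src["y"])^2
  setNames(exp(-d2 / (2 * sigma^2)), layout$channel)
}
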