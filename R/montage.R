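#' Standard 19-channel 10-20 montage
#'
#' Builds the 19-electrode subset of the International 10-20 system used
#' for clinical qEEG (Fp1, Fp2, F3, F4, F7, F8, Fz, T3, T4, T5, T6, C3,
#' C4, Cz, P3, P4, Pz, O1, O2), with idealized unit-sphere positions.
#' The head is modelled as a unit sphere with the vertex (Cz) at +z,
#' +y anterior and +x toward the right ear.  Positions are constructed
#' from the 10-20 arc definitions: the circumferential ring sits at 72
#' degrees inclination from the vertex, midline and central electrodes at
#' 36 degrees, and the parasagittal electrodes (F3/F4/P3/P4) are arc
#' midpoints between their midline and ring neighbours.
#'
#' @param labels Optional character vector to reorder/subset validation
#'   against; the default is the full 19-channel set.
#' @return An object of class `montage`: a list with `labels` and an
#'   `n x 3` matrix `pos` of unit-sphere coordinates (rows named by label).
#' @export
#' @examples
#' m <- montage_1020()
#' m$labels
montage_1020 <- function(labels = NULL) {
  sph <- function(incl_deg, az_deg) {
    i <- incl_deg * pi / 180
    a <- az_deg * pi / 180
    c(sin(i) * cos(a), sin(i) * sin(a), cos(i))
  }
  # great-circle midpoint
  slerp_mid <- function(u, v) {
    w <- u + v
    w / sqrt(sum(w^2))
  }
  ring <- 72   # inclination of the circumferential ring
  mid  <- 36   # Fz/Pz/C3/C4 inclination
  pos <- list(
    Cz  = c(0, 0, 1),
    Fz  = sph(mid, 90),  Pz = sph(mid, -90),
    C3  = sph(mid, 180), C4 = sph(mid, 0),
    Fp1 = sph(ring, 108), Fp2 = sph(ring, 72),
    F7  = sph(ring, 144), F8  = sph(ring, 36),
    T3  = sph(ring, 180), T4  = sph(ring, 0),
    T5  = sph(ring, -144), T6 = sph(ring, -36),
    O1  = sph(ring, -108), O2 = sph(ring, -72)
  )
  pos$F3 <- slerp_mid(pos$Fz, pos$F7)
  pos$F4 <- slerp_mid(pos$Fz, pos$F8)
  pos$P3 <- slerp_mid(pos$Pz, pos$T5)
  pos$P4 <- slerp_mid(pos$Pz, pos$T6)

  order19 <- c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz", "T3", "T4",
               "T5", "T6", "C3", "C4", "Cz", "P3", "P4", "Pz", "O1", "O2")
  if (!is.null(labels)) {
    if (!setequal(labels, order19) || length(labels) != 19L)
      stop("montage must consist of exactly the 19 standard 10-20 labels")
    order19 <- labels
  }
  m <- matrix(unlist(pos[order19]), ncol = 3, byrow = TRUE,
              dimnames = list(order19, c("x", "y", "z")))
  structure(list(labels = order19, pos = m), class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat("10-20 montage:", length(x$labels), "electrodes\n")
  cat(paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' 2-D scalp coordinates for topographic maps
#'
#' Azimuthal equidistant projection of the montage positions (vertex at
#' the origin, nose up), as used for flat scalp topographies.
#'
#' @param montage A [montage_1020()] object.
#' @return Data frame with columns `label`, `x`, `y`.
#' @export
montage_topo_xy <- function(montage) {
  p <- montage$pos
  incl <- acos(pmin(pmax(p[, "z"], -1), 1))
  az <- atan2(p[, "y"], p[, "x"])
  data.frame(label = montage$labels,
             x = incl * cos(az), y = incl * sin(az),
             row.names = NULL)
}
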