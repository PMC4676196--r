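#' @title Theta-band coherence
#' @description Welch overlapped cross-spectral estimation and
#'   magnitude-squared coherence over all electrode pairs, with the
#'   eight named frontoposterior cluster means and per-pair pre/post
#'   change maps.
#' @name spectral_connectivity
NULL

#' Spectral estimation parameters
#'
#' @param window_length_s Welch window length in seconds (default 2,
#'   i.e. one full-length window per 2-s epoch; shorter windows slide
#'   within each epoch).
#' @param overlap_fraction Window overlap in `[0, 1)` (default 0.75).
#' @param taper `"hann"` or `"rectangular"`.
#' @param band Analysis band in Hz, default theta `c(4, 7.5)`.
#' @return A `spectral_params` list.
#' @export
spectral_params <- function(window_length_s = 2, overlap_fraction = 0.75,
                            taper = c("hann", "rectangular"),
                            band = c(4, 7.5)) {
  taper <- match.arg(taper)
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  if (band[1] >= band[2]) stop("band low must be below band high")
  structure(list(window_length_s = window_length_s,
                 overlap_fraction = overlap_fraction,
                 taper = taper, band = band), class = "spectral_params")
}

#' Averaged cross-spectral densities
#'
#' Tapered, overlapped windows are cut within each epoch (so splice
#' joints only ever sit at window edges, where the taper attenuates
#' them); per-window FFT cross-products are averaged across all windows
#' of all epochs.
#'
#' @param epochs An `epoch_set` from [splice_and_epoch()].
#' @param params A [spectral_params()].
#' @return A `cross_spectrum`: complex array `S` (channels x channels x
#'   frequencies, Hermitian in the channel indices), `freqs` in Hz,
#'   `n_windows`, and the channel labels.
#' @export
estimate_cross_spectra <- function(epochs, params = spectral_params()) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (length(epochs$epochs) < 1) stop("need at least one epoch")
  fs <- epochs$fs
  wl <- round(params$window_length_s * fs)
  nper <- ncol(epochs$epochs[[1]])
  if (wl > nper) stop("window longer than epoch")
  step <- max(1L, round(wl * (1 - params$overlap_fraction)))
  tap <- if (params$taper == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq_len(wl) / (wl + 1))
  } else rep(1, wl)
  nf <- wl %/% 2 + 1
  labels <- epochs$montage$labels
  nch <- length(labels)

  # collect FFTs of every window: nf x nch x n_windows
  wins <- list()
  for (ep in epochs$epochs) {
    starts <- seq(1L, nper - wl + 1L, by = step)
    for (s in starts) {
      seg <- ep[, s:(s + wl - 1L), drop = FALSE] * rep(tap, each = nch)
      F <- stats::mvfft(t(seg))[seq_len(nf), , drop = FALSE]
      wins[[length(wins) + 1L]] <- F
    }
  }
  nw <- length(wins)
  W <- array(unlist(wins), dim = c(nf, nch, nw))
  S <- array(complex(real = 0), dim = c(nch, nch, nf))
  for (i in seq_len(nch)) for (j in i:nch) {
    sij <- rowMeans(W[, i, , drop = FALSE] * Conj(W[, j, , drop = FALSE]),
                    dims = 1)
    S[i, j, ] <- sij
    if (j > i) S[j, i, ] <- Conj(sij)
  }
  structure(list(S = S, freqs = seq(0, by = fs / wl, length.out = nf),
                 n_windows = nw, labels = labels),
            class = "cross_spectrum")
}

#' Band-averaged magnitude-squared coherence
#'
#' Per pair, averages `|S_xy(f)|^2 / (S_xx(f) S_yy(f))` over the
#' frequency bins whose centres fall in the band (edges inclusive).
#'
#' @param cs A [estimate_cross_spectra()] result.
#' @param band Hz interval, default theta `c(4, 7.5)`.
#' @return A `coherence_matrix`: symmetric labelled matrix with unit
#'   diagonal, values in `[0, 1]`.
#' @export
band_coherence <- function(cs, band = c(4, 7.5)) {
  stopifnot(inherits(cs, "cross_spectrum"))
  bins <- which(cs$freqs >= band[1] & cs$freqs <= band[2])
  if (!length(bins)) stop("no frequency bins in band")
  n <- length(cs$labels)
  cm <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- Mod(cs$S[i, j, bins])^2
    den <- Re(cs$S[i, i, bins]) * Re(cs$S[j, j, bins])
    v <- mean(num / den)
    cm[i, j] <- cm[j, i] <- min(max(v, 0), 1)
  }
  dimnames(cm) <- list(cs$labels, cs$labels)
  structure(cm, class = c("coherence_matrix", "matrix"))
}

#' The eight frontoposterior coherence clusters
#'
#' Named registry of the eight electrode-pair clusters linking frontal
#' (F3/F4/F7/F8) and posterior (P3/P4/O1/O2) sites within and between
#' hemispheres: 2 + 2 + 4 + 4 intra-hemispheric and 4 x 4
#' inter-hemispheric pairs, 28 distinct pairs in total.
#'
#' @return Named list of two-column character matrices (one row per
#'   electrode pair).
#' @export
#' @examples
#' sum(vapply(coherence_clusters(), nrow, 1L))  # 28
coherence_clusters <- function() {
  p <- function(...) matrix(c(...), ncol = 2, byrow = TRUE,
                            dimnames = list(NULL, c("e1", "e2")))
  list(
    intra_frontal        = p("F3", "F7", "F4", "F8"),
    intra_posterior      = p("P3", "O1", "P4", "O2"),
    intra_left_fp        = p("F7", "P3", "F7", "O1", "F3", "P3", "F3", "O1"),
    intra_right_fp       = p("F8", "P4", "F8", "O2", "F4", "P4", "F4", "O2"),
    inter_frontal        = p("F3", "F4", "F7", "F8", "F3", "F8", "F4", "F7"),
    inter_posterior      = p("P3", "P4", "O1", "O2", "P3", "O2", "P4", "O1"),
    inter_left_right_fp  = p("F7", "P4", "F7", "O2", "F3", "P4", "F3", "O2"),
    inter_right_left_fp  = p("F8", "P3", "F8", "O1", "F4", "P3", "F4", "O1"))
}

#' Cluster mean coherences
#'
#' Arithmetic mean of the constituent pair coherences for each of the
#' eight clusters.
#'
#' @param cm A [band_coherence()] matrix.
#' @param scheme Cluster registry, default [coherence_clusters()].
#' @return Named numeric vector of 8 means.
#' @export
cluster_means <- function(cm, scheme = coherence_clusters()) {
  labs <- rownames(cm)
  vapply(scheme, function(pairs) {
    miss <- setdiff(unique(c(pairs)), labs)
    if (length(miss)) stop("electrode not in matrix: ",
                           paste(miss, collapse = ", "))
    mean(cm[cbind(pairs[, 1], pairs[, 2])])
  }, numeric(1))
}

#' Long-form pair table of a coherence matrix
#'
#' @param cm A [band_coherence()] matrix.
#' @return Data frame `e1`, `e2`, `coherence` with the n(n-1)/2
#'   unordered pairs.
#' @export
coherence_pairs <- function(cm) {
  labs <- rownames(cm)
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  data.frame(e1 = labs[idx[, 1]], e2 = labs[idx[, 2]],
             coherence = cm[idx], stringsAsFactors = FALSE)
}

#' Per-pair pre/post coherence change map
#'
#' Paired t-test per cluster pair on post minus pre coherence across
#' matched subjects; a pair is flagged when p < alpha AND the mean
#' change is positive (a significant increase).  No multiplicity
#' adjustment is applied, matching the planned-comparison analysis.
#'
#' @param pre,post Matched lists of per-subject [band_coherence()]
#'   matrices.
#' @param scheme Cluster registry.
#' @param alpha Significance level (default 0.05).
#' @return Data frame with `cluster`, `e1`, `e2`, `mean_change`, `t`,
#'   `p`, `flagged`.
#' @export
pairwise_change_map <- function(pre, post, scheme = coherence_clusters(),
                                alpha = 0.05) {
  if (length(pre) != length(post)) stop("pre/post subject lists mismatch")
  if (length(pre) < 2) stop("need at least 2 subjects")
  rows <- lapply(names(scheme), function(cl) {
    pairs <- scheme[[cl]]
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
      a <- pairs[k, 1]; b <- pairs[k, 2]
      pv <- vapply(pre, function(m) m[a, b], numeric(1))
      qv <- vapply(post, function(m) m[a, b], numeric(1))
      d <- qv - pv
      if (stats::sd(d) == 0) {
        tt <- list(statistic = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                   p.value = if (mean(d) == 0) 1 else 0)
      } else tt <- stats::t.test(qv, pv, paired = TRUE)
      data.frame(cluster = cl, e1 = a, e2 = b, mean_change = mean(d),
                 t = unname(tt$statistic), p = tt$p.value,
                 flagged = tt$p.value < alpha && mean(d) > 0,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Write / read a labelled coherence matrix as CSV
#' @param cm Coherence matrix.
#' @param path File path.
#' @export
write_coherence_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(unclass(cm)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_coherence_csv
#' @export
read_coherence_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  structure(m, class = c("coherence_matrix", "matrix"))
}
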