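# epoch a recording end-to-end with overlapped Welch windows
coh_of <- function(rec, window_s = 2, overlap = 0.75) {
  mask <- detect_artifacts(rec)
  segs <- extract_clean_segments(rec, mask, select_all = TRUE)
  ep <- splice_and_epoch(segs, epoch_length_s = ncol(rec$samples) / rec$fs)
  band_coherence(estimate_cross_spectra(
    ep, spectral_params(window_length_s = window_s, overlap_fraction = overlap)))
}

test_that("cross-spectrum is Hermitian with non-negative real diagonal", {
  set.seed(1)
  rec <- eeg_recording(matrix(rnorm(19 * 256 * 10, sd = 20), 19), fs = 256)
  ep <- clean_recording(rec, min_total_s = 5)
  cs <- estimate_cross_spectra(ep)
  expect_equal(cs$S, Conj(aperm(cs$S, c(2, 1, 3))))
  autos <- sapply(1:19, function(i) Re(cs$S[i, i, ]))
  expect_true(all(autos >= 0))
  expect_true(all(abs(Im(sapply(1:19, function(i) cs$S[i, i, ]))) < 1e-10))
})

test_that("a pure 6 Hz sinusoid peaks at the 6 Hz bin", {
  fs <- 256; t <- seq_len(fs * 8) / fs
  x <- matrix(rep(sin(2 * pi * 6 * t), each = 19), 19) +
    matrix(rnorm(19 * fs * 8, sd = 1e-3), 19)
  ep <- clean_recording(eeg_recording(x, fs = fs), min_total_s = 5)
  cs <- estimate_cross_spectra(ep)
  auto <- Re(cs$S[1, 1, ])
  expect_equal(cs$freqs[which.max(auto)], 6)
})

test_that("duplicated channels give coherence 1; 19 channels give 171 pairs", {
  set.seed(2)
  fs <- 256
  x <- matrix(rnorm(19 * fs * 20, sd = 10), 19)
  x[2, ] <- x[1, ]                      # exact copy
  cm <- coh_of(eeg_recording(x, fs = fs))
  expect_equal(cm[1, 2], 1, tolerance = 1e-9)
  expect_equal(nrow(coherence_pairs(cm)), 171)
  expect_true(all(cm >= 0 & cm <= 1))
  expect_equal(unname(diag(cm)), rep(1, 19))
})

test_that("coherence is invariant under per-channel gain rescaling", {
  set.seed(3)
  spec <- coupling_spec(groups = list(ab = c("F3", "P3")), shared_gain = 8,
                        ind_sd = 8, noise_sd = 2, duration_s = 30)
  rec <- simulate_eeg(spec, seed = 3)
  cm1 <- coh_of(rec)
  rec$samples <- rec$samples * rep(runif(19, 0.5, 3), times = ncol(rec$samples))
  cm2 <- coh_of(rec)
  expect_equal(cm1, cm2, tolerance = 1e-9)
})

test_that("null coherence of independent channels matches the estimator bias", {
  set.seed(4)
  fs <- 256
  x <- matrix(rnorm(2 * fs * 60, sd = 10), 2)
  rec <- list(samples = x, fs = fs,
              montage = list(labels = c("A", "B")), reference = "average")
  class(rec$montage) <- "montage"; class(rec) <- "eeg_recording"
  segs <- extract_clean_segments(rec, rep(FALSE, ncol(x)), select_all = TRUE)
  ep <- splice_and_epoch(segs, epoch_length_s = 2)
  cs <- estimate_cross_spectra(ep)          # 30 non-overlapping windows
  bins <- which(cs$freqs >= 1 & cs$freqs <= 100)
  coh <- Mod(cs$S[1, 2, bins])^2 / (Re(cs$S[1, 1, bins]) * Re(cs$S[2, 2, bins]))
  expect_gt(mean(coh), 0.5 / cs$n_windows)
  expect_lt(mean(coh), 2 / cs$n_windows)
})

test_that("shared-source coherence converges to the closed form", {
  # three parameter settings, 120 s records, tolerance 0.05
  cases <- list(c(g = 10, ind = 10), c(g = 14, ind = 7), c(g = 6, ind = 12))
  for (i in seq_along(cases)) {
    cc <- cases[[i]]
    spec <- coupling_spec(groups = list(fp = c("F3", "P3")),
                          shared_gain = cc["g"], ind_sd = cc["ind"],
                          noise_sd = 2, duration_s = 120)
    rec <- simulate_eeg(spec, seed = 100L + i)
    cm <- coh_of(rec)
    expect_equal(cm["F3", "P3"],
                 expected_pair_coherence(cc["g"], cc["g"], cc["ind"]),
                 tolerance = 0.05, ignore_attr = TRUE)
  }
})

test_that("the cluster scheme has the published structure", {
  sch <- coherence_clusters()
  expect_equal(unname(vapply(sch, nrow, 1L)), c(2, 2, 4, 4, 4, 4, 4, 4))
  pairs <- do.call(rbind, sch)
  keys <- apply(pairs, 1, function(p) paste(sort(p), collapse = "-"))
  expect_equal(length(unique(keys)), 28)
  expect_true(all(c(pairs) %in% montage_1020()$labels))
})

test_that("cluster means are the arithmetic means of constituent pairs", {
  labs <- montage_1020()$labels
  cm <- matrix(0.5, 19, 19, dimnames = list(labs, labs)); diag(cm) <- 1
  expect_equal(unname(cluster_means(cm)), rep(0.5, 8))
  cm2 <- matrix(0, 19, 19, dimnames = list(labs, labs)); diag(cm2) <- 1
  cm2["F3", "F7"] <- cm2["F7", "F3"] <- 0.2
  cm2["F4", "F8"] <- cm2["F8", "F4"] <- 0.4
  expect_equal(unname(cluster_means(cm2)["intra_frontal"]), 0.3)
  # brute-force recomputation from the raw matrix
  set.seed(6)
  cm3 <- matrix(runif(361), 19, 19, dimnames = list(labs, labs))
  cm3[lower.tri(cm3)] <- t(cm3)[lower.tri(cm3)]; diag(cm3) <- 1
  sch <- coherence_clusters()
  brute <- vapply(sch, function(p)
    mean(vapply(seq_len(nrow(p)), function(k) cm3[p[k, 1], p[k, 2]], 1)), 1)
  expect_equal(cluster_means(cm3), brute)
  bad <- cm3[1:18, 1:18]
  expect_error(cluster_means(bad), "O2")
})

test_that("change map flags only significant increases", {
  labs <- montage_1020()$labels
  base <- matrix(0.4, 19, 19, dimnames = list(labs, labs)); diag(base) <- 1
  pre <- replicate(10, base, simplify = FALSE)
  expect_true(all(pairwise_change_map(pre, pre)$flagged == FALSE))
  expect_error(pairwise_change_map(pre, pre[1:5]), "mismatch")
})

test_that("change map power and type-I behaviour match expectation", {
  sch <- coherence_clusters()
  labs <- montage_1020()$labels
  n <- 18
  make_cm <- function(shift_pairs = NULL, delta = 0) {
    m <- matrix(0.4 + rnorm(361, sd = 0.05), 19, 19,
                dimnames = list(labs, labs))
    m[lower.tri(m)] <- t(m)[lower.tri(m)]; diag(m) <- 1
    if (!is.null(shift_pairs))
      for (k in seq_len(nrow(shift_pairs))) {
        a <- shift_pairs[k, 1]; b <- shift_pairs[k, 2]
        m[a, b] <- m[b, a] <- m[a, b] + delta
      }
    m
  }
  set.seed(8)
  # power: +0.1 shift on the intra-left frontoposterior pairs, noise SD 0.05
  hits <- replicate(200, {
    pre <- replicate(n, make_cm(), simplify = FALSE)
    post <- replicate(n, make_cm(sch$intra_left_fp, 0.1), simplify = FALSE)
    cmap <- pairwise_change_map(pre, post)
    all(cmap$flagged[cmap$cluster == "intra_left_fp"])
  })
  expect_gte(mean(hits), 0.95)
  # type-I: flag fraction under the null is about alpha / 2 (one-sided flag)
  set.seed(9)
  fr <- replicate(1000, {
    pre <- replicate(n, make_cm(), simplify = FALSE)
    post <- replicate(n, make_cm(), simplify = FALSE)
    mean(pairwise_change_map(pre, post)$flagged)
  })
  expect_equal(mean(fr), 0.025, tolerance = 0.2)
})

test_that("window configuration is validated", {
  expect_error(spectral_params(overlap_fraction = 1), "overlap")
  expect_error(spectral_params(band = c(8, 4)), "band")
  set.seed(10)
  rec <- eeg_recording(matrix(rnorm(19 * 512), 19), fs = 256)
  ep <- clean_recording(rec, min_total_s = 1)
  expect_error(estimate_cross_spectra(ep, spectral_params(window_length_s = 4)),
               "window longer than epoch")
  cs <- estimate_cross_spectra(ep)
  expect_error(band_coherence(cs, band = c(200, 300)), "no frequency bins")
})

test_that("coherence matrix CSV round-trip", {
  labs <- montage_1020()$labels
  m <- matrix(runif(361), 19, 19, dimnames = list(labs, labs))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]; diag(m) <- 1
  f <- tempfile(fileext = ".csv")
  write_coherence_csv(m, f)
  back <- read_coherence_csv(f)
  expect_equal(unclass(back), m, tolerance = 1e-12, ignore_attr = TRUE)
})
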