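#' @title Synthetic cohort generator
#' @description Generates complete synthetic pre/post studies: cohort
#'   tables with covariates, recall sequences produced by a
#'   softmax-weighted strategy sampler, and multichannel EEG whose
#'   theta-band coherence is controlled by a shared-source mixing
#'   model, with group-specific post-training effects injectable.
#' @name synthetic_cohort
NULL

#' Recall-strategy parameters
#'
#' Parameters of the sequential softmax sampler that emulates recall
#' behaviour: the next identification is drawn over the remaining sheet
#' items with weight `exp(gamma_sem * same-category-as-previous +
#' gamma_spa * array-adjacent-to-previous)`; each draw is a target with
#' probability `hit_probability`, otherwise a distracter intrusion;
#' recall terminates with `stop_probability` after each identification.
#'
#' @param gamma_sem Semantic clustering bias, >= 0.
#' @param gamma_spa Spatial scanning bias, >= 0.
#' @param hit_probability Probability a draw is from the remaining
#'   targets rather than distracters.
#' @param stop_probability Per-step termination probability.
#' @return A `strategy_params` list.
#' @export
strategy_params <- function(gamma_sem = 0, gamma_spa = 0,
                            hit_probability = 0.85, stop_probability = 0.05) {
  stopifnot(gamma_sem >= 0, gamma_spa >= 0,
            hit_probability >= 0, hit_probability <= 1,
            stop_probability >= 0, stop_probability <= 1)
  structure(list(gamma_sem = gamma_sem, gamma_spa = gamma_spa,
                 hit_probability = hit_probability,
                 stop_probability = stop_probability),
            class = "strategy_params")
}

#' Simulate a recall sequence
#'
#' Sequential sampling without replacement under the softmax strategy
#' model of [strategy_params()]; fully seeded.
#'
#' @param array A [build_array()] object.
#' @param params A [strategy_params()].
#' @param seed Integer seed.
#' @param distracters Distracter labels on the recognition sheet.
#' @return A [recall_record()].
#' @export
simulate_recall <- function(array, params = strategy_params(), seed = 0L,
                            distracters = paste0("dis", 1:12)) {
  stopifnot(inherits(array, "stimulus_array"),
            inherits(params, "strategy_params"))
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(as.integer(seed))
  tg <- array$items$item[array$items$is_target]
  remaining_t <- tg
  remaining_d <- distracters
  seqn <- character(0)
  prev <- NULL
  repeat {
    if (!length(remaining_t) && !length(remaining_d)) break
    use_target <- length(remaining_t) > 0 &&
      (!length(remaining_d) || stats::runif(1) < params$hit_probability)
    if (use_target) {
      w <- rep(1, length(remaining_t))
      if (!is.null(prev) && prev %in% tg) {
        pc <- item_category(array, prev)
        pp <- item_rowcol(array, prev)
        same_cat <- item_category(array, remaining_t) == pc
        rc <- item_rowcol(array, remaining_t)
        adj <- abs(rc[, "row"] - pp[1, "row"]) +
          abs(rc[, "col"] - pp[1, "col"]) == 1
        w <- exp(params$gamma_sem * same_cat + params$gamma_spa * adj)
      }
      pick <- remaining_t[sample.int(length(remaining_t), 1, prob = w)]
      remaining_t <- setdiff(remaining_t, pick)
    } else {
      pick <- remaining_d[sample.int(length(remaining_d), 1)]
      remaining_d <- setdiff(remaining_d, pick)
    }
    seqn <- c(seqn, pick)
    prev <- pick
    if (stats::runif(1) < params$stop_probability) break
  }
  recall_record(seqn, array, distracters)
}

#' Theta coupling specification for synthetic EEG
#'
#' The mixing model: every channel receives band-limited Gaussian
#' shared sources (one per named channel group) scaled by
#' `shared_gain`, an independent band-limited background of SD
#' `ind_sd` in the same band, and a broadband sensor noise floor of SD
#' `noise_sd`.  Because the shared and independent band components are
#' filtered identically, the in-band magnitude-squared coherence
#' between two channels sharing one source is
#' `(g1^2 g2^2) / ((g1^2 + ind^2) (g2^2 + ind^2))` up to the (small)
#' floor contribution; see [expected_pair_coherence()].
#'
#' @param groups Named list of electrode-label vectors; the channels of
#'   each group share one band-limited source.
#' @param shared_gain Gain (microvolt SD contributed by the shared
#'   source), recycled over groups.
#' @param ind_sd SD of the per-channel independent in-band background.
#' @param noise_sd SD of the broadband floor (> 0).
#' @param band Source band in Hz (default theta 4-7.5).
#' @param duration_s,fs Record length and sampling rate.
#' @return A `coupling_spec` list.
#' @export
coupling_spec <- function(groups = list(), shared_gain = 10,
                          ind_sd = 10, noise_sd = 2,
                          band = c(4, 7.5), duration_s = 120, fs = 256) {
  stopifnot(all(shared_gain >= 0), ind_sd >= 0, noise_sd > 0)
  structure(list(groups = groups,
                 shared_gain = rep(shared_gain, length.out = length(groups)),
                 ind_sd = ind_sd, noise_sd = noise_sd, band = band,
                 duration_s = duration_s, fs = fs), class = "coupling_spec")
}

#' Expected in-band coherence under the mixing model
#'
#' Closed form for two channels sharing a single band-limited source
#' with gains `g1`, `g2` and identically filtered independent in-band
#' backgrounds: per-bin (hence band-averaged) magnitude-squared
#' coherence `(g1 g2)^2 / ((g1^2 + ind^2)(g2^2 + ind^2))`, ignoring the
#' broadband floor.
#'
#' @param g1,g2 Shared-source gains of the two channels.
#' @param ind_sd Independent in-band background SD.
#' @return Expected coherence in `[0, 1]`.
#' @export
expected_pair_coherence <- function(g1, g2, ind_sd) {
  (g1 * g2)^2 / ((g1^2 + ind_sd^2) * (g2^2 + ind_sd^2))
}

# unit-variance band-limited Gaussian noise
band_source <- function(n, fs, band, order = 4) {
  x <- stats::rnorm(n + 4 * fs)          # pad to wash out filter edges
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)[(2 * fs + 1):(2 * fs + n)]
  y / stats::sd(y)
}

#' Simulate a multichannel EEG recording
#'
#' @param spec A [coupling_spec()].
#' @param montage A [montage_1020()] object.
#' @param seed Integer seed.
#' @param artifact_bursts Optional data frame `start_s`, `duration_s`,
#'   `amplitude` describing square bursts injected on the first channel
#'   (for artifact-rejection tests).
#' @return An [eeg_recording()] (linked-ears reference, microvolts).
#' @export
simulate_eeg <- function(spec, montage = montage_1020(), seed = 0L,
                         artifact_bursts = NULL) {
  stopifnot(inherits(spec, "coupling_spec"))
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(as.integer(seed))
  ns <- round(spec$duration_s * spec$fs)
  nch <- length(montage$labels)
  X <- matrix(stats::rnorm(nch * ns, sd = spec$noise_sd), nch, ns)
  for (c in seq_len(nch))                # independent in-band background
    X[c, ] <- X[c, ] + spec$ind_sd * band_source(ns, spec$fs, spec$band)
  if (length(spec$groups)) {
    for (k in seq_along(spec$groups)) {
      src <- spec$shared_gain[k] * band_source(ns, spec$fs, spec$band)
      ch <- match(spec$groups[[k]], montage$labels)
      if (anyNA(ch)) stop("unknown electrode in coupling group")
      X[ch, ] <- sweep(X[ch, , drop = FALSE], 2, src, `+`)
    }
  }
  if (!is.null(artifact_bursts)) {
    for (i in seq_len(nrow(artifact_bursts))) {
      a <- artifact_bursts[i, ]
      idx <- (round(a$start_s * spec$fs) + 1):
        min(ns, round((a$start_s + a$duration_s) * spec$fs))
      X[1, idx] <- a$amplitude
    }
  }
  eeg_recording(X, fs = spec$fs, montage = montage,
                reference = "linked-ears")
}

#' Simulate a complete three-arm pre/post study
#'
#' Generates a cohort table (group, age, IQ, ADI-R subscores), pre and
#' post recall records under per-group strategy parameters, and pre and
#' post EEG recordings under per-group coupling specs, with additive
#' effects injected at post only for designated groups.  The default
#' geometry mirrors a three-arm trial retaining 18/17/13 participants.
#'
#' @param n_per_group Named integer vector of retained sizes, default
#'   `c(NGT = 18, PMR = 17, control = 13)`.
#' @param effects List of effect injections, each a list with `group`
#'   and any of `delta_gamma_sem`, `delta_gamma_spa`, `delta_hit`,
#'   `delta_gain` (added to the frontoposterior shared-source gain at
#'   post).
#' @param base_strategy Baseline [strategy_params()].
#' @param base_gain,ind_sd,noise_sd Baseline coupling parameters; the
#'   shared sources connect the frontal and posterior electrode groups
#'   of each hemisphere.
#' @param duration_s,fs EEG record geometry per subject.
#' @param condition Array layout condition for the memory task.
#' @param eeg Logical: also simulate EEG (set `FALSE` for
#'   behaviour-only studies).
#' @param seed Integer master seed; all per-subject seeds derive from it.
#' @return A `synthetic_study`: `cohort` (data frame), `array`,
#'   `recall` (list with `pre`/`post` lists of records), and if
#'   requested `eeg` (`pre`/`post` lists of recordings).
#' @export
simulate_study <- function(n_per_group = c(NGT = 18, PMR = 17, control = 13),
                           effects = list(),
                           base_strategy = strategy_params(
                             gamma_sem = 0.3, gamma_spa = 0.3,
                             hit_probability = 0.7, stop_probability = 0.04),
                           base_gain = 4, ind_sd = 10, noise_sd = 2,
                           duration_s = 60, fs = 256,
                           condition = "randomized", eeg = TRUE,
                           seed = 0L) {
  if (any(n_per_group < 2)) stop("need >= 2 subjects per group")
  groups <- names(n_per_group)
  for (ef in effects)
    if (!ef$group %in% groups) stop("unknown group in effects: ", ef$group)
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(as.integer(seed))
  N <- sum(n_per_group)
  cohort <- data.frame(
    subject = sprintf("S%02d", seq_len(N)),
    group = rep(groups, times = n_per_group),
    age = round(stats::rnorm(N, 11, 3.6), 1),
    iq = round(stats::rnorm(N, 83, 21)),
    adi_social = round(stats::rnorm(N, 22, 6)),
    adi_communication = round(stats::rnorm(N, 19, 5)),
    adi_stereotyped = round(stats::rnorm(N, 6.7, 2.8)),
    stringsAsFactors = FALSE)
  arr <- build_array(condition = condition, seed = as.integer(seed))

  # one shared theta source per frontoposterior electrode pairing, so the
  # injected coupling locus is exactly the intra-hemispheric
  # frontoposterior clusters
  fp_groups <- list(left_fp1 = c("F3", "P3"), left_fp2 = c("F7", "O1"),
                    right_fp1 = c("F4", "P4"), right_fp2 = c("F8", "O2"))
  subject_effect <- function(g) {
    out <- list(strategy = base_strategy, gain = base_gain)
    for (ef in effects) if (ef$group == g) {
      sp <- out$strategy
      sp$gamma_sem <- sp$gamma_sem + (ef$delta_gamma_sem %||% 0)
      sp$gamma_spa <- sp$gamma_spa + (ef$delta_gamma_spa %||% 0)
      sp$hit_probability <- min(1, sp$hit_probability + (ef$delta_hit %||% 0))
      out$strategy <- sp
      out$gain <- out$gain + (ef$delta_gain %||% 0)
    }
    out
  }
  sub_seed <- function(i, phase, what)
    (as.integer(seed) * 1009L + i * 97L + phase * 13L + what) %% .Machine$integer.max

  rec_pre <- list(); rec_post <- list()
  eeg_pre <- list(); eeg_post <- list()
  for (i in seq_len(N)) {
    g <- cohort$group[i]
    post_par <- subject_effect(g)
    rec_pre[[i]] <- simulate_recall(arr, base_strategy,
                                    seed = sub_seed(i, 1L, 1L))
    rec_post[[i]] <- simulate_recall(arr, post_par$strategy,
                                     seed = sub_seed(i, 2L, 1L))
    if (eeg) {
      cs_pre <- coupling_spec(fp_groups, shared_gain = base_gain,
                              ind_sd = ind_sd, noise_sd = noise_sd,
                              duration_s = duration_s, fs = fs)
      cs_post <- coupling_spec(fp_groups, shared_gain = post_par$gain,
                               ind_sd = ind_sd, noise_sd = noise_sd,
                               duration_s = duration_s, fs = fs)
      eeg_pre[[i]] <- simulate_eeg(cs_pre, seed = sub_seed(i, 1L, 2L))
      eeg_post[[i]] <- simulate_eeg(cs_post, seed = sub_seed(i, 2L, 2L))
    }
  }
  out <- list(cohort = cohort, array = arr,
              recall = list(pre = rec_pre, post = rec_post), seed = seed)
  if (eeg) out$eeg <- list(pre = eeg_pre, post = eeg_post)
  structure(out, class = "synthetic_study")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic study:", nrow(x$cohort), "subjects (",
      paste(sprintf("%s=%d", names(table(x$cohort$group)),
                    table(x$cohort$group)), collapse = ", "),
      "), seed", x$seed, "\n")
  invisible(x)
}

#' Score every recall record of a study
#'
#' @param study A [simulate_study()] result.
#' @return Data frame: `subject`, `group`, `time`, and the three scores.
#' @export
score_study <- function(study) {
  one <- function(recs, time) {
    sc <- do.call(rbind, lapply(recs, score_recall))
    cbind(subject = study$cohort$subject, group = study$cohort$group,
          time = time, sc, stringsAsFactors = FALSE)
  }
  rbind(one(study$recall$pre, "pre"), one(study$recall$post, "post"))
}
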