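#' @title End-to-end pipeline
#' @description Orchestrates simulate -> clean -> score -> coherence ->
#'   localize -> stats over a synthetic study, persisting plain-file
#'   (CSV/JSON) intermediates so that every reported statistic can be
#'   recomputed and diffed.
#' @name pipeline_cli
NULL

#' Default pipeline configuration
#'
#' @param seed Master seed.
#' @param outdir Output directory.
#' @param n_per_group Retained group sizes.
#' @param effects Effect injections (see [simulate_study()]).
#' @param duration_s Per-subject EEG duration in seconds.
#' @param eeg Run the EEG stages.
#' @param localize Run the source-localization stage.
#' @param n_nodes Source-grid size for localization.
#' @return A named list accepted by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 0L, outdir = tempfile("thetamem_run_"),
                            n_per_group = c(NGT = 6, PMR = 6, control = 6),
                            effects = list(list(group = "NGT",
                                                delta_gamma_sem = 2.5,
                                                delta_hit = 0.25,
                                                delta_gain = 6)),
                            duration_s = 60, eeg = TRUE, localize = FALSE,
                            n_nodes = 30) {
  list(seed = seed, outdir = outdir, n_per_group = n_per_group,
       effects = effects, duration_s = duration_s, eeg = eeg,
       localize = localize, n_nodes = n_nodes)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unspecified fields fall back to [pipeline_config()] defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- pipeline_config()
  if (!is.null(cfg$n_per_group)) cfg$n_per_group <- unlist(cfg$n_per_group)
  utils::modifyList(base, cfg)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order on a freshly simulated study,
#' writes all intermediates under `config$outdir` (scores and cluster
#' coherences as CSV, the report as JSON) and returns the report.  A
#' stage failure aborts with an error naming the stage; outputs written
#' before the failure are retained.
#'
#' @param config A [pipeline_config()] list.
#' @return A `study_report` list: score statistics (2x3 mixed ANOVA and
#'   per-group paired t per measure), cluster-coherence statistics,
#'   28-pair change maps per group, optional ROI voxel counts, the seed
#'   and a parameter echo.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  study <- stage("simulate",
    simulate_study(n_per_group = config$n_per_group,
                   effects = config$effects,
                   duration_s = config$duration_s,
                   eeg = isTRUE(config$eeg), seed = config$seed))
  scores <- stage("score", score_study(study))
  utils::write.csv(scores, file.path(config$outdir, "scores.csv"),
                   row.names = FALSE)
  write_array_csv(study$array, file.path(config$outdir, "array.csv"))

  report <- list(package_version = as.character(utils::packageVersion("thetamem")),
                 seed = config$seed,
                 parameters = config[setdiff(names(config), "outdir")])

  report$score_stats <- stage("stats", score_statistics(scores))

  if (isTRUE(config$eeg)) {
    coh <- stage("coherence", {
      lapply(c(pre = "pre", post = "post"), function(ph)
        lapply(study$eeg[[ph]], function(rec) {
          ep <- clean_recording(rec, min_total_s = min(60, config$duration_s))
          band_coherence(estimate_cross_spectra(ep))
        }))
    })
    cl <- do.call(rbind, lapply(c("pre", "post"), function(ph)
      do.call(rbind, lapply(seq_along(coh[[ph]]), function(i)
        data.frame(subject = study$cohort$subject[i],
                   group = study$cohort$group[i], time = ph,
                   t(cluster_means(coh[[ph]][[i]])),
                   stringsAsFactors = FALSE)))))
    utils::write.csv(cl, file.path(config$outdir, "cluster_coherence.csv"),
                     row.names = FALSE)
    report$cluster_stats <- stage("stats", cluster_statistics(cl))
    report$change_maps <- stage("coherence", {
      out <- list()
      for (g in unique(study$cohort$group)) {
        idx <- which(study$cohort$group == g)
        cmapg <- pairwise_change_map(coh$pre[idx], coh$post[idx])
        utils::write.csv(cmapg,
                         file.path(config$outdir,
                                   paste0("change_map_", g, ".csv")),
                         row.names = FALSE)
        out[[g]] <- emit_line_topography(cmapg, montage_1020())
      }
      out
    })
    if (isTRUE(config$localize)) {
      report$roi_counts <- stage("localize", {
        grid <- make_source_grid(config$n_nodes)
        op <- sloreta_inverse(build_toy_leadfield(grid))
        out <- list()
        for (g in unique(study$cohort$group)) {
          idx <- which(study$cohort$group == g)
          mp <- function(recs) lapply(recs[idx], function(rec)
            localize_band_power(
              clean_recording(rec, min_total_s = min(60, config$duration_s)),
              op))
          vt <- voxel_paired_t(mp(study$eeg$pre), mp(study$eeg$post))
          utils::write.csv(vt$node_table,
                           file.path(config$outdir,
                                     paste0("source_t_", g, ".csv")),
                           row.names = FALSE)
          out[[g]] <- list(roi_counts = vt$roi_counts,
                           peak_node = vt$peak_node,
                           sign_tally = as.list(vt$sign_tally),
                           chisq = unclass(vt$chisq))
        }
        out
      })
    }
  }
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  structure(report, class = "study_report")
}

# 2x3 mixed ANOVA + per-group paired t for each memory measure
score_statistics <- function(scores) {
  measures <- c("total_recall", "semantic_clustering", "visual_scanning")
  out <- list()
  pre <- scores[scores$time == "pre", ]
  post <- scores[scores$time == "post", ]
  post <- post[match(pre$subject, post$subject), ]
  for (m in measures) {
    an <- mixed_anova_2x3(pre[[m]], post[[m]], pre$group)
    tt <- lapply(split(seq_len(nrow(pre)), pre$group), function(idx)
      unclass(paired_t(pre[[m]][idx], post[[m]][idx])))
    out[[m]] <- list(interaction = unclass(an$interaction),
                     time = unclass(an$time), group = unclass(an$group),
                     paired_t = tt)
  }
  out
}

cluster_statistics <- function(cl) {
  out <- list()
  pre <- cl[cl$time == "pre", ]
  post <- cl[cl$time == "post", ]
  post <- post[match(pre$subject, post$subject), ]
  for (m in names(coherence_clusters())) {
    an <- mixed_anova_2x3(pre[[m]], post[[m]], pre$group)
    tt <- lapply(split(seq_len(nrow(pre)), pre$group), function(idx)
      unclass(paired_t(pre[[m]][idx], post[[m]][idx])))
    out[[m]] <- list(interaction = unclass(an$interaction),
                     paired_t = tt)
  }
  out
}

#' Serialized line-topography description
#'
#' The data behind a line topographic map: scalp electrode coordinates,
#' the flagged (significantly increased) pairs, and the percentage of
#' flagged pairs among the 28 cluster pairs (1 decimal place).
#'
#' @param change_map A [pairwise_change_map()] data frame.
#' @param montage A [montage_1020()] object.
#' @return List with `electrodes`, `edges`, `n_flagged`,
#'   `percent_flagged`.
#' @export
emit_line_topography <- function(change_map, montage = montage_1020()) {
  xy <- montage_topo_xy(montage)
  fl <- change_map[change_map$flagged, c("e1", "e2", "mean_change", "t", "p")]
  rownames(fl) <- NULL
  list(electrodes = xy, edges = fl, n_flagged = nrow(fl),
       percent_flagged = round(100 * nrow(fl) / nrow(change_map), 1))
}

#' Verify a persisted report against its intermediates
#'
#' Recomputes the score and cluster statistics from the stored CSV
#' intermediates and compares them with the persisted `report.json`.
#'
#' @param outdir A [run_pipeline()] output directory.
#' @param tol Numeric tolerance for the comparison.
#' @return `TRUE` invisibly if everything matches; otherwise an error
#'   describing the first mismatch.
#' @export
verify_report <- function(outdir, tol = 1e-8) {
  rep0 <- jsonlite::read_json(file.path(outdir, "report.json"),
                              simplifyVector = TRUE)
  scores <- utils::read.csv(file.path(outdir, "scores.csv"),
                            stringsAsFactors = FALSE)
  re <- score_statistics(scores)
  for (m in names(re)) {
    a <- re[[m]]$interaction$F; b <- rep0$score_stats[[m]]$interaction$F
    if (!isTRUE(all.equal(a, b, tolerance = tol)))
      stop("mismatch in score interaction F for ", m)
  }
  cc_path <- file.path(outdir, "cluster_coherence.csv")
  if (file.exists(cc_path)) {
    cl <- utils::read.csv(cc_path, stringsAsFactors = FALSE)
    rc <- cluster_statistics(cl)
    for (m in names(rc)) {
      a <- rc[[m]]$interaction$F; b <- rep0$cluster_stats[[m]]$interaction$F
      if (!isTRUE(all.equal(a, b, tolerance = tol)))
        stop("mismatch in cluster interaction F for ", m)
    }
  }
  invisible(TRUE)
}
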