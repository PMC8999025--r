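#' Pipeline run configuration
#'
#' Collects every parameter of a cohort-level run. In \code{"synthetic"}
#' mode paired cohorts are generated per group from planted ground truth;
#' in \code{"files"} mode per-subject oxy-Hb TSVs are read from a manifest
#' written by a previous run (or assembled by hand).
#'
#' @param input_mode \code{"synthetic"} or \code{"files"}.
#' @param output_dir Directory for all artifacts (created if missing).
#' @param master_seed Seed for every random stage (mandatory in synthetic
#'   mode).
#' @param groups Synthetic mode: named list per group, each with
#'   \code{n}, \code{truth_pre}, \code{truth_post} (see
#'   [make_block_correlation()]). Defaults to the three-shift design
#'   (17/18/19 subjects) with a modest post-shift connectivity decrease in
#'   the morning and afternoon groups and an increase in the night group.
#' @param manifest Files mode: path to a run manifest JSON.
#' @param duration_s,fs,noise,hemo_sd Recording parameters for synthesis.
#' @param as_intensity Synthesize raw intensities and run the full
#'   preprocessing chain (slower); otherwise simulated oxy-Hb series are
#'   analyzed directly.
#' @param wavelet,mbll_p Preprocessing parameters.
#' @param threshold Absolute correlation cut for the binary network
#'   (default 0.7).
#' @param sweep Density grid for the metric sweep.
#' @param fdr_q Edge-wise FDR level.
#' @param n_null Null networks per small-world evaluation.
#' @return A validated \code{run_config} list.
#' @export
run_config <- function(input_mode = c("synthetic", "files"),
                       output_dir, master_seed = NULL, groups = NULL,
                       manifest = NULL, duration_s = 300, fs = 7.4074,
                       noise = noise_spec(), hemo_sd = 1e-3,
                       as_intensity = TRUE,
                       wavelet = wavelet_params(), mbll_p = mbll_params(),
                       threshold = 0.7, sweep = seq(0.1, 0.9, by = 0.1),
                       fdr_q = 0.05, n_null = 100) {
  input_mode <- match.arg(input_mode)
  if (input_mode == "synthetic") {
    if (is.null(master_seed))
      stopf("master_seed is mandatory in synthetic mode",
            class = "rsfnirs_config_error")
    if (is.null(groups)) groups <- default_synthetic_groups()
  } else {
    if (is.null(manifest) || !file.exists(manifest))
      stopf("files mode requires an existing manifest: %s",
            if (is.null(manifest)) "<missing>" else manifest,
            class = "rsfnirs_config_error")
  }
  structure(list(input_mode = input_mode, output_dir = output_dir,
                 master_seed = master_seed, groups = groups,
                 manifest = manifest, duration_s = duration_s, fs = fs,
                 noise = noise, hemo_sd = hemo_sd,
                 as_intensity = as_intensity, wavelet = wavelet,
                 mbll_p = mbll_p, threshold = threshold, sweep = sweep,
                 fdr_q = fdr_q, n_null = n_null),
            class = "run_config")
}

# three-shift default design: planted within-ROI decrease for morning and
# afternoon, increase for night
default_synthetic_groups <- function() {
  list(
    morning = list(n = 17,
                   truth_pre = make_block_correlation(within_r = 0.8, between_r = 0.3),
                   truth_post = make_block_correlation(within_r = 0.6, between_r = 0.3)),
    afternoon = list(n = 18,
                     truth_pre = make_block_correlation(within_r = 0.8, between_r = 0.3),
                     truth_post = make_block_correlation(within_r = 0.6, between_r = 0.3)),
    night = list(n = 19,
                 truth_pre = make_block_correlation(within_r = 0.6, between_r = 0.3),
                 truth_post = make_block_correlation(within_r = 0.8, between_r = 0.3))
  )
}

#' Run the full connectivity pipeline for every group
#'
#' Per subject and session: oxy-Hb TSV and connectivity TSV. Per group and
#' session: group-mean connectivity, the 0.7-threshold binary network
#' (.edge export), the metric sweep table, and a small-world summary at
#' each sweep density. Per group: edge-wise paired tests (TSV sorted by p),
#' the mean-connectivity paired test, and nodal paired comparisons of
#' betweenness and nodal local efficiency. A JSON manifest records every
#' parameter and seed needed to reproduce the run; a log file records
#' per-stage timings.
#'
#' @param config A \code{run_config}.
#' @return Invisible list of per-group summaries (group-mean matrices,
#'   test results, sweep profiles, small-world results, file index).
#' @export
run_pipeline <- function(config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run.log")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  cat("", file = log_path)
  montage <- load_default_montage()
  t_start <- Sys.time()
  logf("stage=start mode=%s seed=%s", config$input_mode,
       format(config$master_seed))

  subjects_by_group <- gather_subject_hb(config, logf)

  summaries <- list()
  for (gname in names(subjects_by_group)) {
    t_g <- Sys.time()
    subj <- subjects_by_group[[gname]]
    gdir <- file.path(config$output_dir, gname)
    dir.create(gdir, showWarnings = FALSE)

    mats <- list(pre = list(), post = list())
    for (i in seq_along(subj)) {
      for (sess in c("pre", "post")) {
        hb <- subj[[i]][[sess]]
        write_hb_tsv(hb, file.path(gdir, sprintf("%s_%s_oxy.tsv",
                                                 hb$subject_id, sess)))
        cm <- cor_matrix(hb)
        cm$group_label <- gname
        write_cor_tsv(cm, file.path(gdir, sprintf("%s_%s_cor.tsv",
                                                  hb$subject_id, sess)))
        mats[[sess]][[i]] <- cm
      }
    }

    group_mean <- lapply(mats, group_mean_cor, group_label = gname)
    sweeps <- list()
    smallworld_rows <- list()
    for (sess in c("pre", "post")) {
      write_cor_tsv(group_mean[[sess]],
                    file.path(gdir, sprintf("group_mean_cor_%s.tsv", sess)))
      bn <- binarize(group_mean[[sess]], config$threshold)
      write_brainnet_edge(bn, file.path(gdir, sprintf("network_r%g_%s.edge",
                                                      config$threshold, sess)))
      write_brainnet_node(montage,
                          file.path(gdir, sprintf("network_%s.node", sess)),
                          size = pmax(rowSums(bn$adjacency), 1))
      sw_profile <- metric_sweep(group_mean[[sess]], config$sweep)
      sweeps[[sess]] <- sw_profile
      utils::write.table(sw_profile$scalar,
                         file.path(gdir, sprintf("metric_sweep_%s.tsv", sess)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      for (k in seq_along(config$sweep)) {
        net_k <- density_threshold(group_mean[[sess]], config$sweep[k])
        sw <- small_worldness(net_k, n_null = config$n_null,
                              seed = derive_seed(config$master_seed %||% 0,
                                                 match(gname, names(subjects_by_group)),
                                                 match(sess, c("pre", "post")), k))
        smallworld_rows[[length(smallworld_rows) + 1]] <-
          data.frame(group = gname, session = sess, T = config$sweep[k],
                     Cnet = sw$Cnet, Lnet = sw$Lnet, Cran = sw$Cran,
                     Lran = sw$Lran, gamma = sw$gamma, lambda = sw$lambda,
                     sigma = sw$sigma)
      }
    }
    smallworld <- do.call(rbind, smallworld_rows)
    utils::write.table(smallworld, file.path(gdir, "small_world.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    samples <- paired_edge_samples(mats$pre, mats$post, group_label = gname)
    edge_tests <- edgewise_paired_test(samples, q = config$fdr_q)
    write_edge_test_tsv(edge_tests, file.path(gdir, "edge_tests.tsv"), montage)
    mean_test <- mean_cor_paired_test(mats$pre, mats$post)

    profiles <- list(
      pre = lapply(mats$pre, metric_sweep, thresholds = config$sweep),
      post = lapply(mats$post, metric_sweep, thresholds = config$sweep)
    )
    nodal <- list(
      betweenness = nodal_group_comparison(profiles$pre, profiles$post,
                                           "betweenness"),
      nodal_eloc = nodal_group_comparison(profiles$pre, profiles$post,
                                          "nodal_eloc")
    )
    for (nm in names(nodal))
      utils::write.table(nodal[[nm]],
                         file.path(gdir, sprintf("nodal_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)

    logf("stage=group group=%s n=%d elapsed_s=%.2f", gname, length(subj),
         as.numeric(Sys.time() - t_g, units = "secs"))
    summaries[[gname]] <- list(group_mean = group_mean,
                               mean_cor_test = mean_test,
                               edge_tests = edge_tests,
                               sweeps = sweeps, smallworld = smallworld,
                               nodal = nodal, dir = gdir)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("rsfnirs")),
    r_version = R.version.string,
    input_mode = config$input_mode,
    master_seed = config$master_seed,
    duration_s = config$duration_s, fs = config$fs,
    as_intensity = config$as_intensity,
    threshold = config$threshold, sweep = config$sweep,
    fdr_q = config$fdr_q, n_null = config$n_null,
    noise = unclass(config$noise),
    wavelet = unclass(config$wavelet),
    dpf = config$mbll_p$dpf, separation_mm = config$mbll_p$separation_mm,
    groups = lapply(names(subjects_by_group), function(g) list(
      name = g, n = length(subjects_by_group[[g]]),
      subjects = vapply(subjects_by_group[[g]],
                        function(s) s$pre$subject_id, character(1))
    ))
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("stage=done elapsed_s=%.2f", as.numeric(Sys.time() - t_start, units = "secs"))
  invisible(summaries)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Resolve per-group lists of subjects (each list(pre=, post=) hb_timeseries)
# for both input modes.
gather_subject_hb <- function(config, logf) {
  if (config$input_mode == "synthetic") {
    out <- list()
    for (gi in seq_along(config$groups)) {
      gname <- names(config$groups)[gi]
      g <- config$groups[[gi]]
      t0 <- Sys.time()
      cohort <- generate_paired_cohort(
        n_subjects = g$n, truth_pre = g$truth_pre, truth_post = g$truth_post,
        duration_s = config$duration_s, fs = config$fs, noise = config$noise,
        seed = derive_seed(config$master_seed, 104729, gi),
        group_label = c("morning", "afternoon", "night")[
          max(1, min(3, gi))],
        as_intensity = config$as_intensity, hemo_sd = config$hemo_sd)
      out[[gname]] <- lapply(cohort$subjects, function(s) {
        if (config$as_intensity)
          list(pre = preprocess_subject(s$pre, config$wavelet, config$mbll_p),
               post = preprocess_subject(s$post, config$wavelet, config$mbll_p))
        else s
      })
      logf("stage=synthesize group=%s n=%d elapsed_s=%.2f", gname, g$n,
           as.numeric(Sys.time() - t0, units = "secs"))
    }
    out
  } else {
    man <- jsonlite::read_json(config$manifest, simplifyVector = FALSE)
    base <- dirname(config$manifest)
    out <- list()
    for (g in man$groups) {
      files <- lapply(g$files, unlist)
      out[[g$name]] <- lapply(seq_along(files$pre), function(i) {
        for (f in c(files$pre[i], files$post[i]))
          if (!file.exists(file.path(base, f)))
            stopf("missing input file: %s", file.path(base, f),
                  class = "rsfnirs_data_error")
        list(pre = read_hb_tsv(file.path(base, files$pre[i])),
             post = read_hb_tsv(file.path(base, files$post[i])))
      })
      logf("stage=load group=%s n=%d", g$name, length(files$pre))
    }
    out
  }
}

#' Write a files-mode manifest for a directory of oxy-Hb TSVs
#'
#' Helper to drive [run_pipeline()] in \code{"files"} mode from the
#' per-subject TSVs of a previous run: records, per group, matched lists
#' of pre/post file paths (relative to the manifest location).
#'
#' @param groups Named list; each element a list with \code{pre} and
#'   \code{post} character vectors of file paths.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_files_manifest <- function(groups, path) {
  man <- list(groups = lapply(names(groups), function(g)
    list(name = g, files = groups[[g]])))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
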