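#' Configuration for the full analysis pipeline
#'
#' Collects every tunable of the preprocessing, connectivity, graph and
#' inference stages. Defaults follow the standard resting-state protocol:
#' five bands, a 5--100% density grid in steps of 5%, local measures and
#' clinical correlations at 30% density, 10000 permutations, and an
#' edge-wise NBS threshold of t = 2.61.
#'
#' @param input_dir,output_dir Optional directories; `run_pipeline()` reads
#'   recordings/metadata from `input_dir` when no cohort is supplied, and
#'   writes result tables to `output_dir` when it is non-NULL.
#' @param preprocess A [preprocess_config()].
#' @param bands Band labels to analyse.
#' @param densities Density grid for the global-metric sweep.
#' @param p_ref,n_ref,metric SL parameters, see [embed_parameters()] and
#'   [sl_pair()].
#' @param n_perm Permutations for every permutation test.
#' @param t_threshold NBS edge threshold; if NULL it is derived as
#'   [critical_t()] of `nbs_tail_p` at the cohort's df.
#' @param nbs_tail_p One-tailed p for the derived threshold (default
#'   0.005).
#' @param local_density Density at which nodal metrics, normalized metrics
#'   and clinical correlations are computed (default 0.30).
#' @param n_surrogates Surrogate ensemble size for [normalized_metrics()].
#' @param alpha Nominal significance level recorded in the report.
#' @param seed Master seed for every stochastic stage.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(input_dir = NULL, output_dir = NULL,
                            preprocess = preprocess_config(),
                            bands = names(eeg_bands()),
                            densities = seq(0.05, 1, by = 0.05),
                            p_ref = 0.01, n_ref = 10,
                            metric = "euclidean",
                            n_perm = 10000L, t_threshold = NULL,
                            nbs_tail_p = 0.005,
                            local_density = 0.30, n_surrogates = 50L,
                            alpha = 0.05, seed = 1L) {
  if (any(densities <= 0 | densities > 1))
    stop("density grid must lie in (0, 1]")
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 preprocess = preprocess, bands = bands,
                 densities = densities, p_ref = p_ref, n_ref = n_ref,
                 metric = metric, n_perm = as.integer(n_perm),
                 t_threshold = t_threshold, nbs_tail_p = nbs_tail_p,
                 local_density = local_density,
                 n_surrogates = as.integer(n_surrogates), alpha = alpha,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the complete resting-EEG network analysis
#'
#' Executes preprocess -> SL connectivity -> density-thresholded graph
#' metrics -> group statistics for every subject and band: per-band mean-SL
#' permutation tests (covariates age, sex, IQ), NBS on edge-wise SL, global
#' metrics over the density grid with per-density permutation tests,
#' nodal metrics and surrogate-normalized metrics at `local_density`, and
#' partial correlations of patient network metrics with MADRS/YMRS.
#' Deterministic under the config seed.
#'
#' @param config An [analysis_config()].
#' @param cohort Optional list with `recordings` and `meta` (as returned
#'   by [generate_cohort()]); when NULL, recordings are read from
#'   `config$input_dir` (delimited files listed in `metadata.csv`).
#' @param progress Print stage messages.
#' @return A list of result tables: `mean_sl` (per subject/band),
#'   `mean_sl_tests`, `nbs` (per band), `global_metrics`,
#'   `global_metric_tests`, `nodal_metrics`, `nodal_tests`,
#'   `normalized`, `correlations`, `demographics`, plus the `config`.
#'   Tables are also written as CSV (and a JSON report) to
#'   `config$output_dir` when set.
#' @export
run_pipeline <- function(config = analysis_config(), cohort = NULL,
                         progress = FALSE) {
  say <- function(...) if (progress) message(...)
  if (is.null(cohort)) {
    if (is.null(config$input_dir)) stop("no cohort and no input_dir")
    meta <- read_metadata(file.path(config$input_dir, "metadata.csv"))
    recordings <- lapply(meta$subject_id, function(id)
      read_recording(file.path(config$input_dir, paste0(id, ".tsv")),
                     "delimited", subject_id = id))
    cohort <- list(recordings = recordings, meta = meta)
  }
  meta <- cohort$meta
  n_sub <- nrow(meta)
  groups <- factor(meta$group, levels = c("control", "patient"))
  # age/sex/IQ adjustment needs enough residual df to be meaningful
  covars <- if (n_sub >= 12) meta[, c("age", "sex", "iq")] else NULL
  cfg_pp <- config$preprocess

  say("preprocess + SL connectivity (", n_sub, " subjects, ",
      length(config$bands), " bands)")
  params <- lapply(config$bands, function(b) {
    e <- cfg_pp$bands[[b]]
    embed_parameters(e[1], e[2], cfg_pp$target_fs, config$p_ref, config$n_ref)
  })
  names(params) <- config$bands
  sl <- lapply(seq_len(n_sub), function(i) {
    eps <- preprocess_recording(cohort$recordings[[i]], cfg_pp, config$bands)
    out <- lapply(config$bands, function(b)
      sl_matrix(eps[[b]], params[[b]], config$metric,
                subject_id = meta$subject_id[i], band = b))
    names(out) <- config$bands
    out
  })

  mean_sl_tab <- do.call(rbind, lapply(seq_len(n_sub), function(i)
    data.frame(subject_id = meta$subject_id[i], group = meta$group[i],
               band = config$bands,
               mean_sl = vapply(sl[[i]], mean_sl, numeric(1)),
               stringsAsFactors = FALSE)))

  say("mean-SL permutation tests")
  mean_sl_tests <- do.call(rbind, lapply(config$bands, function(b) {
    v <- mean_sl_tab$mean_sl[mean_sl_tab$band == b]
    pr <- permutation_test(v, groups, covars, config$n_perm,
                           seed = config$seed + 11L)
    data.frame(band = b, observed_t = pr$observed_t, p_value = pr$p_value,
               stringsAsFactors = FALSE)
  }))

  say("network-based statistics")
  tthr <- config$t_threshold %||% critical_t(config$nbs_tail_p, n_sub - 2L)
  nbs_res <- lapply(config$bands, function(b)
    nbs(lapply(sl, function(s) unclass(s[[b]])), groups,
        t_threshold = tthr, n_perm = config$n_perm,
        seed = config$seed + 13L))
  names(nbs_res) <- config$bands

  say("global metrics over the density grid")
  gm <- do.call(rbind, lapply(seq_len(n_sub), function(i)
    do.call(rbind, lapply(config$bands, function(b)
      do.call(rbind, lapply(config$densities, function(d) {
        g <- global_metrics(threshold_by_density(sl[[i]][[b]], d))
        data.frame(subject_id = meta$subject_id[i], group = meta$group[i],
                   band = b, density = d, C = g$C, L = g$L, Eg = g$Eg,
                   stringsAsFactors = FALSE)
      }))))))

  global_metric_tests <- do.call(rbind, lapply(config$bands, function(b)
    do.call(rbind, lapply(config$densities, function(d) {
      sub <- gm[gm$band == b & gm$density == d, ]
      do.call(rbind, lapply(c("C", "L", "Eg"), function(mname) {
        pr <- permutation_test(sub[[mname]], groups, covars, config$n_perm,
                               seed = config$seed + 17L)
        data.frame(band = b, density = d, metric = mname,
                   observed_t = pr$observed_t, p_value = pr$p_value,
                   stringsAsFactors = FALSE)
      }))
    }))))

  say("nodal and normalized metrics at ", config$local_density, " density")
  nm <- do.call(rbind, lapply(seq_len(n_sub), function(i)
    do.call(rbind, lapply(config$bands, function(b) {
      net <- threshold_by_density(sl[[i]][[b]], config$local_density)
      cbind(data.frame(subject_id = meta$subject_id[i],
                       group = meta$group[i], band = b,
                       density = config$local_density,
                       stringsAsFactors = FALSE),
            nodal_metrics(net))
    }))))
  nodal_tests <- do.call(rbind, lapply(config$bands, function(b)
    do.call(rbind, lapply(unique(nm$node), function(nd) {
      sub <- nm[nm$band == b & nm$node == nd, ]
      do.call(rbind, lapply(c("strength", "betweenness", "local_eff"),
                            function(mname) {
        pr <- permutation_test(sub[[mname]], groups, covars, config$n_perm,
                               seed = config$seed + 19L)
        data.frame(band = b, node = nd, metric = mname,
                   observed_t = pr$observed_t, p_value = pr$p_value,
                   stringsAsFactors = FALSE)
      }))
    }))))

  norm_tab <- do.call(rbind, lapply(seq_len(n_sub), function(i)
    do.call(rbind, lapply(config$bands, function(b) {
      net <- threshold_by_density(sl[[i]][[b]], config$local_density)
      nmx <- normalized_metrics(net, config$n_surrogates,
                                seed = config$seed + 23L + i)
      data.frame(subject_id = meta$subject_id[i], group = meta$group[i],
                 band = b, gamma = nmx$gamma, lambda = nmx$lambda,
                 sigma = nmx$sigma, stringsAsFactors = FALSE)
    }))))

  say("clinical correlations")
  pat <- meta$group == "patient"
  correlations <- NULL
  if (sum(pat) >= 6 && any(meta$madrs[pat] != meta$madrs[pat][1])) {
    correlations <- do.call(rbind, lapply(config$bands, function(b) {
      ml <- merge(gm[gm$band == b & gm$density == config$local_density, ],
                  norm_tab[norm_tab$band == b, ],
                  by = c("subject_id", "group", "band"))
      ml <- ml[match(meta$subject_id, ml$subject_id), ]
      do.call(rbind, lapply(c("C", "L", "Eg", "gamma", "lambda", "sigma"),
                            function(mname) {
        do.call(rbind, lapply(c("madrs", "ymrs"), function(sc) {
          cr <- partial_correlation(
            ml[[mname]][pat], meta[[sc]][pat],
            if (is.null(covars)) NULL else covars[pat, , drop = FALSE])
          data.frame(band = b, metric = mname, score = sc, r = cr$r,
                     p_value = cr$p_value, n = cr$n,
                     stringsAsFactors = FALSE)
        }))
      }))
    }))
  }

  report <- list(mean_sl = mean_sl_tab, mean_sl_tests = mean_sl_tests,
                 nbs = nbs_res, global_metrics = gm,
                 global_metric_tests = global_metric_tests,
                 nodal_metrics = nm, nodal_tests = nodal_tests,
                 normalized = norm_tab, correlations = correlations,
                 # degenerate for very small cohorts (empty sex cells)
                 demographics = tryCatch(demographic_tests(meta),
                                         error = function(e) NULL),
                 t_threshold = tthr, config = config)
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("mean_sl", "mean_sl_tests", "global_metrics",
            "global_metric_tests", "nodal_metrics", "nodal_tests",
            "normalized", "correlations", "demographics")
  for (tb in tabs)
    if (!is.null(report[[tb]]))
      utils::write.csv(report[[tb]], file.path(dir, paste0(tb, ".csv")),
                       row.names = FALSE)
  nbs_sum <- lapply(report$nbs, function(r)
    list(t_threshold = r$t_threshold,
         n_suprathreshold_edges = nrow(r$edges),
         component_sizes = r$component_sizes,
         corrected_p = r$corrected_p))
  jsonlite::write_json(
    list(seed = report$config$seed, n_perm = report$config$n_perm,
         t_threshold = report$t_threshold,
         bands = report$config$bands, densities = report$config$densities,
         local_density = report$config$local_density, nbs = nbs_sum),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
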