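# End-to-end orchestration: simulate/load -> preprocess -> fit -> cluster ->
# evaluate, the repeated-run benchmark battery behind the summary tables,
# and the HVG sensitivity sweep.

#' Run the full pipeline once
#'
#' Executes preprocess -> self-paced fit -> K-means -> metrics on a count
#' matrix (simulating one first if \code{counts} is a [sim_params()]).
#' When \code{out_dir} is given, intermediates are persisted as TSV plus a
#' JSON manifest recording the configuration, seed and config checksum, so
#' a rerun with the same configuration reproduces identical artifacts.
#'
#' @param counts a [count_matrix()], or a [sim_params()] to simulate from.
#' @param pre_cfg a [preprocess_config()].
#' @param spac_cfg a [spac_config()].
#' @param K number of clusters (defaults to \code{spac_cfg$r}).
#' @param out_dir optional directory for artifacts.
#' @return list with \code{metrics} (a \code{MetricReport}, or \code{NULL}
#'   when no labels are available), \code{fit}, \code{clusters},
#'   \code{processed}.
#' @export
run_pipeline <- function(counts, pre_cfg = preprocess_config(),
                         spac_cfg = spac_config(), K = spac_cfg$r,
                         out_dir = NULL) {
  if (inherits(counts, "SimParams")) counts <- simulate_counts(counts)
  validate_count_matrix(counts)
  pm <- preprocess_pipeline(counts, pre_cfg)
  fit <- spac_fit(pm, spac_cfg)
  cl <- kmeans_embed(fit$factors, K, seed = spac_cfg$seed)
  mr <- if (!is.null(pm$labels)) metric_report(cl, pm$labels) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(fit$history, file.path(out_dir, "history.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(cell = pm$cell_ids, cluster = cl$assignments),
      file.path(out_dir, "assignments.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(mr))
      utils::write.table(
        data.frame(ari = mr$ari, purity = mr$purity, nmi = mr$nmi, N = mr$N),
        file.path(out_dir, "metrics.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    cfg_all <- list(preprocess = unclass(pre_cfg),
                    spac = unclass(spac_cfg), K = K)
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(cfg_all, cfg_path, auto_unbox = TRUE, digits = NA)
    manifest <- list(
      package_version = as.character(utils::packageVersion("scSPaC")),
      r_version = as.character(getRversion()),
      seed = spac_cfg$seed,
      config_md5 = unname(tools::md5sum(cfg_path)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  list(metrics = mr, fit = fit, clusters = cl, processed = pm)
}

#' Repeated-run clustering benchmark
#'
#' The experiment behind the summary tables: for each seed, simulate (or
#' reuse) a labeled count matrix, preprocess it once, and evaluate every
#' requested method against the ground truth. Methods: \code{"scSPaC"}
#' (Frobenius norm, self-paced), \code{"sscSPaC"} (l21 norm, self-paced),
#' \code{"NMF"} (plain unweighted factorization + K-means), and
#' \code{"kmeans"} (K-means directly on the preprocessed cell profiles).
#'
#' @param params a [sim_params()] whose \code{seed} is replaced per run, or
#'   a fixed [count_matrix()] reused across runs (method seeds still vary).
#' @param n_runs number of repetitions (default 20).
#' @param seeds integer vector of seeds, one per run (default
#'   \code{seq_len(n_runs)}).
#' @param pre_cfg a [preprocess_config()].
#' @param spac_cfg a [spac_config()]; its seed is replaced per run.
#' @param K number of clusters.
#' @param methods subset of \code{c("scSPaC", "sscSPaC", "NMF", "kmeans")}.
#' @param nmf_iters update steps for the plain-NMF baseline (default 300,
#'   about the total update budget of a self-paced fit).
#' @param outliers optional list with \code{n} and \code{intensity}; when
#'   given, [plant_outliers()] corrupts each simulated matrix before
#'   preprocessing.
#' @return list with \code{runs} (one row per run x method: seed, method,
#'   ari, purity, nmi) and \code{summary} (per method: mean and sd of each
#'   metric, on the 0-100 percent scale).
#' @export
benchmark_battery <- function(params = sim_params(), n_runs = 20L,
                              seeds = seq_len(n_runs),
                              pre_cfg = preprocess_config(),
                              spac_cfg = spac_config(), K = spac_cfg$r,
                              methods = c("scSPaC", "sscSPaC", "NMF",
                                          "kmeans"),
                              nmf_iters = 300L, outliers = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (s in seeds) {
    cm <- if (inherits(params, "SimParams")) {
      p <- params; p$seed <- as.integer(s)
      simulate_counts(p)
    } else params
    if (!is.null(outliers))
      cm <- plant_outliers(cm, outliers$n, outliers$intensity, seed = s)
    if (is.null(cm$labels)) stop("benchmark requires ground-truth labels")
    pm <- preprocess_pipeline(cm, pre_cfg)
    for (meth in methods) {
      pred <- switch(
        meth,
        scSPaC = {
          cfg <- spac_cfg; cfg$norm <- "frobenius"; cfg$seed <- as.integer(s)
          kmeans_embed(spac_fit(pm, cfg)$factors, K, seed = s)
        },
        sscSPaC = {
          cfg <- spac_cfg; cfg$norm <- "l21"; cfg$seed <- as.integer(s)
          kmeans_embed(spac_fit(pm, cfg)$factors, K, seed = s)
        },
        NMF = {
          f <- nmf_fit(pm, spac_cfg$r, n_iter = nmf_iters, seed = s,
                       trace_every = 0L)
          kmeans_embed(f$factors, K, seed = s)
        },
        kmeans = kmeans_embed(t(pm$X), K, seed = s)
      )
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, method = meth,
        ari = ari(pred$assignments, pm$labels),
        purity = purity(pred$assignments, pm$labels),
        nmi = nmi(pred$assignments, pm$labels))
    }
  }
  runs <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(runs, runs$method), function(d)
    data.frame(method = d$method[1L],
               ari_mean = 100 * mean(d$ari), ari_sd = 100 * stats::sd(d$ari),
               purity_mean = 100 * mean(d$purity),
               purity_sd = 100 * stats::sd(d$purity),
               nmi_mean = 100 * mean(d$nmi), nmi_sd = 100 * stats::sd(d$nmi))))
  rownames(summ) <- NULL
  summ <- summ[match(intersect(methods, summ$method), summ$method), ]
  list(runs = runs, summary = summ)
}

#' Sensitivity of clustering accuracy to the number of HVGs
#'
#' Reruns the benchmark battery once per requested HVG count, with the same
#' seeds throughout, and reports mean and sd ARI per setting.
#'
#' @param hvg_list HVG counts to test (default
#'   \code{c(200, 500, 1000, 1500, 2000, 2500)}).
#' @inheritParams benchmark_battery
#' @param method single method to sweep (default \code{"scSPaC"}).
#' @return data.frame with one row per HVG count, in input order:
#'   \code{n_hvg}, \code{ari_mean}, \code{ari_sd} (percent scale).
#' @export
hvg_sweep <- function(params = sim_params(),
                      hvg_list = c(200L, 500L, 1000L, 1500L, 2000L, 2500L),
                      n_runs = 20L, seeds = seq_len(n_runs),
                      pre_cfg = preprocess_config(),
                      spac_cfg = spac_config(), K = spac_cfg$r,
                      method = "scSPaC") {
  rows <- lapply(hvg_list, function(nh) {
    cfg <- pre_cfg; cfg$n_hvg <- as.integer(nh)
    b <- benchmark_battery(params, n_runs = n_runs, seeds = seeds,
                           pre_cfg = cfg, spac_cfg = spac_cfg, K = K,
                           methods = method)
    data.frame(n_hvg = nh, ari_mean = b$summary$ari_mean,
               ari_sd = b$summary$ari_sd)
  })
  do.call(rbind, rows)
}
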