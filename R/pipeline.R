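#' Pipeline configuration
#'
#' Assembles the configuration for [run_all()]: the synthetic cohort design
#' (or paths to user data), model settings, clustering and differential
#' parameters, stage toggles and the master seed from which every stage seed
#' is derived.
#'
#' @param out_dir output directory for tables and the run manifest.
#' @param design a [cohort_design()] (used when `simulate` is on).
#' @param n_features synthetic panel size.
#' @param stages named logical list toggling `simulate`, `seasonality`,
#'   `clustering`, `projection`, `differential`, `diversity`.
#' @param p_threshold seasonality cutoff for clustering input.
#' @param k_range,fuzzifier,n_restarts clustering parameters.
#' @param B,grid_size,alpha,perm_unit differential parameters.
#' @param seed master seed.
#' @param model a [model_spec()].
#' @param diff_model a [model_spec()] for the differential stage.
#' @param input_data,input_visits optional paths to long-format TSVs to use
#'   instead of simulating.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = "results", design = cohort_design(),
                            n_features = 200,
                            stages = list(),
                            p_threshold = 0.05, k_range = 2:10,
                            fuzzifier = 2, n_restarts = 10,
                            B = 200, grid_size = 52, alpha = 0.05,
                            perm_unit = "subject", seed = 1,
                            model = model_spec(),
                            diff_model = differential_model_spec(),
                            input_data = NULL, input_visits = NULL) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  st <- utils::modifyList(
    list(simulate = TRUE, seasonality = TRUE, clustering = TRUE,
         projection = TRUE, differential = TRUE, diversity = TRUE), stages)
  structure(list(out_dir = out_dir, design = design, n_features = n_features,
                 stages = st, p_threshold = p_threshold, k_range = k_range,
                 fuzzifier = fuzzifier, n_restarts = n_restarts, B = B,
                 grid_size = grid_size, alpha = alpha, perm_unit = perm_unit,
                 seed = seed, model = model, diff_model = diff_model,
                 input_data = input_data, input_visits = input_visits),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields of [pipeline_config()] may be set in a YAML file; nested
#' `model` / `diff_model` blocks are passed to [model_spec()] /
#' [differential_model_spec()], and a `design` block to [cohort_design()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$design)) args$design <- do.call(cohort_design, y$design)
  if (!is.null(y$model)) args$model <- do.call(model_spec, y$model)
  if (!is.null(y$diff_model))
    args$diff_model <- do.call(differential_model_spec, y$diff_model)
  if (!is.null(y$k_range) && length(y$k_range) == 2)
    args$k_range <- y$k_range[1]:y$k_range[2]
  do.call(pipeline_config, args)
}

#' Run the full seasonality analysis pipeline
#'
#' Orchestrates simulate -> per-feature seasonality fits -> fuzzy pattern
#' clustering (+ projection of external streams) -> interval-wise IR/IS
#' differential testing -> microbial richness seasonality, writing one TSV
#' per output contract into `config$out_dir` and a run manifest recording
#' seeds, per-stage row counts, runtimes and output checksums. Reruns with
#' the same configuration and seed reproduce the checksums. A stage failure
#' aborts with a stage-named error and leaves a `FAILED` marker file.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_all <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("seasonomics")),
                   seed = config$seed, stages = list())
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, enabled, fun) {
    if (!enabled) return(invisible(NULL))
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- c(res, list(
      runtime_sec = round(as.numeric(Sys.time() - t0, units = "secs"), 2)))
    invisible(NULL)
  }
  emit <- function(x, file) {
    write_tsv(x, file.path(config$out_dir, file))
    message(sprintf("  wrote %s (%d rows)", file, nrow(x)))
    nrow(x)
  }

  run_stage("simulate", config$stages$simulate, function() {
    message("stage simulate")
    design <- config$design
    sim <- simulate_cohort(design, default_feature_specs(config$n_features),
                           taxa = TRUE, seed = config$seed)
    state$sim <- sim
    list(n_visits = emit(sim$visits, "visits.tsv"),
         n_values = emit(sim$data[c("sample_id", "feature_id", "ome", "value")],
                         "feature_values.tsv"),
         n_truth = emit(sim$truth, "ground_truth.tsv"))
  })

  if (is.null(state$sim) && !is.null(config$input_data)) {
    state$sim <- list(visits = read_visits(config$input_visits),
                      data = read_feature_table(config$input_data))
  }

  run_stage("seasonality", config$stages$seasonality, function() {
    message("stage seasonality")
    sim <- state$sim
    if (is.null(sim)) stopf("no input data (enable simulate or provide input_data)")
    scan <- seasonality_scan(sim$data[c("sample_id", "feature_id", "ome", "value")],
                             sim$visits, config$model)
    state$scan <- scan
    n_sig <- sum(scan$table$p_value <= config$p_threshold, na.rm = TRUE)
    message(sprintf("  %d/%d features with p <= %.3g", n_sig,
                    nrow(scan$table), config$p_threshold))
    curves <- do.call(rbind, lapply(scan$fits, function(f)
      if (inherits(f, "seasonal_fit")) data.frame(
        curve_id = f$feature_id, day = 1:365, value = f$fitted_curve,
        lower = f$curve_band[, "lower"], upper = f$curve_band[, "upper"])))
    list(n_features = emit(scan$table, "seasonality.tsv"),
         n_curve_rows = emit(curves, "curves.tsv"), n_significant = n_sig)
  })

  run_stage("clustering", config$stages$clustering, function() {
    message("stage clustering")
    cm <- standardize_curves(state$scan, config$p_threshold)
    ks <- select_k(cm, config$k_range, m = config$fuzzifier,
                   seed = config$seed + 10L, n_restarts = config$n_restarts)
    model <- ks$models[[as.character(ks$chosen_k)]]
    state$cluster_model <- model
    message(sprintf("  chosen k = %d", ks$chosen_k))
    memb <- data.frame(feature_id = model$feature_ids,
                       round(model$membership, 4),
                       hard_label = model$hard, check.names = FALSE)
    names(memb)[2:(model$k + 1)] <- sprintf("cluster_%d", seq_len(model$k))
    cent <- data.frame(cluster = rep(seq_len(model$k), each = 365),
                       day = rep(1:365, model$k),
                       value = as.vector(t(model$centroids)))
    list(n_clustered = emit(memb, "cluster_membership.tsv"),
         n_centroid_rows = emit(cent, "cluster_centroids.tsv"),
         n_k = emit(ks$table, "k_selection.tsv"), chosen_k = ks$chosen_k)
  })

  run_stage("projection", config$stages$projection &&
              config$stages$clustering, function() {
    message("stage projection")
    streams <- generate_external_streams(seed = config$seed + 20L)
    ids <- unique(streams$stream_id)
    rows <- lapply(ids, function(id) {
      s <- streams[streams$stream_id == id, ]
      ## daily external series: single pseudo-subject, no cohort covariates
      v <- data.frame(sample_id = sprintf("%s_%03d", id, s$day_of_year),
                      subject_id = "stream", day_of_year = s$day_of_year)
      f <- fit_seasonal_model(s$value, v,
                              model_spec(covariates = character(0)))
      cv <- f$fitted_curve
      (cv - mean(cv)) / stats::sd(cv)
    })
    proj <- project_membership(do.call(rbind, rows), state$cluster_model)
    out <- data.frame(stream_id = ids, round(proj, 4), check.names = FALSE)
    list(n_streams = emit(out, "projection_membership.tsv"))
  })

  run_stage("differential", config$stages$differential, function() {
    message("stage differential")
    sim <- state$sim
    if (is.null(sim$visits$group)) stopf("differential stage needs a group column")
    diff_ids <- if (!is.null(sim$truth))
      sim$truth$feature_id[sim$truth$kind == "differential"]
    else unique(sim$data$feature_id)
    de <- differential_engine(sim$visits, config$diff_model, config$grid_size)
    rows <- list(); summ <- list()
    for (i in seq_along(diff_ids)) {
      fid <- diff_ids[i]
      d <- sim$data[sim$data$feature_id == fid, ]
      y <- d$value[match(sim$visits$sample_id, d$sample_id)]
      res <- interval_differential(y, sim$visits, B = config$B,
                                   grid_size = config$grid_size,
                                   alpha = config$alpha,
                                   unit = config$perm_unit,
                                   seed = config$seed + 30L + i,
                                   spec = config$diff_model, engine = de,
                                   feature_id = fid)
      Tn <- length(res$days)
      rows[[fid]] <- data.frame(
        feature_id = fid, interval_start_day = res$days[-Tn],
        interval_end_day = res$days[-1],
        statistic = res$statistics$statistic, p = res$p, adj_p = res$adj_p,
        significant = res$significant)
      summ[[fid]] <- data.frame(
        feature_id = fid, classification = res$classification,
        significant_ranges = if (nrow(res$ranges) == 0) "" else
          paste(sprintf("%.0f-%.0f", res$ranges$start_day,
                        res$ranges$end_day), collapse = ";"))
    }
    list(n_interval_rows = emit(do.call(rbind, rows), "differential_intervals.tsv"),
         n_features = emit(do.call(rbind, summ), "differential_summary.tsv"))
  })

  run_stage("diversity", config$stages$diversity, function() {
    message("stage diversity")
    sim <- state$sim
    if (is.null(sim$counts)) stopf("diversity stage needs taxon counts")
    levels <- c("genus", "family", "order", "class", "phylum")
    out <- lapply(levels, function(lv) {
      ds <- diversity_seasonality(sim$counts, sim$visits, sim$taxonomy, lv,
                                  spec = config$model)
      data.frame(level = lv, p_value = ds$pvalue,
                 winter_summer_contrast = ds$winter_summer_contrast)
    })
    est <- chao1(aggregate_taxa(sim$counts, sim$taxonomy, "genus"))
    list(n_samples = emit(est, "diversity_estimates.tsv"),
         n_levels = emit(do.call(rbind, out), "diversity_seasonality.tsv"))
  })

  files <- list.files(config$out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest$outputs <- lapply(stats::setNames(as.list(unname(tools::md5sum(files))),
                                             basename(files)), identity)
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
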