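#' Pipeline configuration
#'
#' Bundles the stage configurations of the end-to-end run: cohort
#' generation, dimensionality threshold, GA settings per clinical
#' target, classifier settings and stage seeds. Every stochastic stage
#' has an explicit seed derived from `seed` by a fixed small offset.
#'
#' The default GA profile (population 300, 60 generations, early stop)
#' is a desk-scale analysis profile; the full reference protocol
#' (population 1,000, 200 generations) is available by passing
#' `ga = ga_config()`.
#'
#' @param seed Master integer seed.
#' @param cohort [cohort_config()].
#' @param dim_threshold Explained-variance threshold for the
#'   dimensionality stage.
#' @param ga [ga_config()] template for the GA stage (its seed is
#'   re-derived per target).
#' @param ga_targets Clinical targets the GA is run for; the first two
#'   supply the components of the classification stage.
#' @param label_threshold Positive-label cut-off, see [label_positive()].
#' @param cv_k,group_by_patient,kernel,cost Classifier settings, see
#'   [crossval_svm()].
#' @param out_dir Output directory of [run_pipeline()].
#' @return Object of class `acg_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            cohort = cohort_config(),
                            dim_threshold = 0.90,
                            ga = ga_config(population_size = 300, generations = 60,
                                           early_stop = TRUE),
                            ga_targets = c("sofa", "icdsc", "lactate", "pct",
                                           "creatinine", "bilirubin"),
                            label_threshold = 3,
                            cv_k = 5, group_by_patient = TRUE,
                            kernel = "linear", cost = 1,
                            out_dir = tempfile("acg_run_")) {
  seed <- as.integer(seed)
  if (is.na(seed)) stopf("seed must be an integer")
  structure(list(seed = seed, cohort = cohort, dim_threshold = dim_threshold,
                 ga = ga, ga_targets = ga_targets,
                 label_threshold = label_threshold, cv_k = cv_k,
                 group_by_patient = group_by_patient, kernel = kernel,
                 cost = cost, out_dir = out_dir,
                 # fixed per-stage seed offsets, kept below 2^31
                 stage_seeds = list(cohort = seed,
                                    ga = seed + 1000L,
                                    classify = seed + 2000L)),
            class = "acg_pipeline_config")
}

write_num_csv <- function(df, path) {
  dt <- data.table::as.data.table(df)
  for (col in names(dt)) {
    if (is.double(dt[[col]])) data.table::set(dt, j = col, value = fmt_num(dt[[col]]))
  }
  data.table::fwrite(dt, path, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> features -> dimensionality -> GA (per target) ->
#' classify -> report, writing each stage artifact under
#' `config$out_dir` and logging per stage. A stage whose output files
#' already exist is skipped (cache resume); delete an artifact to
#' recompute it. Identical configurations reproduce hash-identical
#' artifacts for the deterministic stages.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage messages.
#' @return Object of class `acg_run_manifest`: per-stage output files,
#'   md5 hashes, wall-clock seconds and whether the stage was executed
#'   or resumed from cache, plus the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "acg_pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(package_version = as.character(utils::packageVersion("acgtools")),
                   seed = config$seed, stages = list())
  results <- list()

  stage <- function(name, outputs, run) {
    paths <- file.path(out, outputs)
    cached <- all(file.exists(paths))
    t0 <- proc.time()[["elapsed"]]
    value <- run(cached)
    elapsed <- proc.time()[["elapsed"]] - t0
    log_msg("[%s] %s (%.2fs)", name, if (cached) "cached" else "computed", elapsed)
    manifest$stages[[name]] <<- list(
      outputs = outputs,
      md5 = unname(tools::md5sum(paths)),
      seconds = elapsed, cached = cached)
    value
  }

  cohort <- stage("simulate", c("clinical.csv", "measurements.csv", "cohort.json"),
                  function(cached) {
    if (cached) return(load_cohort(out))
    coh <- generate_cohort(config$cohort, seed = config$stage_seeds$cohort)
    save_cohort(coh, out)
    coh
  })

  features <- stage("features", "features.csv", function(cached) {
    tab <- build_feature_table(cohort, granularity = "patient_day")
    if (!cached) {
      write_num_csv(cbind(tab$row_index, as.data.frame(tab$values)),
                    file.path(out, "features.csv"))
      write_num_csv(cbind(tab$row_index, tab$targets),
                    file.path(out, "targets.csv"))
    }
    tab
  })

  dims <- stage("dimensionality", "dims.csv", function(cached) {
    d <- patient_day_dimensionality(cohort, c("tof", "att"), config$dim_threshold)
    if (!cached) write_num_csv(d, file.path(out, "dims.csv"))
    d
  })

  std <- standardize_features(features)
  ga_results <- stage("ga", paste0("ga_", config$ga_targets, ".json"),
                      function(cached) {
    res <- list()
    for (i in seq_along(config$ga_targets)) {
      tg <- config$ga_targets[i]
      cfg <- config$ga
      cfg$seed <- config$stage_seeds$ga + i
      if (cached) {
        # resume from the stored result instead of re-evolving
        j <- jsonlite::read_json(file.path(out, paste0("ga_", tg, ".json")),
                                 simplifyVector = TRUE)
        res[[tg]] <- structure(
          list(best = list(features = as.integer(j$feature_indices),
                           fitness = j$fitness,
                           feature_names = j$feature_names),
               fitness_history = j$fitness_history,
               generations_run = j$generations_run, seed = j$seed,
               config = cfg, target = tg),
          class = "acg_ga_result")
        next
      }
      r <- ga_evolve(std, tg, cfg)
      if (!cached) {
        jsonlite::write_json(
          list(target = tg, feature_names = r$best$feature_names,
               feature_indices = r$best$features, fitness = r$best$fitness,
               fitness_history = r$fitness_history,
               generations_run = r$generations_run, seed = cfg$seed,
               config = unclass(cfg)),
          file.path(out, paste0("ga_", tg, ".json")),
          auto_unbox = TRUE, digits = NA, pretty = TRUE)
      }
      res[[tg]] <- r
    }
    res
  })

  clinical <- cohort_clinical(cohort)
  labels <- label_positive(clinical$sofa, clinical$icdsc, config$label_threshold)
  comp_targets <- config$ga_targets[seq_len(min(2, length(config$ga_targets)))]
  components <- vapply(comp_targets,
                       function(tg) pc1_scores(ga_results[[tg]]$best, std),
                       numeric(nrow(std$values)))

  cv <- stage("classify", c("metrics.json", "roc.csv"), function(cached) {
    m <- crossval_svm(components, labels, row_key = std$row_index,
                      k = config$cv_k, seed = config$stage_seeds$classify,
                      group_by_patient = config$group_by_patient,
                      kernel = config$kernel, cost = config$cost)
    # out-of-fold scores can lose a class entirely when every fold holding
    # it was degenerate; report the curve as absent rather than failing
    roc <- tryCatch(roc_curve(m$scores, m$labels), error = function(e) {
      warning("ROC unavailable: ", conditionMessage(e), call. = FALSE)
      structure(list(points = data.frame(fpr = numeric(0), tpr = numeric(0)),
                     auc = NA_real_), class = "acg_roc")
    })
    if (!cached) {
      jsonlite::write_json(
        list(k = m$k, seed = m$seed, mean_accuracy = m$mean_accuracy,
             mean_sensitivity = m$mean_sensitivity,
             mean_specificity = m$mean_specificity,
             auc = roc$auc, per_fold = m$per_fold),
        file.path(out, "metrics.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      write_num_csv(roc$points, file.path(out, "roc.csv"))
    }
    list(metrics = m, roc = roc)
  })

  report <- stage("report", "report.json", function(cached) {
    ds <- dimensionality_summary(cohort, config$dim_threshold)
    ga_scores <- lapply(ga_results, function(r) pc1_scores(r$best, std))
    ct <- correlation_table(ds, ga_scores, clinical)
    gc_tab <- group_compare(clinical, day = 1)
    rep <- list(group_comparison_day1 = gc_tab, correlations = ct)
    if (!cached) {
      jsonlite::write_json(rep, file.path(out, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    rep
  })

  results <- list(cohort = cohort, features = features, dims = dims,
                  ga = ga_results, cv = cv$metrics, roc = cv$roc,
                  report = report)
  structure(c(manifest, list(out_dir = out, results = results)),
            class = "acg_run_manifest")
}

#' @export
print.acg_run_manifest <- function(x, ...) {
  cat(sprintf("ACG pipeline run (seed %d) -> %s\n", x$seed, x$out_dir))
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-14s %s  %.2fs  %s\n", nm,
                if (s$cached) "cached " else "computed", s$seconds,
                paste(s$outputs, collapse = ", ")))
  }
  invisible(x)
}
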