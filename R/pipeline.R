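# End-to-end orchestration: simulate -> score -> stage -> fit -> explain ->
# report, with derived per-stage seeds and a reproducible run manifest.

#' Pipeline configuration
#'
#' Bundles the per-stage options. All per-stage seeds are derived
#' deterministically from `seed`, so a run is fully reproducible from the
#' configuration alone.
#'
#' @param simulation Arguments passed to [cohort_config()] (list; `seed` is
#'   filled in from the global seed).
#' @param staging Arguments passed to [apply_flowchart()] (list).
#' @param merf Arguments passed to [merf_control()] (list; seed filled in).
#' @param explain Options for the explanation stage: `n_explain` rows
#'   explained, `n_background`, `n_permutations` pairs, `n_subsets` for the
#'   age-CAG interaction, `pd_features`.
#' @param train_fraction Subject-level training fraction (default 0.8).
#' @param seed Global integer seed (mandatory).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulation = list(), staging = list(),
                            merf = list(), explain = list(),
                            train_fraction = 0.8, seed) {
  if (missing(seed)) stop("seed is mandatory")
  expl_defaults <- list(n_explain = 100, n_background = 200,
                        n_permutations = 64, n_subsets = 16,
                        pd_features = c("age", "cag", "isced", "bmi"))
  expl_defaults[names(explain)] <- explain
  structure(list(simulation = simulation, staging = staging, merf = merf,
                 explain = expl_defaults, train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' The file mirrors [pipeline_config()]: top-level keys `simulation`,
#' `staging`, `merf`, `explain`, `train_fraction` and a mandatory `seed`.
#' Files ending in `.json` are parsed with jsonlite; anything else is
#' treated as YAML (requires the `yaml` package).
#'
#' @param path Path to the configuration file.
#' @return A `"pipeline_config"` object.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configuration requires the 'yaml' package")
    yaml::read_yaml(path)
  }
  if (is.null(raw$seed)) stop("configuration must set a seed")
  pipeline_config(
    simulation = if (is.null(raw$simulation)) list() else raw$simulation,
    staging = if (is.null(raw$staging)) list() else raw$staging,
    merf = if (is.null(raw$merf)) list() else raw$merf,
    explain = if (is.null(raw$explain)) list() else raw$explain,
    train_fraction = if (is.null(raw$train_fraction)) 0.8 else
      raw$train_fraction,
    seed = raw$seed)
}

stage_seed <- function(seed, k) as.integer((abs(seed) %% 1000003L) * 100L + k)

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation, cUHDRS scoring, control-model
#' fitting and presymptomatic staging, decliner classification, the
#' Table-1-style group comparison, MERF fitting with a subject-level
#' train/validation split, and Shapley/partial-dependence explanation.
#' Every stage writes plain CSV/JSON outputs under `out_dir` so stages can
#' be inspected and re-tested in isolation, and a `manifest.json` records
#' the configuration hash, seed and stage outputs; identical configuration
#' and seed reproduce an identical manifest hash.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created; must be empty or absent).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  # --- simulate ---
  sim <- run_stage("simulate", {
    sim_args <- config$simulation
    sim_args$seed <- stage_seed(config$seed, 1L)
    cohort <- simulate_cohort(do.call(cohort_config, sim_args))
    write_cohort(cohort, file.path(out_dir, "cohort"))
    cohort
  })
  note("simulate: ", nrow(sim$baseline), " subjects, ",
       nrow(sim$visits), " visits")
  gt <- sim$truth$config$effect_spec
  jsonlite::write_json(
    list(coefs = as.list(gt$coefs), coffee_levels = gt$coffee_levels,
         random_intercept_sd = gt$random_intercept_sd,
         random_slope_sd = gt$random_slope_sd,
         residual_sd = gt$residual_sd),
    file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)

  # --- score ---
  visits <- run_stage("score", score_visits(sim$visits, warn_range = FALSE))
  utils::write.csv(visits, file.path(out_dir, "visits_scored.csv"),
                   row.names = FALSE)

  # --- stage ---
  staging <- run_stage("stage", {
    is_ctrl <- sim$baseline$group == "control"
    ctrl_ids <- sim$baseline$subjid[is_ctrl]
    carr_ids <- sim$baseline$subjid[!is_ctrl]
    if (length(carr_ids) == 0) stop("staged cohort is empty: no carriers simulated")
    if (length(ctrl_ids) < 2) stop("need at least 2 family controls")
    ctrl_model <- fit_control_model(visits[visits$subjid %in% ctrl_ids, ],
                                    sim$baseline[is_ctrl, ])
    st <- do.call(apply_flowchart,
                  c(list(visits = visits[visits$subjid %in% carr_ids, ],
                         baseline = sim$baseline[!is_ctrl, ],
                         model = ctrl_model), config$staging))
    utils::write.csv(st$decisions, file.path(out_dir, "staging.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.list(st$counts),
                         file.path(out_dir, "flowchart_counts.json"),
                         auto_unbox = TRUE)
    if (st$counts[["retained"]] == 0)
      stop("staged cohort is empty: no presymptomatic carriers retained")
    st
  })
  note("stage: retained ", staging$counts[["retained"]], " of ",
       sum(staging$counts), " carriers")

  keep <- staging$decisions$subjid[staging$decisions$presymptomatic]
  vis_kept <- visits[visits$subjid %in% keep, ]
  base_kept <- sim$baseline[sim$baseline$subjid %in% keep, ]

  # --- decliners ---
  decl <- run_stage("decliners", {
    deltas <- delta_cuhdrs_per_time(vis_kept)
    cls <- classify_decliners(deltas)
    out <- merge(deltas, cls$labels[, c("subjid", "label")], by = "subjid")
    utils::write.csv(out, file.path(out_dir, "decliners.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(threshold = cls$threshold),
                         file.path(out_dir, "decliner_threshold.json"),
                         auto_unbox = TRUE, digits = NA)
    cls
  })
  note("decliners: threshold ", signif(decl$threshold, 4))

  # --- table one ---
  run_stage("table_one", {
    t1 <- build_table_one(vis_kept, base_kept, decl$labels)
    utils::write.csv(t1, file.path(out_dir, "table_one.csv"),
                     row.names = FALSE)
    format_table_one(t1, file.path(out_dir, "table_one.txt"))
  })

  # --- merf ---
  merf_out <- run_stage("merf", {
    fm <- feature_matrix(vis_kept, base_kept)
    train <- split_subjects(fm$subjects, frac = config$train_fraction,
                            seed = stage_seed(config$seed, 2L))
    ctl_args <- config$merf
    ctl_args$seed <- stage_seed(config$seed, 3L)
    model <- fit_merf(fm$X[train, ], fm$y[train], fm$subjects[train],
                      control = do.call(merf_control, ctl_args))
    ev_tr <- evaluate_merf(model, fm$X[train, ], fm$y[train],
                           subjects = fm$subjects[train])
    ev_va <- if (any(!train))
      evaluate_merf(model, fm$X[!train, ], fm$y[!train]) else
      list(mae = NA_real_, mse = NA_real_)
    jsonlite::write_json(
      list(train = ev_tr, validation = ev_va,
           n_iterations = model$n_iterations, converged = model$converged,
           sigma2 = model$sigma2, D = as.list(as.data.frame(model$D)),
           gll_trace = model$gll_trace),
      file.path(out_dir, "merf_summary.json"), auto_unbox = TRUE, digits = NA)
    saveRDS(model, file.path(out_dir, "merf_model.rds"))
    list(model = model, fm = fm, train = train)
  })
  note("merf: ", merf_out$model$n_iterations, " iterations, sigma2 ",
       signif(merf_out$model$sigma2, 4))

  # --- explain ---
  run_stage("explain", {
    ec <- config$explain
    fm <- merf_out$fm
    Xtr <- fm$X[merf_out$train, , drop = FALSE]
    es <- stage_seed(config$seed, 4L)
    idx <- with_seed(es, sample.int(nrow(Xtr), min(ec$n_explain, nrow(Xtr))))
    bgi <- with_seed(es + 1L,
                     sample.int(nrow(Xtr), min(ec$n_background, nrow(Xtr))))
    expl <- shap_values(merf_out$model, Xtr[idx, , drop = FALSE],
                        Xtr[bgi, , drop = FALSE],
                        n_permutations = ec$n_permutations, seed = es + 2L)
    imp <- importance_ranking(expl)
    utils::write.csv(imp, file.path(out_dir, "shap_importance.csv"),
                     row.names = FALSE)
    phi_long <- data.frame(
      observation = rep(seq_len(nrow(expl$phi)), ncol(expl$phi)),
      feature = rep(colnames(expl$phi), each = nrow(expl$phi)),
      phi = as.vector(expl$phi))
    utils::write.csv(phi_long, file.path(out_dir, "shap_values.csv"),
                     row.names = FALSE)
    inter <- shap_interaction(merf_out$model, Xtr[idx, , drop = FALSE],
                              Xtr[bgi, , drop = FALSE], c("age", "cag"),
                              n_subsets = ec$n_subsets, seed = es + 3L)
    jsonlite::write_json(
      list(base_value = expl$base_value,
           age_cag_interaction_mean_abs = inter$mean_abs,
           importance = imp),
      file.path(out_dir, "explain_summary.json"), auto_unbox = TRUE,
      digits = NA)
    pd_all <- lapply(ec$pd_features, function(ft) {
      pd <- partial_dependence(merf_out$model, Xtr, ft)
      data.frame(feature = ft, pd[, c("stratum", "grid", "pd")])
    })
    utils::write.csv(do.call(rbind, pd_all),
                     file.path(out_dir, "partial_dependence.csv"),
                     row.names = FALSE)
    # planted-vs-recovered signs for effects large enough to recover
    big <- gt$coefs[abs(gt$coefs) >= 0.3]
    if (length(big)) {
      rec <- do.call(rbind, lapply(names(big), function(ft) {
        pd <- partial_dependence(merf_out$model, Xtr, ft)
        slope <- stats::coef(stats::lm(pd ~ grid, pd))[2]
        data.frame(feature = ft, planted_sign = sign(big[[ft]]),
                   recovered_sign = sign(unname(slope)),
                   pd_slope = unname(slope))
      }))
      utils::write.csv(rec, file.path(out_dir, "recovery.csv"),
                       row.names = FALSE)
    }
  })
  note("explain: done")

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_json)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("hdprogress")),
    outputs = sort(setdiff(list.files(out_dir), "manifest.json")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Render a human-readable summary of a pipeline run
#'
#' Collects the run directory's stage outputs into one plain-text report:
#' selection flowchart counts, decliner threshold, Table-1 analog, MERF
#' errors, the Shapley importance ranking, and — when the run carries a
#' ground-truth record — a planted-vs-recovered effect-sign table. Missing
#' stage outputs are listed as absent; the report still renders. The report
#' is a pure function of the run directory, so reruns are byte-identical.
#'
#' @param run_dir Directory produced by [run_pipeline()].
#' @param file Output path (default `report.txt` inside `run_dir`).
#' @return The report lines, invisibly.
#' @export
pipeline_report <- function(run_dir, file = file.path(run_dir, "report.txt")) {
  lines <- c("Presymptomatic HD progression pipeline report",
             strrep("=", 45))
  absent <- character(0)
  grab <- function(fname) {
    p <- file.path(run_dir, fname)
    if (!file.exists(p)) { absent <<- c(absent, fname); return(NULL) }
    p
  }

  p <- grab("flowchart_counts.json")
  if (!is.null(p)) {
    cnt <- jsonlite::read_json(p)
    lines <- c(lines, "", "Cohort selection (exclusions in flowchart order):",
               vapply(names(cnt), function(k)
                 sprintf("  %-24s %d", k, cnt[[k]]), ""))
  }
  p <- grab("decliner_threshold.json")
  if (!is.null(p))
    lines <- c(lines, "", sprintf(
      "Decliner threshold |mean(delta/yr)| = %.4f cUHDRS/yr",
      jsonlite::read_json(p)$threshold))
  p <- grab("table_one.txt")
  if (!is.null(p))
    lines <- c(lines, "", "Slow vs fast decliners:", readLines(p))
  p <- grab("merf_summary.json")
  if (!is.null(p)) {
    ms <- jsonlite::read_json(p)
    lines <- c(lines, "", sprintf(
      "MERF: %d iterations; train MAE %.3f MSE %.3f; validation MAE %s MSE %s",
      ms$n_iterations, ms$train$mae, ms$train$mse,
      format(round(as.numeric(ms$validation$mae), 3)),
      format(round(as.numeric(ms$validation$mse), 3))))
  }
  p <- grab("shap_importance.csv")
  if (!is.null(p)) {
    imp <- utils::read.csv(p)
    lines <- c(lines, "", "Shapley importance (mean |phi|, cUHDRS points):",
               vapply(seq_len(min(10, nrow(imp))), function(i)
                 sprintf("  %-16s %.4f", imp$feature[i],
                         imp$mean_abs_shap[i]), ""))
  }
  p <- grab("explain_summary.json")
  if (!is.null(p)) {
    es <- jsonlite::read_json(p)
    lines <- c(lines, sprintf("  age x CAG interaction mean|phi|: %.4f",
                              es$age_cag_interaction_mean_abs),
               sprintf("  base value: %.4f", es$base_value))
  }
  if (file.exists(file.path(run_dir, "ground_truth.json")) &&
      file.exists(file.path(run_dir, "recovery.csv"))) {
    rec <- utils::read.csv(file.path(run_dir, "recovery.csv"))
    lines <- c(lines, "", "Ground-truth recovery (planted vs recovered sign):",
               vapply(seq_len(nrow(rec)), function(i)
                 sprintf("  %-16s planted %+d  recovered %+d  (PD slope %.4f)",
                         rec$feature[i], rec$planted_sign[i],
                         rec$recovered_sign[i], rec$pd_slope[i]), ""))
  }
  if (length(absent))
    lines <- c(lines, "", "Absent stage outputs:",
               paste0("  ", absent))
  lines <- unname(lines)
  writeLines(lines, file)
  invisible(lines)
}
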