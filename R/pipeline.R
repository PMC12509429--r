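# End-to-end orchestration: simulate -> validate -> score -> encode ->
# benchmark -> explain -> ate -> subgroups, driven by a validated config.

pipeline_defaults <- function() {
  list(
    n = 500,
    seed = 1,
    folds = 5,
    bootstrap = 5000,
    min_subgroup = 250,
    benchmark_seeds = 1:5,
    families = c("ols", "svm", "tree", "rf", "xgboost"),
    use_grid = FALSE,
    learner = "xgboost",
    treatments = c("BAR", "SE", "UI", "SS", "BEN", "Midnight", "PN", "SI"),
    split_vars = c("BAR", "SE"),
    shap_mode = "sampled",
    shap_instances = 50,
    shap_permutations = 200,
    sd_convention = "sample",
    stages = c("simulate", "validate", "score", "benchmark", "explain",
               "ate", "subgroups"),
    out_dir = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Parses a YAML file (or takes a list), rejects unknown keys (typo
#' safety), injects defaults (folds 5, bootstrap 5000, minimum subgroup
#' size 250, ...), and enforces the guard rails (bootstrap floor 100,
#' folds >= 2, n >= 10).
#'
#' @param config path to a YAML file, or a named list (possibly empty).
#' @return Named list of class `run_config` with all settings resolved.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_gapdml("config file '%s' not found", config)
    # keep YAML-1.1 boolean-looking keys (like a bare `n:`) as literal
    # strings, then restore boolean values
    keep <- list("bool#yes" = function(x) x, "bool#no" = function(x) x)
    config <- yaml::yaml.load(paste(readLines(config), collapse = "\n"),
                              handlers = keep)
    if (is.null(config)) config <- list()
    config <- lapply(config, function(v) {
      if (is.character(v) && length(v) == 1 &&
          tolower(v) %in% c("true", "false", "yes", "no"))
        tolower(v) %in% c("true", "yes") else v
    })
  }
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop_gapdml("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config)
  if (cfg$bootstrap < 100)
    stop_gapdml("bootstrap = %d is below the floor of 100", cfg$bootstrap)
  if (cfg$folds < 2) stop_gapdml("folds must be >= 2")
  if (cfg$n < 10) stop_gapdml("n must be >= 10")
  bad <- setdiff(cfg$stages, pipeline_defaults()$stages)
  if (length(bad)) stop_gapdml("unknown stage(s): %s", paste(bad, collapse = ", "))
  structure(cfg, class = "run_config")
}

write_artifact <- function(obj, dir, name, what = c("csv", "json")) {
  if (is.null(dir)) return(invisible(NULL))
  what <- match.arg(what)
  path <- file.path(dir, paste0(name, ".", what))
  if (what == "csv") write.csv(obj, path, row.names = FALSE)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                            force = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order on a freshly
#' simulated survey: measurement validation, gap scoring, encoding with the
#' correlation screen, the algorithm benchmark, Shapley attribution with
#' dimension aggregates, the multi-treatment ATE table and the median-split
#' subgroup blocks. Every stochastic stage draws its seed deterministically
#' from the run seed, so re-running an identical config reproduces all
#' artifacts. When `out_dir` is set, per-stage CSV/JSON artifacts are
#' written there.
#'
#' @param config a [validate_config()] result, a raw list, or a YAML path.
#' @return Object of class `report_bundle`: named list of stage results
#'   plus a provenance block.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  if (!is.null(cfg$out_dir) && !dir.exists(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE)
  bundle <- list()
  stages <- cfg$stages

  message(sprintf("[simulate] n = %d, seed = %d", cfg$n, cfg$seed))
  survey <- generate_survey(cfg$n, seed = cfg$seed,
                            config = survey_config(sd_convention = cfg$sd_convention))
  bundle$survey <- survey
  if (!is.null(cfg$out_dir))
    write_survey(survey, file.path(cfg$out_dir, "survey.csv"))
  dat <- survey$survey_table

  if ("validate" %in% stages) {
    message("[validate] measurement statistics")
    bundle$validation <- validation_report(survey$items)
    write_artifact(bundle$validation$constructs, cfg$out_dir, "validation", "csv")
  }

  if ("score" %in% stages) {
    message("[score] PARS-3 + standardized gap")
    bundle$gap <- survey$gap
    write_artifact(data.frame(actual = survey$pars3$actual_score,
                              ideal = survey$pars3$ideal_score,
                              raw_gap = survey$gap$raw_gap,
                              delta_z = survey$gap$delta_z),
                   cfg$out_dir, "gap_scores", "csv")
  }

  message("[encode] z-score + one-hot + correlation screen")
  enc <- encode_features(dat[setdiff(names(dat), "delta_z")], survey$schema,
                         drop_first = TRUE)
  bundle$encoded <- enc
  model_dat <- data.frame(enc$matrix, check.names = TRUE)
  model_dat$delta_z <- dat$delta_z

  if ("benchmark" %in% stages) {
    message(sprintf("[benchmark] %s over %d seed(s)",
                    paste(cfg$families, collapse = "/"), length(cfg$benchmark_seeds)))
    bundle$leaderboard <- compare_algorithms(
      model_dat, seeds = cfg$benchmark_seeds, families = cfg$families,
      use_grid = cfg$use_grid, folds = cfg$folds)
    write_artifact(bundle$leaderboard$summary, cfg$out_dir, "leaderboard", "csv")
  }

  if ("explain" %in% stages) {
    message("[explain] Shapley attribution")
    X <- as.matrix(model_dat[setdiff(names(model_dat), "delta_z")])
    y <- model_dat$delta_z
    lrn <- make_learner(cfg$learner, list())
    fit <- lrn$fit(X, y, seed = derive_seed(cfg$seed, "explain_fit"))
    predict_fn <- function(M) {
      colnames(M) <- colnames(X)
      lrn$predict(fit, M)
    }
    rows <- seq_len(min(cfg$shap_instances, nrow(X)))
    am <- shapley_attribution(predict_fn, X[rows, , drop = FALSE],
                              background = X, mode = cfg$shap_mode,
                              permutations = cfg$shap_permutations,
                              seed = derive_seed(cfg$seed, "shap"))
    dims <- list(psychological_cognition = intersect(c("BAR", "SE"), colnames(X)),
                 smart_sport = intersect(c("UI", "SS"), colnames(X)))
    bundle$attribution <- am
    bundle$ranking <- importance_ranking(am, dims)
    if (cfg$learner == "xgboost")
      bundle$gain_ranking <- gain_importance(fit)
    write_artifact(bundle$ranking$table, cfg$out_dir, "importance", "csv")
    write_artifact(beeswarm_data(am, X[rows, , drop = FALSE]),
                   cfg$out_dir, "beeswarm", "csv")
  }

  if ("ate" %in% stages) {
    message(sprintf("[ate] %d treatment(s), K = %d, B = %d",
                    length(cfg$treatments), cfg$folds, cfg$bootstrap))
    treatments <- intersect(cfg$treatments, names(model_dat))
    bundle$ate <- dml_ate_table(model_dat, treatments, learner = cfg$learner,
                                K = cfg$folds, B = cfg$bootstrap,
                                seed = derive_seed(cfg$seed, "ate"))
    write_artifact(bundle$ate$table, cfg$out_dir, "ate_table", "csv")
  }

  if ("subgroups" %in% stages) {
    message(sprintf("[subgroups] median splits on %s",
                    paste(cfg$split_vars, collapse = ", ")))
    treatments <- intersect(cfg$treatments, names(model_dat))
    bundle$subgroups <- lapply(cfg$split_vars, function(sv) {
      tryCatch(
        subgroup_ates(model_dat, sv, setdiff(treatments, sv),
                      min_size = cfg$min_subgroup, learner = cfg$learner,
                      K = cfg$folds, B = cfg$bootstrap,
                      seed = derive_seed(cfg$seed, paste0("sub_", sv))),
        error = function(e) conditionMessage(e))
    })
    names(bundle$subgroups) <- cfg$split_vars
    for (sv in cfg$split_vars) {
      sg <- bundle$subgroups[[sv]]
      if (inherits(sg, "dml_subgroups")) {
        blocks <- do.call(rbind, lapply(names(sg$groups), function(side)
          cbind(split = sv, side = side, n = sg$groups[[side]]$n,
                sg$groups[[side]]$table)))
        write_artifact(blocks, cfg$out_dir, paste0("subgroups_", sv), "csv")
      }
    }
  }

  bundle$provenance <- list(
    seed = cfg$seed, n = cfg$n,
    config = unclass(cfg)[setdiff(names(cfg), "out_dir")],
    r_version = as.character(getRversion()),
    timestamp_utc = format(Sys.time(), tz = "UTC"))
  if (!is.null(cfg$out_dir))
    jsonlite::write_json(bundle$provenance[c("seed", "n", "config", "r_version")],
                         file.path(cfg$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  structure(bundle, class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> stages:",
      paste(setdiff(names(x), "provenance"), collapse = ", "), "\n")
  invisible(x)
}
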