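# End-to-end pipeline: split -> encode -> autoscale -> stepwise select
# -> VIF check -> fit configured models -> metric table -> contribution
# map -> candidate design, with every artifact written to a run
# directory alongside provenance metadata (config, seeds).

#' Default pipeline configuration
#'
#' @param out_dir Run directory to create.
#' @param peptides Path to a peptide-activity CSV, or NULL to generate a
#'   synthetic dataset from [ground_truth()].
#' @param aaindex Path to an AAindex1 flat file, or NULL for
#'   [default_properties()].
#' @param enter,remove Stepwise significance thresholds.
#' @param vif_limit Collinearity limit for [check_selection()].
#' @param methods Model methods to fit (subset of MLR, PLS, SVR, RF).
#' @param ks k-fold values.
#' @param seed Master seed (models, folds, synthetic data).
#' @param design Per-position residue constraints for candidate design
#'   (list with `pos1`, `pos2`, `pos3`), or NULL to design over
#'   Trp/Tyr/Cys at the C-terminus.
#' @param n_properties Property-pool size when generating defaults.
#' @return Configuration list.
#' @export
pipeline_config <- function(out_dir,
                            peptides = NULL,
                            aaindex = NULL,
                            enter = 0.05, remove = 0.10,
                            vif_limit = 5,
                            methods = c("MLR", "PLS", "SVR", "RF"),
                            ks = c(4, 6, 10),
                            seed = 1L,
                            design = list(pos1 = standard_residues(),
                                          pos2 = standard_residues(),
                                          pos3 = c("W", "Y", "C")),
                            n_properties = 195L) {
  list(out_dir = out_dir, peptides = peptides, aaindex = aaindex,
       enter = enter, remove = remove, vif_limit = vif_limit,
       methods = methods, ks = ks, seed = as.integer(seed),
       design = design, n_properties = as.integer(n_properties))
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields fall back to [pipeline_config()] defaults.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$out_dir)) stop("config must set out_dir")
  cfg <- pipeline_config(out_dir = raw$out_dir)
  for (nm in intersect(names(raw), names(cfg))) cfg[[nm]] <- raw[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

validate_config <- function(config) {
  required <- c("out_dir", "enter", "remove", "vif_limit", "methods",
                "ks", "seed")
  missing_f <- setdiff(required, names(config))
  if (length(missing_f)) {
    stop("config missing field(s): ", paste(missing_f, collapse = ", "))
  }
  if (config$enter > config$remove) {
    stop("config invalid: enter threshold exceeds remove threshold")
  }
  bad <- setdiff(config$methods, c("MLR", "PLS", "SVR", "RF"))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  invisible(config)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full QSAR pipeline
#'
#' Executes descending-activity train/test splitting, descriptor
#' encoding, autoscaling, stepwise variable selection with VIF
#' validation, model fitting for every configured method with the full
#' metric bundle, residue-contribution mapping from the linear model, and
#' constrained candidate design. Artifacts written to the run directory:
#' `selection.json`, `model_<method>.json`, `metrics.csv`,
#' `contributions.csv`, `candidates.csv`, `peptides.csv` and
#' `provenance.json`. Reruns with the same configuration and seed are
#' bit-identical.
#'
#' @param config Configuration list from [pipeline_config()] /
#'   [read_pipeline_config()], or a path to a YAML config.
#' @return The run directory path, invisibly; a summary list as the
#'   `"result"` attribute.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)

  properties <- stage("load-properties", {
    if (is.null(config$aaindex)) {
      default_properties(m = config$n_properties, seed = config$seed)
    } else {
      filter_complete(read_aaindex(config$aaindex))
    }
  })

  dataset <- stage("load-peptides", {
    if (is.null(config$peptides)) {
      generate_peptide_dataset(
        ground_truth(n_peptides = 91L, seed = config$seed),
        properties = properties)
    } else {
      list(peptides = read_peptide_table(config$peptides), truth = NULL)
    }
  })
  peptides <- dataset$peptides
  utils::write.csv(peptides, out("peptides.csv"), row.names = FALSE)

  split <- stage("split", split_train_test(peptides))
  X_train <- stage("encode", encode_peptides(split$train$sequence, properties))
  X_test <- if (nrow(split$test)) {
    encode_peptides(split$test$sequence, properties)
  } else NULL

  sc <- stage("autoscale", autoscale(X_train, y = split$train$activity))

  sel <- stage("select", stepwise_select(sc$X, sc$y,
                                         enter = config$enter,
                                         remove = config$remove))
  vif_report <- if (length(sel$vifs)) {
    check_selection(sel, vif_limit = config$vif_limit)
  } else {
    list(pass = NA, offenders = numeric(0), vif_limit = config$vif_limit)
  }
  jsonlite::write_json(
    list(selected = sel$selected, steps = sel$steps,
         thresholds = as.list(sel$thresholds), vifs = as.list(sel$vifs),
         vif_pass = vif_report$pass, truncated = sel$truncated),
    out("selection.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (!length(sel$selected)) {
    stop("pipeline stage 'select' failed: no variables selected")
  }

  Xs_sel <- sc$X[, sel$selected, drop = FALSE]
  models <- list()
  metric_rows <- list()
  for (method in config$methods) {
    model <- stage(paste0("fit-", method), switch(method,
      MLR = fit_mlr(Xs_sel, sc$y, scaling = sc$params),
      PLS = fit_pls(Xs_sel, sc$y, scaling = sc$params),
      SVR = fit_svr(Xs_sel, sc$y, seed = config$seed, scaling = sc$params),
      RF  = fit_rf(Xs_sel, sc$y, seed = config$seed, scaling = sc$params)
    ))
    model <- stage(paste0("metrics-", method), model_metrics(
      model, X_train, split$train$activity, X_test, split$test$activity,
      ks = config$ks, seed = config$seed))
    models[[method]] <- model
    m <- model$metrics
    row <- data.frame(method = method, n = m$n, m = m$m,
                      R2_train = m$R2_train, SD = m$SD, F = m$F,
                      Q2_loo = m$Q2_loo, stringsAsFactors = FALSE)
    for (k in names(m$Q2_kfold)) row[[paste0("Q2_", k)]] <- m$Q2_kfold[[k]]
    row$PRESS <- m$PRESS
    row$n_test <- if (is.null(m$n_test)) NA_integer_ else m$n_test
    row$R2_test <- if (is.null(m$R2_test)) NA_real_ else m$R2_test
    metric_rows[[method]] <- row
    jsonlite::write_json(
      list(method = model$method, variables = model$variables,
           coefficients = as.list(model$coefficients),
           hyperparameters = model$hyperparameters,
           seed = config$seed, metrics = m[!vapply(m, is.null, TRUE)]),
      out(paste0("model_", tolower(method), ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  metrics <- do.call(rbind, metric_rows)
  rownames(metrics) <- NULL
  utils::write.csv(metrics, out("metrics.csv"), row.names = FALSE)

  contrib <- NULL
  linear <- intersect(c("MLR", "PLS"), names(models))
  if (length(linear)) {
    contrib <- stage("contributions",
                     residue_contributions(models[[linear[1]]], properties))
    write_contributions(contrib, out("contributions.csv"))
  }

  candidates <- NULL
  if (!is.null(config$design) && length(linear)) {
    candidates <- stage("design", {
      seqs <- enumerate_candidates(config$design$pos1 %||% standard_residues(),
                                   config$design$pos2 %||% standard_residues(),
                                   config$design$pos3 %||% standard_residues())
      score_candidates(seqs, models[[linear[1]]], properties,
                       train_range = descriptor_range(X_train))
    })
    utils::write.csv(candidates, out("candidates.csv"), row.names = FALSE)
  }

  jsonlite::write_json(
    list(seed = config$seed,
         thresholds = list(enter = config$enter, remove = config$remove),
         vif_limit = config$vif_limit, methods = config$methods,
         ks = config$ks, n_properties = length(properties),
         n_train = nrow(split$train), n_test = nrow(split$test),
         package_version = as.character(utils::packageVersion("pepqsar"))),
    out("provenance.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  result <- list(split = split, selection = sel, vif_report = vif_report,
                 models = models, metrics = metrics,
                 contributions = contrib, candidates = candidates,
                 truth = dataset$truth)
  ret <- config$out_dir
  attr(ret, "result") <- result
  invisible(ret)
}
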