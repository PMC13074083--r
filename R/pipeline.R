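# End-to-end pipeline: descriptors -> prefilter -> partition -> GA selection
# -> validation -> applicability domain / Y-randomization -> prediction,
# with a manifest recording seeds, parameters and input hashes.

#' Default pipeline configuration
#'
#' Returns the full default [run_pipeline()] configuration as a named list;
#' supply overrides as arguments or via a YAML file
#' (\code{run_pipeline("config.yml")}).
#'
#' @param ... overrides of the defaults (same names as the list entries).
#' @return configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = "gaqsar_run",
    # inputs: either smiles/sdf + activities CSVs, a descriptor CSV +
    # activities CSV, or synthetic = TRUE to use the bundled generator
    smiles = NULL, sdf = NULL, descriptors = NULL, activities = NULL,
    synthetic = FALSE,
    synthetic_n = 115L, synthetic_p = 60L,
    prefilter = list(near_constant_frac = 0.80, corr_cutoff = 0.95,
                     var_floor = 1e-4),
    train_frac = 81 / 115,
    ga = list(k = 5L, pop_size = 100L, generations = 200L),
    lmo = list(leave_frac = 0.2, repeats = 1000L),
    yrand_iterations = 2000L
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

.read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  do.call(pipeline_config, config)
}

#' Run the full GA-MLR QSAR pipeline
#'
#' Executes, in order: descriptor acquisition, descriptor pre-filtering,
#' training/test partitioning, GA descriptor selection with MLR fitting,
#' the validation statistics suite, applicability-domain and
#' Y-randomization analysis, and prediction for all compounds. Each stage
#' writes its artifacts into the run directory; a \code{manifest.json}
#' records the stage sequence, seeds, parameters, input hashes and package
#' version. A stage failure aborts the run with the stage name after
#' persisting the partial manifest. No stage mutates its inputs.
#'
#' @param config a configuration list from [pipeline_config()], or the path
#'   to a YAML file with the same fields.
#' @return the run directory path, invisibly; the manifest is also returned
#'   as the attribute \code{"manifest"}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- .read_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "gaqsar",
    version = as.character(utils::packageVersion("gaqsar")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    input_hashes = list(),
    stages = list()
  )
  for (f in c("smiles", "sdf", "descriptors", "activities")) {
    if (!is.null(cfg[[f]]) && file.exists(cfg[[f]])) {
      manifest$input_hashes[[f]] <- unname(tools::md5sum(cfg[[f]]))
    }
  }
  save_manifest <- function() {
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, null = "null"),
               file.path(cfg$out_dir, "manifest.json"))
  }
  stage <- function(name, code) {
    res <- tryCatch(force(code), error = function(e) {
      manifest$stages[[length(manifest$stages) + 1L]] <<-
        list(name = name, status = "failed", error = conditionMessage(e))
      save_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(name = name, status = "ok",
           artifacts = attr(res, "artifacts"))
    res
  }
  art <- function(x, files) { attr(x, "artifacts") <- files; x }
  out <- function(name) file.path(cfg$out_dir, name)

  # 1. descriptors ---------------------------------------------------------
  data <- stage("descriptors", {
    if (isTRUE(cfg$synthetic)) {
      sim <- gen_qsar_dataset(cfg$synthetic_n, cfg$synthetic_p,
                              qsar_truth(seed = cfg$seed))
      X <- sim$X; y <- sim$y
    } else if (!is.null(cfg$smiles) || !is.null(cfg$sdf)) {
      mols <- if (!is.null(cfg$sdf)) read_sdf_molecules(cfg$sdf) else
        read_smiles(cfg$smiles)
      tab <- descriptor_table(mols)
      X <- as.matrix(tab[, -1, drop = FALSE]); rownames(X) <- tab$id
      act <- read_compound_table(cfg$activities)
      y <- stats::setNames(act$pIC50, act$id)[rownames(X)]
    } else if (!is.null(cfg$descriptors)) {
      X <- read_descriptor_matrix(cfg$descriptors)
      act <- read_compound_table(cfg$activities)
      y <- stats::setNames(act$pIC50, act$id)[rownames(X)]
    } else {
      stop("no input: set smiles/sdf, descriptors, or synthetic = TRUE")
    }
    if (anyNA(y)) stop("activities missing for some compounds")
    write_descriptor_matrix(X, out("descriptors.csv"))
    art(list(X = X, y = y), "descriptors.csv")
  })

  # 2. prefilter ------------------------------------------------------------
  filt <- stage("prefilter", {
    pf <- prefilter(data$X, data$y,
                    near_constant_frac = cfg$prefilter$near_constant_frac,
                    corr_cutoff = cfg$prefilter$corr_cutoff,
                    var_floor = cfg$prefilter$var_floor)
    filter_report_json(pf$report, out("filter_report.json"))
    art(pf, "filter_report.json")
  })

  # 3. partition ------------------------------------------------------------
  parts <- stage("partition", {
    rec <- data.frame(id = rownames(filt$X), stringsAsFactors = FALSE)
    n_train <- round(cfg$train_frac * nrow(rec))
    rec <- partition_compounds(rec, n_train, seed = cfg$seed)
    utils::write.csv(rec, out("partitions.csv"), row.names = FALSE)
    tr <- rec$id[rec$partition == "training"]
    te <- rec$id[rec$partition == "internal_test"]
    art(list(train = tr, test = te), "partitions.csv")
  })

  Xtr <- filt$X[parts$train, , drop = FALSE]
  ytr <- data$y[parts$train]
  Xte <- filt$X[parts$test, , drop = FALSE]
  yte <- data$y[parts$test]

  # 4. GA selection + fit ---------------------------------------------------
  sel <- stage("gaselect", {
    res <- ga_select(Xtr, ytr,
                     ga_config(k = cfg$ga$k, pop_size = cfg$ga$pop_size,
                               generations = cfg$ga$generations,
                               seed = cfg$seed))
    model_to_json(res$model, out("model.json"))
    utils::write.csv(
      data.frame(generation = seq_along(res$trace) - 1L,
                 best_q2loo = res$trace),
      out("ga_trace.csv"), row.names = FALSE)
    art(res, c("model.json", "ga_trace.csv"))
  })

  # 5. validation ----------------------------------------------------------
  stage("validate", {
    rep <- validate_all(sel$model, Xtr, ytr, Xte, yte,
                        lmo_frac = cfg$lmo$leave_frac,
                        lmo_repeats = cfg$lmo$repeats, seed = cfg$seed)
    report_to_json(rep, out("validation.json"))
    art(rep, "validation.json")
  })

  # 6. applicability domain + Y-randomization -------------------------------
  stage("ad_yrand", {
    nms <- names(sel$model$coefficients)
    ad <- williams_ad(sel$model, Xtr[, nms, drop = FALSE],
                      Xte[, nms, drop = FALSE])
    utils::write.csv(ad$table, out("williams.csv"), row.names = FALSE)
    yr <- y_randomize(Xtr[, nms, drop = FALSE], ytr,
                      iterations = cfg$yrand_iterations, seed = cfg$seed)
    writeLines(jsonlite::toJSON(
      list(iterations = yr$iterations, seed = yr$seed,
           r2_scr_mean = yr$r2_scr_mean, r2_scr_max = yr$r2_scr_max,
           q2_scr_mean = yr$q2_scr_mean, q2_scr_max = yr$q2_scr_max,
           r2_orig = yr$r2_orig, q2_orig = yr$q2_orig),
      auto_unbox = TRUE, digits = NA), out("yrandomization.json"))
    art(list(ad = ad, yrand = yr), c("williams.csv", "yrandomization.json"))
  })

  # 7. prediction -----------------------------------------------------------
  stage("predict", {
    pred <- predict(sel$model, filt$X)
    df <- data.frame(id = rownames(filt$X), predicted_pIC50 = pred,
                     observed_pIC50 = data$y[rownames(filt$X)])
    utils::write.csv(df, out("predictions.csv"), row.names = FALSE)
    art(df, "predictions.csv")
  })

  save_manifest()
  res <- cfg$out_dir
  attr(res, "manifest") <- manifest
  invisible(res)
}
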