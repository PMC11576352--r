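# Pipeline orchestration: stages hand results to each other through plain
# TSV/JSON files so every intermediate is inspectable, and a manifest of
# content hashes makes reruns verifiable. Each stage is also usable
# stand-alone through the exported module functions.

.stage_keys <- list(
  simulate = c("n_classes", "n_per_class", "biomarkers", "conc_range",
               "shift_jitter_sd", "noise_sd", "grid", "presence_count"),
  preprocess = c("excluded_regions", "normalization", "area_target", "scaling"),
  pca = c("n_components", "center", "scale", "alpha", "exclude"),
  oplsda = c("n_orth", "center", "scale", "folds", "test_matrix"),
  stocsy = c("driver_ppm"),
  multiblock = c("blocks", "n_components"),
  compass = c("sample", "ppm_hi", "ppm_lo", "threshold", "max_shift_points"),
  boxstats = c("grouping")
)
.top_keys <- c("seed", "stages", "input_matrix", "input_annotations",
               "log_level", names(.stage_keys))

# write a data frame as plain TSV (17 significant digits for doubles)
write_tsv_df <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  for (j in which(num)) df[[j]] <- fmt17(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

validate_config <- function(config) {
  unknown <- setdiff(names(config), .top_keys)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$stages) || length(config$stages) == 0)
    stop("config must list at least one stage")
  bad_stage <- setdiff(unlist(config$stages), names(.stage_keys))
  if (length(bad_stage) > 0)
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  for (st in intersect(names(config), names(.stage_keys))) {
    unknown <- setdiff(names(config[[st]]), .stage_keys[[st]])
    if (length(unknown) > 0)
      stop(sprintf("unknown key(s) in [%s]: %s", st,
                   paste(unknown, collapse = ", ")))
  }
  invisible(config)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in their declared order; each stage
#' consumes the in-memory result of the previous one (or the configured
#' input files) and writes its outputs as TSV/JSON into `out_dir`. A
#' resolved copy of the configuration and a manifest with an MD5 hash of
#' every written file are placed next to the outputs; rerunning with the
#' same configuration and inputs reproduces identical hashes, since all
#' randomness is driven by the configured seed.
#'
#' @param config Named list (or path to a JSON file) with `seed`, `stages`
#'   (ordered subset of `simulate`, `preprocess`, `pca`, `oplsda`, `stocsy`,
#'   `multiblock`, `compass`, `boxstats`), one optional section per stage,
#'   and `input_matrix` / `input_annotations` paths when the first stage is
#'   not `simulate`. Unknown keys are rejected.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `manifest` (data frame of file, md5) and
#'   the final in-memory `matrix`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  written <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    written <<- c(written, name)
  }
  m <- NULL
  ann <- NULL
  if (!is.null(config$input_matrix)) m <- read_tsv_matrix(config$input_matrix)
  if (!is.null(config$input_annotations))
    ann <- read_annotations(config$input_annotations)
  for (st in unlist(config$stages)) {
    opts <- config[[st]] %||% list()
    res <- tryCatch(
      switch(st,
        simulate = {
          cfg <- do.call(sim_config, c(opts, list(seed = seed)))
          ds <- simulate_dataset(cfg)
          emit("matrix.tsv", function(p) write_tsv_matrix(ds$matrix, p))
          emit("annotations.tsv", function(p) write_annotations(ds$annotations, p))
          emit("truth.tsv", function(p) write_tsv_df(ds$truth, p))
          m <- ds$matrix; ann <- ds$annotations
        },
        preprocess = {
          pr <- preprocess(m,
            excluded_regions = opts$excluded_regions,
            normalization = opts$normalization %||% "none",
            area_target = opts$area_target %||% 100,
            scaling = opts$scaling %||% "none")
          emit("processed_matrix.tsv", function(p) write_tsv_matrix(pr$matrix, p))
          emit("preprocess_factors.tsv", function(p) write_tsv_df(
            data.frame(sample_id = names(pr$dilution_factors),
                       dilution_factor = as.numeric(pr$dilution_factors)), p))
          emit("preprocess_scaling.tsv", function(p) write_tsv_df(
            data.frame(ppm = pr$matrix$ppm, center = pr$centers,
                       scale = pr$scales), p))
          m <- pr$matrix
        },
        pca = {
          excl <- as.character(opts$exclude %||% character(0))
          fitargs <- list(n_components = opts$n_components %||% 2,
                          center = opts$center %||% TRUE,
                          scale = opts$scale %||% "none")
          rf <- do.call(refit_excluding, c(list(m, excl), fitargs))
          model <- rf$model
          out <- hotelling_outliers(model, opts$alpha %||% 0.05)
          sc <- rbind(model$scores, rf$excluded_scores)
          emit("pca_scores.tsv", function(p) write_tsv_df(
            data.frame(sample_id = c(model$sample_ids, rownames(rf$excluded_scores)),
                       excluded = rep(c(FALSE, TRUE),
                                      c(nrow(model$scores), nrow(rf$excluded_scores))),
                       as.data.frame(sc, row.names = NULL)), p))
          emit("pca_loadings.tsv", function(p) write_tsv_df(
            data.frame(ppm = model$ppm,
                       as.data.frame(model$loadings, row.names = NULL)), p))
          emit("pca_variance.tsv", function(p) write_tsv_df(
            data.frame(component = seq_along(model$explained_variance_ratio),
                       explained_variance_ratio = model$explained_variance_ratio), p))
          emit("pca_outliers.tsv", function(p) write_tsv_df(
            data.frame(sample_id = names(out$t2), t2 = as.numeric(out$t2),
                       limit = out$limit, flagged = names(out$t2) %in% out$flagged), p))
        },
        oplsda = {
          cls <- ann$class[match(sample_ids(m), ann$sample_id)]
          model <- fit_oplsda(m, cls, n_orth = opts$n_orth %||% 1,
                              center = opts$center %||% TRUE,
                              scale = opts$scale %||% "none")
          cv <- cross_validate_oplsda(m, cls, n_orth = opts$n_orth %||% 1,
                                      folds = opts$folds %||% 7, seed = seed,
                                      center = opts$center %||% TRUE,
                                      scale = opts$scale %||% "none")
          emit("oplsda_scores.tsv", function(p) write_tsv_df(
            data.frame(sample_id = model$sample_ids, t_pred = model$t_pred,
                       as.data.frame(model$T_o, row.names = NULL)), p))
          emit("oplsda_loadings.tsv", function(p)
            write_tsv_df(loading_decomposition(model), p))
          emit("oplsda_model.json", function(p) jsonlite::write_json(
            list(class_labels = model$class_labels, q = model$q,
                 y_mean = model$y_mean, n_orth = model$n_orth,
                 r2x_pred = model$r2x_pred, r2x_orth = model$r2x_orth,
                 r2y = model$r2y, q2 = cv$q2,
                 centers = model$centers, scales = model$scales,
                 w = model$w, p_pred = model$p_pred,
                 W_o = model$W_o, P_o = model$P_o),
            p, auto_unbox = TRUE, digits = NA))
          pred_m <- if (!is.null(opts$test_matrix))
            read_tsv_matrix(opts$test_matrix) else m
          pred <- predict_oplsda(model, pred_m)
          emit("oplsda_predictions.tsv", function(p) write_tsv_df(
            data.frame(sample_id = names(pred$y_hat),
                       y_hat = as.numeric(pred$y_hat),
                       predicted_class = as.character(pred$predicted_class)), p))
        },
        stocsy = {
          if (is.null(opts$driver_ppm)) stop("stocsy stage needs driver_ppm")
          st_res <- stocsy(m, opts$driver_ppm)
          emit("stocsy.tsv", function(p) write_tsv_df(
            data.frame(ppm = st_res$ppm, correlation = st_res$correlation,
                       covariance = st_res$covariance), p))
        },
        multiblock = {
          blocks <- lapply(opts$blocks, function(b)
            do.call(block_definition, as.list(b)))
          mb <- fit_mbpca(m, blocks, n_components = opts$n_components %||% 2)
          emit("mb_super_scores.tsv", function(p) write_tsv_df(
            data.frame(sample_id = mb$sample_ids,
                       as.data.frame(mb$super_scores, row.names = NULL)), p))
          emit("mb_super_weights.tsv", function(p) write_tsv_df(
            data.frame(block = vapply(mb$blocks, `[[`, character(1), "name"),
                       as.data.frame(mb$super_weights, row.names = NULL)), p))
        },
        compass = {
          pat <- extract_reference(m, opts$sample, opts$ppm_hi, opts$ppm_lo)
          cm <- compass_match(m, pat,
                              max_shift_points = opts$max_shift_points %||% 3,
                              threshold = opts$threshold %||% 0.8)
          emit("compass.tsv", function(p) write_tsv_df(
            data.frame(sample_id = names(cm$best_correlation),
                       best_correlation = as.numeric(cm$best_correlation),
                       best_shift = as.integer(cm$best_shift),
                       matched_intensity = as.numeric(cm$matched_intensity),
                       contains_pattern = as.logical(cm$contains_pattern)), p))
          emit("compass_summary.json", function(p) jsonlite::write_json(
            list(n_containing = cm$n_containing, threshold = cm$threshold,
                 max_shift_points = cm$max_shift_points,
                 ranking = cm$ranking), p, auto_unbox = TRUE, digits = NA))
        },
        boxstats = {
          bs <- box_stats(m, ann, grouping = opts$grouping %||% "by_class")
          emit("boxstats.tsv", function(p) write_tsv_df(as.data.frame(bs), p))
        }
      ),
      error = function(e) stop(sprintf("stage '%s' failed: %s", st,
                                       conditionMessage(e)), call. = FALSE))
    if (is.null(m) && !identical(st, "simulate"))
      stop(sprintf("stage '%s' has no input matrix", st))
  }
  cfg_path <- file.path(out_dir, "resolved_config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  written <- c(written, "resolved_config.json")
  hashes <- tools::md5sum(file.path(out_dir, written))
  manifest <- data.frame(file = written, md5 = as.character(hashes),
                         row.names = NULL)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA)
  invisible(list(manifest = manifest, matrix = m))
}
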