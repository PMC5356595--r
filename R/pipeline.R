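#' Configuration for an end-to-end pipeline run
#'
#' Inputs come either from the three TSV paths or from a simulation
#' configuration (exactly one of the two). All defaults are echoed into the
#' run manifest so a run is reproducible from its manifest alone.
#'
#' @param expression,samples,annotation input TSV paths (see
#'   [read_expression()], [read_sample_annotation()],
#'   [read_transcript_annotation()]), or `NULL` when simulating.
#' @param simulate a [simulation_config()], or `NULL` when reading files.
#' @param thresholds a [specificity_thresholds()] list.
#' @param control a [qp_control()] list.
#' @param panel_pair two subtype labels for the L1 panel stage, or `NULL`
#'   to skip it.
#' @param panel_seed,panel_folds CV fold seed and count for the panel stage.
#' @param coexpression run the pair stage (default `TRUE`).
#' @param marker_auc compute the per-feature one-vs-rest AUC tables and the
#'   isoform-vs-gene comparison (default `TRUE`; needs an annotation).
#' @param out_dir output directory for stage TSVs and the JSON manifest, or
#'   `NULL` to return results only.
#' @return list of class `run_config`.
#' @export
run_config <- function(expression = NULL, samples = NULL, annotation = NULL,
                       simulate = NULL,
                       thresholds = specificity_thresholds(),
                       control = qp_control(),
                       panel_pair = c("LumA", "LumB"),
                       panel_seed = 1L, panel_folds = 5L,
                       coexpression = TRUE, marker_auc = TRUE,
                       out_dir = NULL) {
  from_files <- !is.null(expression)
  if (from_files && is.null(samples))
    stop("file input needs both expression and sample annotation paths")
  if (!from_files && is.null(simulate))
    stop("provide input paths or a simulation config")
  if (from_files && !is.null(simulate))
    stop("provide input paths or a simulation config, not both")
  structure(list(expression = expression, samples = samples,
                 annotation = annotation, simulate = simulate,
                 thresholds = thresholds, control = control,
                 panel_pair = panel_pair, panel_seed = as.integer(panel_seed),
                 panel_folds = as.integer(panel_folds),
                 coexpression = isTRUE(coexpression),
                 marker_auc = isTRUE(marker_auc),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `thresholds`,
#' `control` and `simulate` are nested maps passed to
#' [specificity_thresholds()], [qp_control()] and [simulation_config()].
#'
#' @param path YAML file path.
#' @return a `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("thresholds", "control", "simulate"))]
  if (!is.null(y$thresholds)) args$thresholds <- do.call(specificity_thresholds, y$thresholds)
  if (!is.null(y$control)) args$control <- do.call(qp_control, y$control)
  if (!is.null(y$simulate)) args$simulate <- do.call(simulation_config, y$simulate)
  do.call(run_config, args)
}

write_stage_tsv <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full discovery pipeline
#'
#' Stages, in order: load or simulate data; batch robust quasi-Poisson fits
#' on the discovery split; subtype-specificity decisions; pair co-expression
#' decisions; one-vs-rest marker AUCs with isoform-vs-gene comparison; L1
#' panel with incremental AUC for the configured subtype pair. Every stage's
#' feature counts, exclusions and wall time land in the manifest; re-running
#' an identical config reproduces identical outputs.
#'
#' @param cfg a [run_config()] object.
#' @return list with `manifest` plus the per-stage results
#'   (`data`, `fits`, `specificity`, `coexpression`, `auc`, `panel`).
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) stop("cfg must come from run_config()")
  if (!is.null(cfg$out_dir) && !dir.exists(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("isospec")),
                   r_version = as.character(getRversion()),
                   config = unclass_deep(cfg), stages = list())
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    val
  }

  dat <- tick("data", {
    if (!is.null(cfg$simulate)) {
      simulate_dataset(cfg$simulate)
    } else {
      list(expression = read_expression(cfg$expression),
           samples = read_sample_annotation(cfg$samples),
           annotation = if (!is.null(cfg$annotation))
             read_transcript_annotation(cfg$annotation),
           truth = NULL)
    }
  })
  manifest$stages$data$n_features <- nrow(dat$expression)
  manifest$stages$data$n_samples <- ncol(dat$expression)

  disc <- align_split(dat$expression, dat$samples, "discovery")
  fits <- tick("fit", fit_qp_matrix(disc$x, disc$subtype, cfg$control))
  manifest$stages$fit$n_converged <- sum(fits$converged)
  manifest$stages$fit$n_not_converged <- sum(!fits$converged)

  spec <- tick("specificity",
               run_specificity(disc$x, disc$subtype, cfg$thresholds,
                               cfg$control, fits = fits))
  manifest$stages$specificity$n_decisions <- sum(spec$decision)
  write_stage_tsv(spec, cfg$out_dir, "specificity")

  coex <- NULL
  if (cfg$coexpression && nlevels(disc$subtype) >= 3) {
    coex <- tick("coexpression",
                 run_coexpression(disc$x, disc$subtype, cfg$thresholds,
                                  cfg$control, fits = fits))
    manifest$stages$coexpression$n_decisions <- sum(coex$decision)
    write_stage_tsv(coex, cfg$out_dir, "coexpression")
  }

  auc <- NULL
  if (cfg$marker_auc) {
    auc <- tick("marker_auc", {
      iso <- marker_auc_table(dat$expression, dat$samples, level = "isoform")
      cmp <- NULL
      if (!is.null(dat$annotation)) {
        gx <- aggregate_gene_level(dat$expression, dat$annotation)
        gene <- marker_auc_table(gx, dat$samples, level = "gene")
        cmp <- compare_isoform_gene_auc(iso, gene, dat$annotation)
      }
      list(isoform = iso, comparison = cmp)
    })
    if (!is.null(auc$comparison))
      manifest$stages$marker_auc$fraction_isoform_better <-
        attr(auc$comparison, "fraction_better")
    write_stage_tsv(auc$isoform, cfg$out_dir, "marker_auc")
  }

  panel <- NULL
  if (!is.null(cfg$panel_pair) &&
      all(cfg$panel_pair %in% levels(disc$subtype))) {
    panel <- tick("panel", {
      vali <- align_split(dat$expression, dat$samples, "validation")
      sel_d <- disc$subtype %in% cfg$panel_pair
      sel_v <- vali$subtype %in% cfg$panel_pair
      pm <- fit_l1_panel(disc$x[, sel_d, drop = FALSE],
                         as.character(disc$subtype[sel_d]),
                         nfolds = cfg$panel_folds, seed = cfg$panel_seed)
      curve <- if (length(pm$selected_features))
        incremental_panel_auc(pm, disc$x[, sel_d, drop = FALSE],
                              as.character(disc$subtype[sel_d]),
                              vali$x[, sel_v, drop = FALSE],
                              as.character(vali$subtype[sel_v]))
      list(model = pm, curve = curve)
    })
    manifest$stages$panel$n_selected <- length(panel$model$selected_features)
    if (!is.null(panel$curve)) write_stage_tsv(panel$curve, cfg$out_dir, "panel_auc")
  }

  if (!is.null(cfg$out_dir))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  list(manifest = manifest, data = dat, fits = fits, specificity = spec,
       coexpression = coex, auc = auc, panel = panel)
}

# strip S3 classes recursively so a config serializes cleanly to JSON
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
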