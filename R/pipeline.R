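#' Read and validate a run configuration
#'
#' The configuration is one YAML file with a versioned schema holding the
#' read layout, input paths, model specification and screen parameters. All
#' analysis thresholds (p < 0.01, 10% tail fraction, 1% FDR, matching
#' tolerance 1) are named parameters with those values as defaults.
#'
#' @param path YAML file path.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg, dir = dirname(path))
}

#' @rdname read_run_config
#' @param cfg a list with the same structure as the YAML file.
#' @param dir directory against which relative paths resolve.
#' @export
as_run_config <- function(cfg, dir = ".") {
  defaults <- list(
    schema_version = 1L,
    tolerance = 1L,
    layout = list(anchor = "GTACGGATCC", umi_len = 15L, bc1_len = 10L,
                  bc2_len = 10L,
                  segment_order = c("UMI", "ANCHOR", "BC1", "BC2"),
                  anchor_max_mismatch = 2L),
    model = list(treatment = "treatment", blocks = NULL, reference = NULL),
    screen = list(k = 5L, pc = 2L, fraction = 0.10, alpha = 0.01,
                  fdr = 0.01, n_perm = 1000L, gsea_weight = 1,
                  min_set_size = 3L, seed = 1L),
    outdir = "idseq_run")
  cfg <- utils::modifyList(defaults, cfg)
  for (key in c("fastq", "panel", "plate", "inhibition")) {
    if (!is.null(cfg[[key]]) && !grepl("^/", cfg[[key]]))
      cfg[[key]] <- file.path(dir, cfg[[key]])
  }
  for (key in c("panel", "plate")) {
    if (is.null(cfg[[key]]))
      stop("config error: required input '", key, "' missing")
    if (!file.exists(cfg[[key]]))
      stop("config error: ", key, " file not found: ", cfg[[key]])
  }
  structure(cfg, class = "run_config")
}

#' Run the full pipeline from a configuration
#'
#' Chains demultiplexing, size-factor normalization, the per-antibody
#' differential model and (when an inhibition matrix is configured) the
#' screen layer, writing each stage's output plus a provenance manifest
#' (package version, seeds, input hashes) to the output directory. All
#' stochastic steps consume seeds recorded in the manifest, so re-running
#' from the same config reproduces every output byte-identically.
#'
#' @param config a `run_config` (from [read_run_config()] /
#'   [as_run_config()]) or a path to a YAML config.
#' @return the output directory, invisibly; stage outputs on disk:
#'   `counts.tsv`, `demux_qc.json`, `size_factors.tsv`, `diff_table.tsv`,
#'   and under screen mode `signed_p.tsv`, `estimates.tsv`,
#'   `pca_scores.tsv`, `pca_loadings.tsv`, `contrast.tsv`, `probe_sets.json`,
#'   `enrichment.tsv`, `profiles.tsv`, plus `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  layout <- stage("config", do.call(read_layout, config$layout))
  panel <- stage("config", read_antibody_panel(config$panel))
  plate <- stage("config", read_plate_map(config$plate))
  stage("config", {
    for (p in list(panel, plate)) {
      v <- validate_panel(p, config$tolerance)
      if (!v$pass)
        stop("barcodes too close for tolerance ", config$tolerance,
             " (min distance ", v$min_distance, ")")
    }
  })

  if (is.null(config$fastq))
    stop("stage 'demux' failed: no fastq input configured", call. = FALSE)
  umi <- stage("demux",
               count_umis(config$fastq, layout, panel, plate,
                          tolerance = config$tolerance))
  write_counts(umi, file.path(outdir, "counts.tsv"))
  jsonlite::write_json(demux_report(umi),
                       file.path(outdir, "demux_qc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  sf <- stage("normalize", size_factors(umi))
  utils::write.table(
    data.frame(well_id = names(sf), size_factor = unclass(sf)),
    file.path(outdir, "size_factors.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  spec <- stage("diff", model_spec(plate, treatment = config$model$treatment,
                                   blocks = config$model$blocks,
                                   reference = config$model$reference))
  per_level <- length(spec$treatment_levels) > 2L
  if (!per_level) {
    dt <- stage("diff", differential_table(umi, spec, sf))
    write_diff_table(dt, file.path(outdir, "diff_table.tsv"))
    signed_p <- NULL
  } else {
    ## screen mode: contrast every treatment level (probe) against the
    ## reference, building probes x phenotypes signed-p / estimate matrices
    ref <- config$model$reference %||% spec$treatment_levels[1L]
    cov <- plate$covariates
    levels_all <- setdiff(spec$treatment_levels, ref)
    signed_p <- matrix(NA_real_, length(levels_all), nrow(umi$counts),
                       dimnames = list(levels_all, rownames(umi$counts)))
    estimates <- signed_p
    for (lv in levels_all) {
      keep <- cov[[config$model$treatment]] %in% c(ref, lv)
      sub_plate <- cov[keep, , drop = FALSE]
      sub_spec <- stage("diff",
                        model_spec(sub_plate,
                                   treatment = config$model$treatment,
                                   blocks = config$model$blocks,
                                   reference = ref))
      dt <- stage("diff", differential_table(
        umi$counts[, keep, drop = FALSE], sub_spec, sf[keep]))
      signed_p[lv, ] <- dt$signed_logp
      estimates[lv, ] <- dt$estimate
    }
    utils::write.table(cbind(probe = rownames(signed_p),
                             as.data.frame(signed_p)),
                       file.path(outdir, "signed_p.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cbind(probe = rownames(estimates),
                             as.data.frame(estimates)),
                       file.path(outdir, "estimates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(signed_p) && !is.null(config$inhibition)) {
    scr <- config$screen
    pca <- stage("screen-pca", screen_pca(impute_screen_matrix(signed_p),
                                          k = min(scr$k, dim(signed_p))))
    utils::write.table(cbind(probe = rownames(pca$scores),
                             as.data.frame(pca$scores)),
                       file.path(outdir, "pca_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cbind(phenotype = rownames(pca$loadings),
                             as.data.frame(pca$loadings)),
                       file.path(outdir, "pca_loadings.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pc <- pca$scores[, min(scr$pc, ncol(pca$scores))]
    ctr <- stage("contrast",
                 decile_contrast(impute_screen_matrix(signed_p), pc,
                                 fraction = scr$fraction,
                                 alpha = scr$alpha, fdr = scr$fdr))
    utils::write.table(ctr, file.path(outdir, "contrast.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    inh <- stage("probe-sets", {
      df <- read_delim_auto(config$inhibition)
      m <- as.matrix(df[, -1L, drop = FALSE]); rownames(m) <- df[[1L]]
      m
    })
    sets <- stage("probe-sets", assign_probe_sets(inh, alpha = scr$alpha))
    jsonlite::write_json(lapply(sets, unclass),
                         file.path(outdir, "probe_sets.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    enr <- stage("gsea", gsea(pc, sets, weight = scr$gsea_weight,
                              n_perm = scr$n_perm, seed = scr$seed,
                              min_size = scr$min_set_size))
    utils::write.table(as.data.frame(enr), file.path(outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    prof <- stage("profiles", {
      keep <- vapply(sets, function(s) length(s$members) >= scr$min_set_size,
                     logical(1))
      kinase_profiles(impute_screen_matrix(estimates), sets[keep])
    })
    utils::write.table(cbind(kinase = rownames(prof$mean),
                             as.data.frame(prof$mean)),
                       file.path(outdir, "profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  inputs <- Filter(Negate(is.null),
                   config[c("fastq", "panel", "plate", "inhibition")])
  manifest <- list(
    package = "idseqr",
    version = as.character(utils::packageVersion("idseqr")),
    schema_version = config$schema_version,
    seeds = list(screen = config$screen$seed),
    tolerance = config$tolerance,
    input_md5 = as.list(tools::md5sum(unlist(inputs))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
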