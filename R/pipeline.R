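pipeline_schema <- list(
  top = c("seed", "q_threshold", "fc_threshold", "pseudocount", "rank_scope",
          "require_degs", "simulate", "inputs"),
  simulate = c("scenario", "n_genes", "n_naive", "n_diseased", "noise_sd",
               "n_de", "log2fc", "prop_up", "pathway_sizes", "rho",
               "model_label"),
  inputs = c("matrices", "metadata", "gmt", "human_profiles", "ortholog_table")
)

#' Build and validate a pipeline configuration
#'
#' A configuration is a plain YAML file (or an equivalent named list) with a
#' strict schema: unknown keys are rejected by name. Top-level keys:
#' `seed`, `q_threshold` (default 0.1), `fc_threshold` (default 1.5),
#' `pseudocount` (default 1), `rank_scope` (`global`/`pathway`),
#' `require_degs` (logical), and exactly one of:
#' \itemize{
#'   \item `simulate`: `scenario: panel` (keys n_genes, n_naive, n_diseased,
#'     noise_sd, n_de, log2fc, prop_up, model_label) or `scenario: paired`
#'     (keys pathway_sizes, rho);
#'   \item `inputs`: paths — `matrices` (named list model -> expression TSV),
#'     `metadata` (sample-annotation TSV), `gmt`, `human_profiles` (named
#'     list label -> DE-profile TSV), optional `ortholog_table`.
#' }
#'
#' @param x path to a YAML config file, or a named list.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  check_keys <- function(keys, allowed, where) {
    unknown <- setdiff(keys, allowed)
    if (length(unknown) > 0L)
      stop("unknown config key", if (length(unknown) > 1L) "s", " in ", where,
           ": ", paste(unknown, collapse = ", "))
  }
  check_keys(names(cfg), pipeline_schema$top, "top level")
  if (!is.null(cfg$simulate))
    check_keys(names(cfg$simulate), pipeline_schema$simulate, "simulate")
  if (!is.null(cfg$inputs))
    check_keys(names(cfg$inputs), pipeline_schema$inputs, "inputs")
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop("config needs either a 'simulate' scenario or an 'inputs' block")
  defaults <- list(seed = 1L, q_threshold = 0.1, fc_threshold = 1.5,
                   pseudocount = 1, rank_scope = "global", require_degs = FALSE)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (!cfg$rank_scope %in% c("global", "pathway"))
    stop("rank_scope must be 'global' or 'pathway'")
  if (!is.null(cfg$simulate) &&
      !identical(cfg$simulate$scenario, "panel") &&
      !identical(cfg$simulate$scenario, "paired"))
    stop("simulate scenario must be 'panel' or 'paired'")
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate-or-load, per-model differential expression, DEG-set
#' comparison, pathway summaries, and cross-species association from a
#' single validated config, writing every stage's table plus a run manifest
#' into `out_dir`. Reruns with the same config and seed are byte-identical.
#'
#' @param config a `pipeline_config` (or path / list accepted by
#'   [pipeline_config()]).
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list of the in-memory stage results; files written:
#'   `config.yaml`, `de_<model>.tsv`, `venn_counts.tsv`,
#'   `pathway_summary.tsv`, `association.tsv`, `truth.tsv` (simulated runs),
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config_path <- file.path(out_dir, "config.yaml")
  writeLines(yaml::as.yaml(unclass(cfg)), config_path)

  de_tables <- list()
  mouse_profiles <- NULL
  human_profiles <- NULL
  sets <- NULL
  truth <- NULL
  ortho <- NULL

  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    if (identical(sim$scenario, "panel")) {
      effect <- if (!is.null(sim$n_de))
        list(n_de = sim$n_de, log2fc = sim$log2fc,
             prop_up = if (is.null(sim$prop_up)) 0.5 else sim$prop_up)
      res <- simulate_panel_counts(
        n_genes = if (is.null(sim$n_genes)) 770 else sim$n_genes,
        n_naive = if (is.null(sim$n_naive)) 5 else sim$n_naive,
        n_diseased = if (is.null(sim$n_diseased)) 7 else sim$n_diseased,
        effect_spec = effect,
        noise_sd = if (is.null(sim$noise_sd)) 0.5 else sim$noise_sd,
        seed = cfg$seed,
        model_label = if (is.null(sim$model_label)) "simulated" else sim$model_label)
      ann <- res$annotation
      tab <- de_analysis(res$matrix, ann, pseudocount = cfg$pseudocount,
                         q_threshold = cfg$q_threshold,
                         fc_threshold = cfg$fc_threshold)
      de_tables[[attr(tab, "model_label")]] <- tab
      truth <- res$truth
    } else {
      res <- simulate_paired_profiles(
        pathway_sizes = sim$pathway_sizes,
        rho_per_pathway = if (is.null(sim$rho)) 1 else sim$rho,
        seed = cfg$seed)
      mouse_profiles <- list(res$mouse)
      human_profiles <- list(res$human)
      sets <- res$sets
      truth <- res$truth
    }
  } else {
    inp <- cfg$inputs
    ann_all <- if (!is.null(inp$metadata)) read_sample_annotation(inp$metadata)
    for (model in names(inp$matrices)) {
      mat <- read_expression_matrix(inp$matrices[[model]],
                                    scale_tag = "normalized")
      ann <- ann_all[ann_all$model_label == model &
                       ann_all$sample_id %in% colnames(mat), , drop = FALSE]
      de_tables[[model]] <- de_analysis(mat, ann, model_label = model,
                                        pseudocount = cfg$pseudocount,
                                        q_threshold = cfg$q_threshold,
                                        fc_threshold = cfg$fc_threshold)
    }
    if (!is.null(inp$gmt)) sets <- read_gene_sets_gmt(inp$gmt)
    if (!is.null(inp$human_profiles))
      human_profiles <- lapply(names(inp$human_profiles), function(lbl)
        read_de_profile(inp$human_profiles[[lbl]], label = lbl))
    if (!is.null(inp$ortholog_table))
      ortho <- utils::read.table(inp$ortholog_table, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
  }

  counts <- list()
  for (model in names(de_tables)) {
    path <- file.path(out_dir, paste0("de_", gsub("[^A-Za-z0-9_.-]", "_", model), ".tsv"))
    write_de_table(de_tables[[model]], path)
    counts[[paste0("de_", model)]] <- nrow(de_tables[[model]])
  }
  if (length(de_tables) >= 2L) {
    venn <- compare_deg_sets(de_tables)
    utils::write.table(as.data.frame(venn), file.path(out_dir, "venn_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts$venn <- nrow(venn)
  } else venn <- NULL
  if (!is.null(sets) && length(de_tables) > 0L) {
    summ <- do.call(rbind, lapply(de_tables, pathway_deg_summary, sets = sets))
    rownames(summ) <- NULL
    utils::write.table(summ, file.path(out_dir, "pathway_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts$pathway_summary <- nrow(summ)
  } else summ <- NULL
  assoc <- NULL
  if (!is.null(sets) && !is.null(human_profiles)) {
    mouse_in <- if (!is.null(mouse_profiles)) mouse_profiles else de_tables
    assoc <- association_table(mouse_in, human_profiles, sets,
                               ortholog_table = ortho,
                               require_degs = isTRUE(cfg$require_degs),
                               rank_scope = cfg$rank_scope)
    utils::write.table(assoc, file.path(out_dir, "association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts$association <- nrow(assoc)
  }
  if (!is.null(truth)) {
    utils::write.table(truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts$truth <- nrow(truth)
  }

  manifest <- list(
    config_hash = unname(tools::md5sum(config_path)),
    package = "crossdeg",
    version = as.character(utils::packageVersion("crossdeg")),
    seed = cfg$seed,
    stage_rows = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(de_tables = de_tables, venn = venn, pathway_summary = summ,
                 association = assoc, truth = truth, manifest = manifest))
}
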