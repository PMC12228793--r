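#' Validate a pipeline configuration
#'
#' The configuration is a nested list (typically read from a YAML file) with
#' one block per stage. Unknown blocks or keys are errors, not warnings.
#'
#' @param config list or path to a YAML file.
#' @return the validated configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  allowed <- list(
    simulate = names(formals(sim_config)),
    qc = names(formals(qc_thresholds)),
    score = c("alpha", "scale"),
    classify = c("rule", "k"),
    noise = c("depth", "fraction", "min_cells"),
    deg = c("lfc_cut", "q_cut", "pc"),
    commune = c("n_perm", "Kh", "p_cut", "n_decoys", "sasp_only"),
    dorc = c("half_window", "n_bg", "p_cut", "n_sig_min"),
    dynamics = c("cells_per_bin", "span"),
    run = c("out_dir", "seed", "stages"))
  bad <- setdiff(names(config), names(allowed))
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))
  for (blk in names(config)) {
    extra <- setdiff(names(config[[blk]]), allowed[[blk]])
    if (length(extra))
      stop("unknown key(s) in block '", blk, "': ", paste(extra, collapse = ", "))
  }
  config
}

cfg_get <- function(config, block, key, default) {
  v <- config[[block]][[key]]
  if (is.null(v)) default else v
}

#' Run the full synthetic-study pipeline
#'
#' Drives simulate -> qc -> normalize -> score -> classify -> noise -> deg ->
#' sasp -> commune -> dorc -> dynamics on the synthetic multiome, writing
#' stage outputs as TSVs under `out_dir` and returning a run manifest
#' (config echo, seed, per-stage output paths and row counts). Stages fail
#' fast with stage-named errors.
#'
#' @param config list or YAML path (see [validate_config()]).
#' @param out_dir output directory.
#' @param seed master seed; stage seeds derive from it.
#' @return the manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("senatlas_run_"),
                         seed = 1) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, config = config, stages = list(),
                   version = as.character(utils::packageVersion("senatlas")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) stop("stage '", name, "': ", conditionMessage(e),
                                            call. = FALSE))
  }
  emit <- function(name, df, file) {
    path <- file.path(out_dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages[[name]] <<- list(path = path, rows = nrow(df))
    path
  }

  sim_args <- config$simulate
  sim_args$seed <- cfg_get(config, "simulate", "seed", seed)
  sim <- stage("simulate", generate_multiome(do.call(sim_config, sim_args)))
  th <- stage("qc", do.call(qc_thresholds, config$qc %||% list()))
  qcr <- stage("qc", qc_filter(sim$rna, sim$atac, th))
  emit("qc", qcr$report, "qc_report.tsv")
  rna <- stage("normalize", normalize_log(qcr$rna, cfg_get(config, "score", "scale", 1e4)))
  atac <- qcr$atac

  st <- stage("score", score_all(rna, sim$gene_sets,
                                 alpha = cfg_get(config, "score", "alpha", 0.25)))
  emit("score", data.frame(cell_id = rownames(st$scores), st$scores), "scores.tsv")
  call <- stage("classify", uss_classify(st, rna$cells$cell_type,
                                         rule = cfg_get(config, "classify", "rule", "all"),
                                         k = cfg_get(config, "classify", "k", 3)))
  frac <- sn_fraction_table(call, rna$cells)
  emit("classify", frac, "sn_fractions.tsv")

  depth <- cfg_get(config, "noise", "depth", round(sim$config$rna_depth_mean / 2))
  inv <- stage("noise", select_invariant_genes(rna, cfg_get(config, "noise", "fraction", 0.10)))
  noise <- stage("noise", transcriptional_noise(rna, inv, depth, seed = seed + 1,
                                                min_cells = cfg_get(config, "noise", "min_cells", 10)))
  emit("noise", noise$per_type, "noise_per_type.tsv")

  lfc <- cfg_get(config, "deg", "lfc_cut", 0.5)
  qv <- cfg_get(config, "deg", "q_cut", 0.05)
  de_list <- stage("deg", {
    types <- unique(rna$cells$cell_type)
    out <- list()
    for (ct in types) {
      sel <- rna$cells$cell_type == ct
      sn <- call$senescent[sel]
      if (sum(sn) >= 3 && sum(!sn) >= 3) {
        sub <- subset_cells(rna, rna$cells$cell_id[sel])
        out[[ct]] <- rank_sum_de(sub, sn, pc = cfg_get(config, "deg", "pc", 0.01))
      }
    }
    out
  })
  catalog <- stage("deg", sn_deg_catalog(de_list, lfc_cut = lfc, q_cut = qv))
  emit("deg", data.frame(direction = c("up", "down"),
                         n_union = c(length(catalog$up_union), length(catalog$down_union))),
       "deg_summary.tsv")
  sasp <- stage("sasp", intersect_sasp(catalog, sim$gene_sets$sets$SASP))
  emit("sasp", data.frame(k = seq_along(sasp$shared_at_least),
                          shared_at_least = sasp$shared_at_least,
                          shared_exactly = sasp$shared_exactly), "sasp_sharing.tsv")

  lrt <- stage("commune", generate_lr_table(sim$config, sim$truth,
                                            n_decoys = cfg_get(config, "commune", "n_decoys", 20)))
  nperm <- cfg_get(config, "commune", "n_perm", 100)
  young_ids <- rna$cells$cell_id[rna$cells$age_group == "young"]
  aged_ids <- rna$cells$cell_id[rna$cells$age_group == "aged"]
  tens_y <- stage("commune", permutation_significance(subset_cells(rna, young_ids), lrt,
                                                      n_perm = nperm, seed = seed + 2, group = "young"))
  tens_a <- stage("commune", permutation_significance(subset_cells(rna, aged_ids), lrt,
                                                      n_perm = nperm, seed = seed + 3, group = "aged"))
  strength <- stage("commune", interaction_strength(tens_a, tens_y,
                                                    p_cut = cfg_get(config, "commune", "p_cut", 0.05)))
  emit("commune", data.frame(group = c("aged", "young"),
                             total_strength = c(strength$total, strength$total_b)),
       "interaction_strength.tsv")

  dorc <- stage("dorc", build_dorc(atac, rna, sim$tss,
                                   genes = c(sim$truth$dorc_genes, sim$truth$lead_genes,
                                             unlist(sim$truth$tf_targets, use.names = FALSE)),
                                   half_window = cfg_get(config, "dorc", "half_window", 50000),
                                   n_bg = cfg_get(config, "dorc", "n_bg", 100),
                                   p_cut = cfg_get(config, "dorc", "p_cut", 0.05),
                                   n_sig_min = cfg_get(config, "dorc", "n_sig_min", 5),
                                   seed = seed + 4))
  emit("dorc", dorc$genes, "dorc_genes.tsv")
  reg <- stage("dorc", regulation_score(dorc, sim$motif_hits, rna))
  emit("dorc", as.data.frame(reg), "regulation_scores.tsv")

  cpb <- cfg_get(config, "dynamics", "cells_per_bin",
                 max(5L, floor(ncol(rna$counts) / 100)))
  leads <- stage("dynamics", {
    pt <- sim$truth$pseudotime[colnames(rna$counts)]
    lg <- intersect(sim$truth$lead_genes, rownames(dorc$scores))
    vapply(lg, function(g) {
      dorc_rna_dynamics(dorc$scores[g, ], rna$norm[g, ], pt,
                        cells_per_bin = cpb,
                        span = cfg_get(config, "dynamics", "span", 0.3))$lead_bins
    }, integer(1))
  })
  emit("dynamics", data.frame(gene = names(leads), lead_bins = as.integer(leads)),
       "lead_bins.tsv")

  manifest$results <- list(
    sn_fractions = frac,
    noise_ratio = noise$per_type$ratio_aged_young,
    up_union = length(catalog$up_union), down_union = length(catalog$down_union),
    sasp_union = sasp$union_size,
    strength_aged = strength$total, strength_young = strength$total_b,
    median_lead_bins = stats::median(as.numeric(leads)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
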