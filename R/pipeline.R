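#' Pipeline configuration
#'
#' Assembles and validates the single configuration object that drives
#' [runPipeline()]. With no input paths the pipeline runs on synthetic data
#' generated from \code{sim} (a [simConfig()]); supplying paths switches a
#' stage to user data (bring-your-own-table).
#'
#' @param seed global RNG seed (also forwarded to the simulation config
#'   unless one is supplied).
#' @param alpha significance level for calls and screens.
#' @param lfc_min minimum |log2 fold change| for a directional call.
#' @param shrinkage dispersion shrinkage weight toward the binned trend.
#' @param pseudo pseudo-count for zero group means in the NB contrast.
#' @param strat_method stratification method (\code{mixture} /
#'   \code{threshold}).
#' @param convention network weight convention (\code{repression} /
#'   \code{literal}).
#' @param require_ipc whether the protective filter requires IPC reversal.
#' @param score_min,mirsvr_max,impi_min filtering thresholds.
#' @param sim a [simConfig()]; defaults to \code{simConfig(seed = seed)}.
#' @param annotation_path optional path to a mitochondrial annotation TSV;
#'   \code{NA} keeps the synthetic annotation.
#' @return validated list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(seed = 1L, alpha = 0.05, lfc_min = 0,
                           shrinkage = 0.3, pseudo = 0.5,
                           strat_method = c("mixture", "threshold"),
                           convention = c("repression", "literal"),
                           require_ipc = TRUE,
                           score_min = 80.0, mirsvr_max = -1.2,
                           impi_min = 0.7,
                           sim = NULL, annotation_path = NA_character_) {
  strat_method <- match.arg(strat_method)
  convention <- match.arg(convention)
  .assertScalarProb(alpha, "alpha")
  if (is.null(sim)) sim <- simConfig(seed = seed)
  if (!inherits(sim, "simConfig")) sim <- do.call(simConfig, as.list(sim))
  structure(list(seed = as.integer(seed), alpha = alpha, lfc_min = lfc_min,
                 shrinkage = shrinkage, pseudo = pseudo,
                 strat_method = strat_method, convention = convention,
                 require_ipc = require_ipc, score_min = score_min,
                 mirsvr_max = mirsvr_max, impi_min = impi_min, sim = sim,
                 annotation_path = annotation_path),
            class = "pipelineConfig")
}

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full responder/network pipeline
#'
#' Executes the stages in order — stratify, differential expression per
#' contrast, regulation calls, protective-pattern selection and category
#' partition, signed network construction, mitochondrial subnetwork — and
#' writes every stage output plus a manifest into \code{outdir}. Re-running
#' with the same configuration reproduces the outputs (deterministic
#' stages byte-identically).
#'
#' @param config a [pipelineConfig()] (or list coercible to one).
#' @param outdir output directory, created if missing.
#' @return invisibly, a list with the in-memory stage results
#'   (\code{stratification}, \code{contrasts}, \code{calls},
#'   \code{selected}, \code{categories}, \code{network}, \code{mito_network},
#'   \code{manifest}).
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = tempfile()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)  # structured config file
  if (!inherits(config, "pipelineConfig"))
    config <- do.call(pipelineConfig, config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- .configHash(config)
  note <- paste0("config_hash: ", hash)
  counts_log <- list()

  # -- inputs ---------------------------------------------------------------
  inputs <- .stage("simulate", {
    list(troponin = simulateTroponin(config$sim),
         se = simulateMirCounts(config$sim),
         dbs = simulateInteractionDbs(config$sim),
         # kept as a path here so a missing file surfaces in the mito stage
         ann = if (is.na(config$annotation_path))
           simulateMitoAnnotation(config$sim)$annotation
         else config$annotation_path)
  })

  # -- stratification -------------------------------------------------------
  strat <- .stage("stratify", {
    an <- inputs$troponin$animals
    tni <- stats::setNames(an$tni, an$animal_id)
    splitResponders(tni[an$arm == "IPoC"],
                    reference_ir = tni[an$arm == "IR"],
                    reference_ipc = tni[an$arm == "IPC"],
                    method = config$strat_method)
  })
  lab_df <- data.frame(animal_id = names(responderLabels(strat)),
                       label = unname(responderLabels(strat)),
                       posterior = unname(strat@posterior),
                       method = strat@method, stringsAsFactors = FALSE)
  .writeTableWithComment(lab_df, file.path(outdir, "responder_labels.csv"),
                         note, sep = ",")
  .writeTableWithComment(summarizeGroups(inputs$troponin$animals, strat),
                         file.path(outdir, "group_summary.tsv"), note)
  counts_log$stratify <- c(input = nrow(lab_df),
                           responders = sum(lab_df$label == "responder"))

  # -- differential expression ----------------------------------------------
  de <- .stage("differential_expression", {
    se <- inputs$se
    cnt <- SummarizedExperiment::assay(se, "counts")
    # pipeline groups come from the estimated stratification, not the truth
    grp <- se$arm
    ipoc <- grp == "IPoC"
    est <- responderLabels(strat)[colnames(se)[ipoc]]
    grp[ipoc] <- ifelse(est == "responder", "IPoC_R", "IPoC_NR")
    sf <- medianOfRatios(cnt)
    disp <- estimateDispersion(cnt, sf, groups = grp,
                               shrinkage = config$shrinkage)
    specs <- list(IR_vs_Sham = c("IR", "Sham"),
                  IPC_vs_IR = c("IPC", "IR"),
                  IPoCR_vs_IR = c("IPoC_R", "IR"),
                  IPoCNR_vs_IR = c("IPoC_NR", "IR"))
    res <- lapply(specs, function(ct)
      nbWaldContrast(cnt, sf, disp, grp, ct, pseudo = config$pseudo))
    for (nm in names(res)) {
      res[[nm]]$contrast <- nm
      .writeTableWithComment(res[[nm]],
        file.path(outdir, paste0("contrast_", nm, ".tsv")), note)
    }
    res
  })
  counts_log$contrasts <- c(n_contrasts = length(de),
                            n_features = nrow(de[[1]]))

  # -- calls, protective filter, partition ----------------------------------
  calls <- .stage("regulation_calls", {
    stacked <- do.call(rbind, de)
    callRegulation(stacked, alpha = config$alpha,
                   lfc_min = config$lfc_min)
  })
  selected <- .stage("protective_filter", {
    out <- protectiveMirFilter(calls, require_ipc = config$require_ipc)
    .writeTableWithComment(out[out$selected, ],
                           file.path(outdir, "selected_mirs.tsv"), note)
    out
  })
  categories <- .stage("pattern_partition", {
    sig <- function(ct) {
      sub <- calls[calls$contrast == ct, ]
      stats::setNames(sub$direction != "unchanged", sub$feature_id)
    }
    feats <- sort(unique(calls$feature_id))
    flags <- data.frame(feature_id = feats,
                        sig_ipc = sig("IPC_vs_IR")[feats],
                        sig_ipocr = sig("IPoCR_vs_IR")[feats],
                        sig_ipocnr = sig("IPoCNR_vs_IR")[feats],
                        row.names = NULL)
    cats <- classifyMrnaPattern(flags)
    .writeTableWithComment(cats, file.path(outdir, "categories.tsv"), note)
    jsonlite::write_json(as.list(table(cats$category)),
                         file.path(outdir, "category_counts.json"),
                         auto_unbox = TRUE)
    cats
  })
  counts_log$protective_filter <- c(
    input = nrow(selected), selected = sum(selected$selected),
    alpha = config$alpha)

  # -- network --------------------------------------------------------------
  net <- .stage("network", {
    raw <- do.call(rbind, inputs$dbs$tables)
    kept <- filterInteractions(raw, score_min = config$score_min,
                               mirsvr_max = config$mirsvr_max)
    counts_log$interaction_filter <- c(
      input = nrow(raw), kept = nrow(kept),
      score_min = config$score_min, mirsvr_max = config$mirsvr_max)
    sel <- selected[selected$selected, ]
    network <- buildNetwork(
      data.frame(mir_id = sel$feature_id, direction = sel$ir_direction,
                 stringsAsFactors = FALSE),
      kept, convention = config$convention)
    .writeTableWithComment(nodeStrength(network),
                           file.path(outdir, "node_strength.tsv"), note)
    exportNetwork(network, file.path(outdir, "network_edges.tsv"),
                  "edgelist")
    exportNetwork(network, file.path(outdir, "network.sif"), "sif")
    network
  })
  counts_log$network <- c(mirs = length(mirNodes(net)),
                          targets = length(targetNodes(net)),
                          edges = nrow(edgeTable(net)))

  # -- mitochondrial subnetwork ---------------------------------------------
  mito_net <- .stage("mito_subnetwork", {
    ann <- loadAnnotation(inputs$ann)
    matches <- reconcileIds(targetNodes(net), ann)
    .writeTableWithComment(matches,
                           file.path(outdir, "mito_matches.tsv"), note)
    kept <- mitoSelect(matches, ann, impi_min = config$impi_min)
    writeLines(kept, file.path(outdir, "mito_targets.txt"))
    subnet <- extractSubnetwork(net, kept)
    .writeTableWithComment(nodeStrength(subnet),
                           file.path(outdir, "mito_node_strength.tsv"),
                           note)
    exportNetwork(subnet, file.path(outdir, "mito_network_edges.tsv"),
                  "edgelist")
    counts_log$mito_filter <- c(
      input = length(targetNodes(net)), kept = length(kept),
      impi_min = config$impi_min)
    subnet
  })
  counts_log$mito_subnetwork <- c(mirs = length(mirNodes(mito_net)),
                                  targets = length(targetNodes(mito_net)),
                                  edges = nrow(edgeTable(mito_net)))

  manifest <- list(
    package = "IPoCnet",
    version = as.character(utils::packageVersion("IPoCnet")),
    seed = config$seed, config_hash = hash,
    contrasts = names(de), stage_counts = counts_log)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(stratification = strat, contrasts = de, calls = calls,
                 selected = selected, categories = categories,
                 network = net, mito_network = mito_net,
                 manifest = manifest, outdir = outdir))
}

#' Human-readable summary of a completed pipeline run
#'
#' Reads the stage outputs of a [runPipeline()] run directory and prints
#' counts per stage: responder split, up-/down-regulated and total
#' differentially expressed miRs (with percentages), selected protective
#' miRs, pattern-category tallies, and the top targets of the
#' mitochondrial subnetwork by |strength|.
#'
#' @param outdir a run directory produced by [runPipeline()].
#' @param top_k number of top targets to list.
#' @param alpha significance level used to count regulated miRs.
#' @return invisibly, the report lines (character vector); printed as a
#'   side effect.
#' @export
reportSummary <- function(outdir, top_k = 10L, alpha = 0.05) {
  manifest_path <- file.path(outdir, "manifest.json")
  if (!file.exists(manifest_path))
    stop("incomplete run directory: no manifest found", call. = FALSE)
  manifest <- jsonlite::read_json(manifest_path)
  lines <- c(sprintf("Pipeline run (seed %s, config %s)",
                     manifest$seed, manifest$config_hash))

  labels <- .readTable(file.path(outdir, "responder_labels.csv"), sep = ",")
  lines <- c(lines, sprintf(
    "Stratification: %d responders / %d non-responders (%s method)",
    sum(labels$label == "responder"), sum(labels$label == "non_responder"),
    labels$method[1]))

  ir <- .readTable(file.path(outdir, "contrast_IR_vs_Sham.tsv"))
  all_ct <- lapply(manifest$contrasts, function(nm)
    .readTable(file.path(outdir, paste0("contrast_", nm, ".tsv"))))
  de_any <- sort(unique(unlist(lapply(all_ct, function(d)
    d$feature_id[d$p <= alpha]))))
  n_de <- length(de_any)
  up <- sum(ir$p <= alpha & ir$log2fc > 0)
  down <- sum(ir$p <= alpha & ir$log2fc < 0)
  lines <- c(lines, sprintf(
    "Differential expression: %d of %d miRs regulated in any contrast",
    n_de, nrow(ir)))
  if (n_de > 0) lines <- c(lines, sprintf(
    "  injury: %d up (%.1f%%), %d down (%.1f%%) of %d",
    up, percentOf(up, n_de), down, percentOf(down, n_de), n_de))

  sel <- .readTable(file.path(outdir, "selected_mirs.tsv"))
  lines <- c(lines, sprintf("Protective-pattern miRs selected: %d",
                            nrow(sel)))

  cat_counts <- jsonlite::read_json(file.path(outdir,
                                              "category_counts.json"))
  lines <- c(lines, "Pattern categories:",
             paste0("  ", names(cat_counts), ": ",
                    unlist(cat_counts), collapse = "\n"))

  ms <- .readTable(file.path(outdir, "mito_node_strength.tsv"))
  if (nrow(ms) == 0L) {
    lines <- c(lines, "Mitochondrial subnetwork: none")
  } else {
    kk <- utils::head(ms, top_k)
    lines <- c(lines,
               sprintf("Top %d mitochondrial targets by |strength|:",
                       nrow(kk)),
               sprintf("  %-12s strength %+d (degree %d)", kk$target_id,
                       kk$strength, kk$degree))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
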