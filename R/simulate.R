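#' Simulation configuration for the synthetic conditioning study
#'
#' Builds and validates the configuration object consumed by all synthetic
#' data generators. The defaults emulate the structure of a four-arm rat
#' ischaemia/reperfusion study: 20 animals per arm, a bimodal troponin I
#' distribution in the post-conditioned (IPoC) arm with 40% responders
#' (8 responders / 12 non-responders at the default arm size), 627 expressed
#' miRs of which 286 are differentially regulated (82 up and 77 down after
#' I/R; the remainder regulated by conditioning only), conditioning-dependent
#' reversal of the I/R changes, and interaction/annotation tables with
#' realistic identifier aliasing.
#'
#' All generators draw from per-generator substreams derived from the single
#' \code{seed}, so the same configuration always reproduces identical
#' outputs and adding a generator never perturbs existing ones.
#'
#' @param seed integer, the single global RNG seed.
#' @param n_per_arm animals per experimental arm.
#' @param responder_fraction proportion of the IPoC arm planted as
#'   responders (in (0,1)).
#' @param tni_params named list of per-group \code{c(meanlog, sdlog)}
#'   parameters (natural-log scale, ng/mL) for the troponin I draw; groups
#'   \code{Sham, IR, IPC, IPoC_R, IPoC_NR}. Injury markers are right-skewed,
#'   hence the log-normal model.
#' @param n_mirs number of expressed miRs.
#' @param n_de number of differentially expressed miRs (any contrast).
#' @param n_up,n_down number of miRs up-/down-regulated by I/R vs Sham.
#' @param reversal_fractions named list (\code{IPC}, \code{IPoCR},
#'   \code{IPoCNR}), each a \code{c(up=, down=)} pair: fraction of
#'   I/R-regulated miRs whose change that arm reverses.
#' @param enhanced_fractions \code{c(up=, down=)}: fraction of I/R-regulated
#'   miRs whose change is further enhanced (same direction, larger
#'   magnitude) in non-responders.
#' @param dispersion NB dispersion, scalar or per-feature vector
#'   (variance = mu + dispersion * mu^2).
#' @param lib_size_range multiplicative span of per-sample library-size
#'   factors (drawn log-uniform).
#' @param lfc_range magnitude range for planted |log2 fold changes|.
#' @param db_sizes named record counts for the three interaction dialects
#'   (\code{validated}, \code{predicted_score}, \code{predicted_mirsvr}).
#' @param n_targets size of the target-gene vocabulary.
#' @param mito_fraction proportion of target genes planted as mitochondrial.
#' @param alias_rate fraction of annotation rows with blanked or aliased
#'   identifier columns (exercises the reconciliation cascade).
#' @param qpcr_noise_sd additive Ct noise SD for the qPCR generator.
#' @return a validated list of class \code{"simConfig"}.
#' @export
simConfig <- function(seed = 1L,
                      n_per_arm = 20L,
                      responder_fraction = 0.4,
                      tni_params = NULL,
                      n_mirs = 627L,
                      n_de = 286L,
                      n_up = 82L,
                      n_down = 77L,
                      reversal_fractions = NULL,
                      enhanced_fractions = c(up = 4 / 82, down = 1 / 77),
                      dispersion = 0.1,
                      lib_size_range = c(0.5, 2),
                      lfc_range = c(1, 3),
                      db_sizes = c(validated = 300L, predicted_score = 400L,
                                   predicted_mirsvr = 400L),
                      n_targets = 250L,
                      mito_fraction = 0.3,
                      alias_rate = 0.2,
                      qpcr_noise_sd = 0.25) {
  if (is.null(tni_params))
    tni_params <- list(
      Sham    = c(meanlog = log(0.5), sdlog = 0.40),
      IR      = c(meanlog = log(60),  sdlog = 0.35),
      IPC     = c(meanlog = log(8),   sdlog = 0.35),
      IPoC_R  = c(meanlog = log(8),   sdlog = 0.35),
      IPoC_NR = c(meanlog = log(60),  sdlog = 0.35))
  if (is.null(reversal_fractions))
    reversal_fractions <- list(
      IPC    = c(up = 0.5,     down = 0.85),
      IPoCR  = c(up = 23 / 82, down = 20 / 77),
      IPoCNR = c(up = 0,       down = 0))

  n_per_arm <- .assertCount(n_per_arm, "n_per_arm")
  n_mirs <- .assertCount(n_mirs, "n_mirs")
  n_de <- .assertCount(n_de, "n_de")
  n_up <- .assertCount(n_up, "n_up", positive = FALSE)
  n_down <- .assertCount(n_down, "n_down", positive = FALSE)
  .assertScalarProb(responder_fraction, "responder_fraction")
  if (n_up + n_down > n_de)
    stop("invalid config: n_up + n_down must not exceed n_de", call. = FALSE)
  if (n_de > n_mirs)
    stop("invalid config: n_de must not exceed n_mirs", call. = FALSE)
  if (!all(is.finite(dispersion)) || any(dispersion <= 0))
    stop("parameter 'dispersion' must be > 0", call. = FALSE)
  if (length(lib_size_range) != 2L || any(lib_size_range <= 0) ||
      lib_size_range[1] > lib_size_range[2])
    stop("parameter 'lib_size_range' must be an increasing positive pair",
         call. = FALSE)
  for (g in names(tni_params))
    if (tni_params[[g]][2] <= 0)
      stop("parameter error: non-positive spread for TnI group ", g,
           call. = FALSE)
  for (a in names(reversal_fractions))
    for (v in reversal_fractions[[a]])
      .assertScalarProb(v, paste0("reversal_fractions$", a), open = FALSE)
  .assertScalarProb(mito_fraction, "mito_fraction", open = FALSE)
  .assertScalarProb(alias_rate, "alias_rate", open = FALSE)
  if (any(db_sizes < 0)) stop("db_sizes must be non-negative", call. = FALSE)

  structure(list(
    seed = as.integer(seed), n_per_arm = n_per_arm,
    responder_fraction = responder_fraction, tni_params = tni_params,
    n_mirs = n_mirs, n_de = n_de, n_up = n_up, n_down = n_down,
    reversal_fractions = reversal_fractions,
    enhanced_fractions = enhanced_fractions,
    dispersion = dispersion, lib_size_range = lib_size_range,
    lfc_range = lfc_range, db_sizes = db_sizes, n_targets = n_targets,
    mito_fraction = mito_fraction, alias_rate = alias_rate,
    qpcr_noise_sd = qpcr_noise_sd), class = "simConfig")
}

# stream indices for the per-generator substreams ('counts' seeds the
# planted effect structure, 'counts_noise' the NB draws on top of it)
.STREAMS <- c(labels = 1L, troponin = 2L, counts = 3L, qpcr = 4L,
              interactions = 5L, annotation = 6L, counts_noise = 7L)

# Responder labels are planted (assigned, not sampled in number): exactly
# round(responder_fraction * n_per_arm) animals of the IPoC arm are
# responders; which ones is a seeded permutation. Both the troponin and the
# count generator call this, so their labels always agree.
.plantResponders <- function(config) {
  n <- config$n_per_arm
  n_resp <- as.integer(round(config$responder_fraction * n))
  ids <- sprintf("IPoC%02d", seq_len(n))
  resp <- .withSubstream(config$seed, .STREAMS[["labels"]], {
    ord <- sample.int(n)
    ids[ord[seq_len(n_resp)]]
  })
  stats::setNames(ids %in% resp, ids)
}

.armIds <- function(config) {
  n <- config$n_per_arm
  list(Sham = sprintf("Sham%02d", seq_len(n)),
       IR   = sprintf("IR%02d", seq_len(n)),
       IPC  = sprintf("IPC%02d", seq_len(n)),
       IPoC = sprintf("IPoC%02d", seq_len(n)))
}

# five-level group factor for every animal (IPoC split by planted label)
.plantGroups <- function(config) {
  ids <- .armIds(config)
  resp <- .plantResponders(config)
  grp <- c(rep("Sham", length(ids$Sham)), rep("IR", length(ids$IR)),
           rep("IPC", length(ids$IPC)),
           ifelse(resp[ids$IPoC], "IPoC_R", "IPoC_NR"))
  stats::setNames(grp, unlist(ids, use.names = FALSE))
}

#' Simulate plasma troponin I and morphometry for a four-arm study
#'
#' Draws per-animal plasma troponin I (log-normal; injury markers are
#' right-skewed), heart-weight/body-weight ratio and echocardiography
#' summary fields. The Sham arm is low, I/R high, IPC intermediate-low; the
#' IPoC arm is a two-component log-normal mixture whose responder component
#' sits near IPC and whose non-responder component sits near I/R. Responder
#' membership is planted (see [simConfig()]) and recorded in the truth
#' table.
#'
#' @param config a [simConfig()] object.
#' @return list with \code{animals} (one row per animal: \code{animal_id},
#'   \code{arm}, \code{tni} in ng/mL, \code{hw_bw} in mg/g, echo fields) and
#'   \code{truth} (per-animal planted group and responder flag).
#' @export
simulateTroponin <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  groups <- .plantGroups(config)
  ids <- names(groups)
  arm <- sub("[0-9]+$", "", ids)
  tp <- config$tni_params

  # per-group echo/morphometry population parameters (means, SDs) chosen to
  # be realistic for 7-day post-infarct rats
  echo <- list(
    #          hw_bw       HR        FS        EF       LVEDD     AWTd
    Sham    = list(hw = c(2.6, 0.20), hr = c(355, 40), fs = c(62, 10),
                   ef = c(92, 5), edd = c(4.9, 0.6), awt = c(1.7, 0.3)),
    IR      = list(hw = c(3.4, 0.25), hr = c(395, 35), fs = c(46, 12),
                   ef = c(80, 10), edd = c(5.7, 0.9), awt = c(1.8, 0.4)),
    IPC     = list(hw = c(2.9, 0.20), hr = c(420, 35), fs = c(54, 13),
                   ef = c(91, 6), edd = c(5.0, 0.6), awt = c(2.0, 0.3)),
    IPoC_R  = list(hw = c(2.7, 0.20), hr = c(405, 30), fs = c(50, 7),
                   ef = c(86, 5), edd = c(5.5, 0.6), awt = c(1.8, 0.4)),
    IPoC_NR = list(hw = c(3.3, 0.25), hr = c(400, 45), fs = c(42, 13),
                   ef = c(86, 10), edd = c(5.4, 0.8), awt = c(1.9, 0.4)))

  animals <- .withSubstream(config$seed, .STREAMS[["troponin"]], {
    n <- length(ids)
    draw <- function(fld, i) {
      p <- echo[[groups[i]]][[fld]]
      stats::rnorm(1, p[1], p[2])
    }
    tni <- vapply(seq_len(n), function(i) {
      p <- tp[[groups[i]]]
      stats::rlnorm(1, meanlog = p[1], sdlog = p[2])
    }, numeric(1))
    hw_bw <- pmax(0.5, vapply(seq_len(n), draw, numeric(1), fld = "hw"))
    hr <- vapply(seq_len(n), draw, numeric(1), fld = "hr")
    fs <- pmin(99, pmax(1, vapply(seq_len(n), draw, numeric(1), fld = "fs")))
    ef <- pmin(99, pmax(1, vapply(seq_len(n), draw, numeric(1), fld = "ef")))
    lvedd <- pmax(2, vapply(seq_len(n), draw, numeric(1), fld = "edd"))
    # end-systolic dimension as a fraction of end-diastolic keeps the
    # LVESD <= LVEDD invariant by construction
    lvesd <- lvedd * (1 - fs / 100)
    awtd <- pmax(0.5, vapply(seq_len(n), draw, numeric(1), fld = "awt"))
    data.frame(animal_id = ids, arm = arm, tni = tni, hw_bw = hw_bw,
               HR = hr, AWTd = awtd, AWTs = awtd + 1.1,
               PWTd = awtd + 0.05, PWTs = awtd + 1.0,
               LVEDD = lvedd, LVESD = lvesd, FS = fs, EF = ef,
               stringsAsFactors = FALSE)
  })
  truth <- data.frame(animal_id = ids, group = unname(groups),
                      responder = ifelse(arm == "IPoC",
                                         groups == "IPoC_R", NA),
                      stringsAsFactors = FALSE)
  list(animals = animals, truth = truth)
}

# planted per-feature log2 fold-change structure shared by the count
# generator and its truth table
.plantMirEffects <- function(config) {
  n <- config$n_mirs
  mir_ids <- sprintf("rno-miR-%04d-%s", seq_len(n),
                     rep(c("3p", "5p"), length.out = n))
  up_idx <- seq_len(config$n_up)
  down_idx <- config$n_up + seq_len(config$n_down)
  cond_idx <- if (config$n_de > config$n_up + config$n_down)
    (config$n_up + config$n_down + 1L):config$n_de else integer(0)

  .withSubstream(config$seed, .STREAMS[["counts"]], {
    mag <- stats::runif(n, config$lfc_range[1], config$lfc_range[2])
    lfc_ir <- numeric(n)
    lfc_ir[up_idx] <- mag[up_idx]
    lfc_ir[down_idx] <- -mag[down_idx]

    pick <- function(idx, frac) {
      k <- as.integer(round(frac * length(idx)))
      if (k == 0L || length(idx) == 0L) return(integer(0))
      idx[sample.int(length(idx), k)]
    }
    rf <- config$reversal_fractions
    rev_ipc <- c(pick(up_idx, rf$IPC[["up"]]), pick(down_idx, rf$IPC[["down"]]))
    rev_r <- c(pick(up_idx, rf$IPoCR[["up"]]), pick(down_idx, rf$IPoCR[["down"]]))
    rev_nr <- c(pick(up_idx, rf$IPoCNR[["up"]]),
                pick(down_idx, rf$IPoCNR[["down"]]))
    enh_nr <- c(pick(setdiff(up_idx, rev_nr), config$enhanced_fractions[["up"]]),
                pick(setdiff(down_idx, rev_nr),
                     config$enhanced_fractions[["down"]]))

    # absolute (vs Sham) log2 offsets per group
    off_ipc <- lfc_ir; off_ipc[rev_ipc] <- 0
    off_r <- lfc_ir; off_r[rev_r] <- 0
    off_nr <- lfc_ir
    off_nr[rev_nr] <- 0
    off_nr[enh_nr] <- lfc_ir[enh_nr] + sign(lfc_ir[enh_nr]) * 1

    # conditioning-only features: regulated in IPoC-R but not by I/R
    if (length(cond_idx)) {
      s <- rep(c(1, -1), length.out = length(cond_idx))
      off_r[cond_idx] <- s * mag[cond_idx]
    }

    base <- stats::rlnorm(n, meanlog = 4, sdlog = 1.5)
    data.frame(
      mir_id = mir_ids, base_mean = base,
      lfc_ir_vs_sham = lfc_ir,
      lfc_ipc_vs_ir = off_ipc - lfc_ir,
      lfc_ipocr_vs_ir = off_r - lfc_ir,
      lfc_ipocnr_vs_ir = off_nr - lfc_ir,
      is_de = seq_len(n) <= config$n_de,
      reversed_ipc = seq_len(n) %in% rev_ipc,
      reversed_ipocr = seq_len(n) %in% rev_r,
      reversed_ipocnr = seq_len(n) %in% rev_nr,
      enhanced_ipocnr = seq_len(n) %in% enh_nr,
      stringsAsFactors = FALSE)
  })
}

#' Simulate a miR count matrix with planted differential expression
#'
#' Draws negative-binomial counts for every animal of the four-arm study
#' with per-sample library-size factors (log-uniform over
#' \code{lib_size_range}) and planted per-group log2 fold changes:
#' I/R-regulated miRs change vs Sham, conditioning arms reverse a configured
#' fraction of those changes (IPoC non-responders mostly do not; a
#' configurable minority is further enhanced), and the remaining
#' differentially expressed miRs are regulated in the responder arm only.
#'
#' @param config a [simConfig()] object.
#' @return a \code{SummarizedExperiment}: assay \code{"counts"}, per-sample
#'   \code{colData} (\code{arm}, \code{group}, \code{responder},
#'   \code{true_size_factor}) and per-feature \code{rowData} holding the
#'   full truth table (planted log2 fold changes per contrast, reversal and
#'   enhancement flags).
#' @export
simulateMirCounts <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  groups <- .plantGroups(config)
  eff <- .plantMirEffects(config)
  n <- config$n_mirs
  ns <- length(groups)
  alpha <- rep(config$dispersion, length.out = n)

  offsets <- cbind(Sham = 0,
                   IR = eff$lfc_ir_vs_sham,
                   IPC = eff$lfc_ir_vs_sham + eff$lfc_ipc_vs_ir,
                   IPoC_R = eff$lfc_ir_vs_sham + eff$lfc_ipocr_vs_ir,
                   IPoC_NR = eff$lfc_ir_vs_sham + eff$lfc_ipocnr_vs_ir)

  res <- .withSubstream(config$seed, .STREAMS[["counts_noise"]], {
    sf <- exp(stats::runif(ns, log(config$lib_size_range[1]),
                           log(config$lib_size_range[2])))
    counts <- matrix(0L, nrow = n, ncol = ns,
                     dimnames = list(eff$mir_id, names(groups)))
    for (j in seq_len(ns)) {
      mu <- eff$base_mean * 2^offsets[, groups[j]] * sf[j]
      counts[, j] <- if (all(alpha < 1e-12)) stats::rpois(n, mu)
        else stats::rnbinom(n, mu = mu, size = 1 / alpha)
    }
    list(counts = counts, sf = sf)
  })

  cd <- S4Vectors::DataFrame(
    animal_id = names(groups),
    arm = sub("[0-9]+$", "", names(groups)),
    group = unname(groups),
    responder = ifelse(grepl("^IPoC", names(groups)),
                       unname(groups) == "IPoC_R", NA),
    true_size_factor = res$sf,
    row.names = names(groups))
  rd <- S4Vectors::DataFrame(eff, row.names = eff$mir_id)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = res$counts), colData = cd, rowData = rd,
    metadata = list(config = config))
}

#' Simulate a qPCR Ct table with planted group fold changes
#'
#' Generates threshold-cycle values for a set of target genes plus a
#' housekeeping gene across the five study groups, such that double-delta-Ct
#' recovery of the planted fold changes (vs the reference group) is
#' unbiased: \code{Ct = baseCt - log2(fold) + noise} with the housekeeping
#' gene flat across groups.
#'
#' @param config a [simConfig()] object (supplies seed and Ct noise SD).
#' @param fold_truth data.frame with column \code{gene} plus one numeric
#'   column per non-reference group giving the planted fold change vs the
#'   reference; default plants a strong responder-specific induction
#'   (9.74-fold) alongside moderate effects.
#' @param n_per_group samples per group.
#' @param reference_group group the folds are relative to.
#' @param housekeeping_id name of the housekeeping feature.
#' @param noise_sd additive Ct noise SD; \code{0} gives exact recovery.
#' @return list: \code{ct} (feature x sample matrix), \code{samples}
#'   (sample annotation), \code{truth} (the planted folds),
#'   \code{housekeeping_id}.
#' @export
simulateQpcr <- function(config, fold_truth = NULL, n_per_group = 5L,
                         reference_group = "Sham",
                         housekeeping_id = "Gapdh",
                         noise_sd = config$qpcr_noise_sd) {
  stopifnot(inherits(config, "simConfig"))
  grps <- c("Sham", "IR", "IPC", "IPoC_R", "IPoC_NR")
  if (is.null(fold_truth))
    fold_truth <- data.frame(
      gene = c("Serca2a", "Vegfa", "Jdp2"),
      IR = c(0.70, 0.69, 1.76),
      IPC = c(2.99, 0.90, 1.52),
      IPoC_R = c(9.74, 1.60, 0.44),
      IPoC_NR = c(5.02, 1.65, 1.11),
      stringsAsFactors = FALSE)
  if (length(grps) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (housekeeping_id %in% fold_truth$gene)
    stop("housekeeping feature must not appear in fold_truth", call. = FALSE)

  samples <- data.frame(
    sample_id = paste0(rep(grps, each = n_per_group), "_q",
                       seq_len(n_per_group)),
    group = rep(grps, each = n_per_group), stringsAsFactors = FALSE)
  genes <- c(fold_truth$gene, housekeeping_id)
  base_ct <- stats::setNames(c(seq(24, by = 0.5,
                                   length.out = nrow(fold_truth)), 18), genes)

  ct <- .withSubstream(config$seed, .STREAMS[["qpcr"]], {
    m <- matrix(NA_real_, nrow = length(genes), ncol = nrow(samples),
                dimnames = list(genes, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      g <- samples$group[j]
      for (gene in fold_truth$gene) {
        fold <- if (g == reference_group) 1
          else fold_truth[fold_truth$gene == gene, g]
        m[gene, j] <- base_ct[gene] - log2(fold) +
          stats::rnorm(1, 0, noise_sd)
      }
      m[housekeeping_id, j] <- base_ct[housekeeping_id] +
        stats::rnorm(1, 0, noise_sd)
    }
    m
  })
  list(ct = ct, samples = samples, truth = fold_truth,
       housekeeping_id = housekeeping_id)
}

.targetVocab <- function(config) sprintf("Gene%04d", seq_len(config$n_targets))

#' Simulate miR-target interaction tables in three database dialects
#'
#' Emits three interaction tables mimicking the common database dialects:
#' a validated dialect (no score), a prediction-score dialect (score in
#' \code{[0, 100]}) and a mirSVR-style dialect (score \code{<= 0}; more
#' negative means stronger predicted repression). Scores straddle the usual
#' filtering thresholds (80 and -1.2) so that threshold filtering is
#' non-trivial, and the miR/target vocabularies contain both overlapping and
#' disjoint identifiers.
#'
#' @param config a [simConfig()] object.
#' @param mirs miR vocabulary; defaults to the first 60 simulated miR names
#'   plus a few foreign ones absent from the count matrix.
#' @param targets target vocabulary; defaults to the simulated gene
#'   vocabulary plus a few foreign symbols.
#' @return list: \code{tables} (named list of the three data.frames, each
#'   with columns \code{mir_id}, \code{target_id}, \code{source},
#'   \code{score}) and \code{truth} (per-record logical \code{passes} under
#'   the standard thresholds).
#' @export
simulateInteractionDbs <- function(config, mirs = NULL, targets = NULL) {
  stopifnot(inherits(config, "simConfig"))
  if (is.null(mirs)) {
    n_m <- min(60L, config$n_mirs)
    mirs <- c(sprintf("rno-miR-%04d-%s", seq_len(n_m),
                      rep(c("3p", "5p"), length.out = n_m)),
              sprintf("rno-miR-9%03d-3p", 1:5))
  }
  if (is.null(targets))
    targets <- c(.targetVocab(config), sprintf("ExtGene%02d", 1:8))
  sz <- config$db_sizes

  .withSubstream(config$seed, .STREAMS[["interactions"]], {
    drawPairs <- function(k) {
      if (k == 0L) return(data.frame(mir_id = character(0),
                                     target_id = character(0),
                                     stringsAsFactors = FALSE))
      data.frame(mir_id = sample(mirs, k, replace = TRUE),
                 target_id = sample(targets, k, replace = TRUE),
                 stringsAsFactors = FALSE)
    }
    val <- drawPairs(sz[["validated"]])
    val$source <- rep("validated", nrow(val))
    val$score <- rep(NA_real_, nrow(val))

    pred <- drawPairs(sz[["predicted_score"]])
    pred$source <- rep("predicted_score", nrow(pred))
    pred$score <- stats::runif(nrow(pred), 0, 100)

    svr <- drawPairs(sz[["predicted_mirsvr"]])
    svr$source <- rep("predicted_mirsvr", nrow(svr))
    svr$score <- -stats::runif(nrow(svr), 0, 2.5)

    truth <- data.frame(
      source = c(val$source, pred$source, svr$source),
      mir_id = c(val$mir_id, pred$mir_id, svr$mir_id),
      target_id = c(val$target_id, pred$target_id, svr$target_id),
      passes = c(rep(TRUE, nrow(val)), pred$score > 80.0,
                 svr$score < -1.2),
      stringsAsFactors = FALSE)
    list(tables = list(validated = val, predicted_score = pred,
                       predicted_mirsvr = svr),
         truth = truth)
  })
}

#' Simulate a mitochondrial annotation table with identifier aliasing
#'
#' Builds an IMPI-style annotation for the target-gene vocabulary: Ensembl,
#' RGD and NCBI identifiers, symbol and description per gene, an IMPI score
#' in \code{[0, 1]}, a GO-mitochondrial flag and an IMPI class
#' (\code{known} / \code{predicted} / \code{other}). A fraction
#' \code{alias_rate} of rows has identifier columns blanked or the symbol
#' case-mutated (deterministically, by row index) to force the downstream
#' reconciliation cascade through its lower-priority levels.
#'
#' Planted mitochondrial genes either carry a high IMPI score, or a GO flag
#' with moderate score, so the standard filter (GO flag or score above 0.7)
#' recovers exactly the planted set when aliasing is off.
#'
#' @param config a [simConfig()] object.
#' @param targets gene vocabulary to annotate (default: the simulated one).
#' @param score_mode \code{"realistic"} (uniform score ranges) or
#'   \code{"two_point"} (scores exactly 0.9 / 0.1, useful for exact
#'   truth-recovery checks).
#' @return list: \code{annotation} (the table) and \code{truth}
#'   (per-gene planted \code{is_mito} and clean identifiers).
#' @export
simulateMitoAnnotation <- function(config, targets = NULL,
                                   score_mode = c("realistic", "two_point")) {
  stopifnot(inherits(config, "simConfig"))
  score_mode <- match.arg(score_mode)
  if (is.null(targets)) targets <- .targetVocab(config)
  n <- length(targets)

  .withSubstream(config$seed, .STREAMS[["annotation"]], {
    n_mito <- as.integer(round(config$mito_fraction * n))
    mito <- logical(n)
    if (n_mito > 0) mito[sample.int(n, n_mito)] <- TRUE

    if (score_mode == "two_point") {
      impi <- ifelse(mito, 0.9, 0.1)
      go <- rep(FALSE, n)
    } else {
      # mito genes: 60% high-IMPI only, 20% both, 20% GO-only (low score)
      kind <- ifelse(!mito, "none",
                     sample(c("impi", "both", "go"), n, replace = TRUE,
                            prob = c(0.6, 0.2, 0.2)))
      impi <- ifelse(kind %in% c("impi", "both"),
                     stats::runif(n, 0.75, 1),
                     ifelse(kind == "go", stats::runif(n, 0.1, 0.6),
                            stats::runif(n, 0, 0.6)))
      go <- kind %in% c("both", "go")
    }
    cls <- ifelse(mito, ifelse(impi > 0.9 | go, "known", "predicted"),
                  "other")
    # some non-mito rows keep class 'predicted' so the class restriction
    # and the score/GO filter are genuinely different sieves
    if (score_mode == "realistic") {
      idx <- which(!mito)
      keep_pred <- idx[seq_along(idx) %% 4 == 0]
      cls[keep_pred] <- "predicted"
    }

    ann <- data.frame(
      ensembl_id = sprintf("ENSRNOG%011d", seq_len(n)),
      rgd_id = sprintf("RGD:%d", 61000 + seq_len(n)),
      ncbi_id = as.character(100000 + seq_len(n)),
      symbol = targets,
      description = sprintf("%s, cellular protein %04d", targets,
                            seq_len(n)),
      impi_score = impi, go_mito = go, impi_class = cls,
      stringsAsFactors = FALSE)

    # deterministic aliasing: row-index cycle of three mutations
    n_alias <- as.integer(round(config$alias_rate * n))
    if (n_alias > 0) {
      rows <- sample.int(n, n_alias)
      for (k in seq_along(rows)) {
        i <- rows[k]
        switch((k %% 3) + 1L,
          { ann$ensembl_id[i] <- "" },                       # drop ensembl
          { ann$ensembl_id[i] <- ""; ann$rgd_id[i] <- "" },  # drop ens+rgd
          { ann$ensembl_id[i] <- ""; ann$rgd_id[i] <- ""
            ann$ncbi_id[i] <- ""
            ann$symbol[i] <- toupper(ann$symbol[i]) })       # symbol case
      }
    }
    truth <- data.frame(target_id = targets, is_mito = mito,
                        impi_score = impi, go_mito = go,
                        stringsAsFactors = FALSE)
    list(annotation = ann, truth = truth)
  })
}

#' Write a full synthetic data set to disk in the standard plain-text forms
#'
#' Counts as features-x-samples TSV, sample annotation as CSV, the three
#' interaction tables as TSV (columns \code{mir_id, target_id, source,
#' score}), the mitochondrial annotation as TSV, and every truth table as
#' JSON.
#'
#' @param config a [simConfig()] object.
#' @param dir output directory (created if missing).
#' @return invisibly, the named list of file paths written.
#' @export
exportSimulation <- function(config, dir) {
  stopifnot(inherits(config, "simConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tro <- simulateTroponin(config)
  se <- simulateMirCounts(config)
  dbs <- simulateInteractionDbs(config)
  ann <- simulateMitoAnnotation(config)

  paths <- list(
    counts = file.path(dir, "mir_counts.tsv"),
    samples = file.path(dir, "samples.csv"),
    validated = file.path(dir, "interactions_validated.tsv"),
    predicted_score = file.path(dir, "interactions_predicted_score.tsv"),
    predicted_mirsvr = file.path(dir, "interactions_predicted_mirsvr.tsv"),
    annotation = file.path(dir, "mito_annotation.tsv"),
    truth = file.path(dir, "truth.json"))

  cnt <- as.data.frame(SummarizedExperiment::assay(se, "counts"))
  cnt <- cbind(mir_id = rownames(cnt), cnt)
  utils::write.table(cnt, paths$counts, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(tro$animals, paths$samples, row.names = FALSE)
  for (d in c("validated", "predicted_score", "predicted_mirsvr"))
    utils::write.table(dbs$tables[[d]], paths[[d]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(ann$annotation, paths$annotation, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(
    animals = tro$truth,
    mirs = as.data.frame(SummarizedExperiment::rowData(se)),
    size_factors = as.list(stats::setNames(
      se$true_size_factor, colnames(se))),
    interactions = dbs$truth,
    mito = ann$truth)
  jsonlite::write_json(truth, paths$truth, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
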