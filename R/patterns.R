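.CONTRASTS <- c("IR_vs_Sham", "IPC_vs_IR", "IPoCR_vs_IR", "IPoCNR_vs_IR")

#' Discretize contrast results into regulation calls
#'
#' A feature is called \code{up} when \code{p <= alpha} and its log2 fold
#' change exceeds \code{lfc_min}, \code{down} when \code{p <= alpha} and
#' the log2 fold change is below \code{-lfc_min}, and \code{unchanged}
#' otherwise. Boundary p-values equal to \code{alpha} are called
#' (\code{<=} semantics); a significant feature with log2 fold change
#' exactly zero is called \code{unchanged} (directionless significance
#' carries no information for a direction-based rule).
#'
#' @param results data.frame with columns \code{feature_id},
#'   \code{contrast}, \code{log2fc}, \code{p} (typically stacked
#'   [nbWaldContrast()] outputs with a contrast column added).
#' @param alpha significance level.
#' @param lfc_min minimum |log2 fold change| magnitude (default 0).
#' @return data.frame: \code{feature_id}, \code{contrast},
#'   \code{direction} (\code{up}/\code{down}/\code{unchanged}), \code{p},
#'   \code{log2fc}.
#' @export
callRegulation <- function(results, alpha = 0.05, lfc_min = 0) {
  stopifnot(is.data.frame(results),
            all(c("feature_id", "contrast", "log2fc", "p") %in%
                  names(results)))
  .assertScalarProb(alpha, "alpha")
  sig <- results$p <= alpha
  dir <- ifelse(sig & results$log2fc > lfc_min, "up",
                ifelse(sig & results$log2fc < -lfc_min, "down",
                       "unchanged"))
  data.frame(feature_id = results$feature_id, contrast = results$contrast,
             direction = dir, p = results$p, log2fc = results$log2fc,
             stringsAsFactors = FALSE)
}

.opposite <- function(a, b)
  (a == "up" & b == "down") | (a == "down" & b == "up")

#' Select miRs with a protective conditioning-reversed expression pattern
#'
#' A miR is selected when (i) it is regulated by I/R (non-unchanged in the
#' I/R vs Sham contrast); (ii) the responder arm reverses that change
#' (IPoC-R vs I/R in the opposite direction); (iii) pre-conditioning also
#' reverses it (IPC vs I/R opposite) — required by default, optional via
#' \code{require_ipc = FALSE}; and (iv) non-responders show no protective
#' change (IPoC-NR vs I/R is not opposite to the I/R change; unchanged or a
#' further change in the same direction both qualify as non-protective).
#'
#' @param calls regulation calls (from [callRegulation()]) covering all
#'   four contrasts \code{IR_vs_Sham}, \code{IPC_vs_IR}, \code{IPoCR_vs_IR},
#'   \code{IPoCNR_vs_IR} for every feature.
#' @param require_ipc logical; whether clause (iii) is enforced.
#' @return data.frame, one row per feature: \code{feature_id},
#'   \code{ir_direction}, \code{selected}, \code{rationale} (which clauses
#'   held).
#' @export
protectiveMirFilter <- function(calls, require_ipc = TRUE) {
  stopifnot(is.data.frame(calls),
            all(c("feature_id", "contrast", "direction") %in% names(calls)))
  missing_ct <- setdiff(.CONTRASTS, unique(calls$contrast))
  if (length(missing_ct))
    stop("missing contrast(s): ", paste(missing_ct, collapse = ", "),
         call. = FALSE)
  key <- paste(calls$feature_id, calls$contrast, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- calls[key %in% key[duplicated(key)], ]
    agree <- all(tapply(dup$direction, paste(dup$feature_id, dup$contrast),
                        function(d) length(unique(d)) == 1L))
    if (!agree)
      stop("contradictory duplicate calls for the same feature/contrast",
           call. = FALSE)
    calls <- calls[!duplicated(key), ]
  }
  wide <- lapply(.CONTRASTS, function(ct) {
    sub <- calls[calls$contrast == ct, ]
    stats::setNames(sub$direction, sub$feature_id)
  })
  names(wide) <- .CONTRASTS
  feats <- sort(unique(calls$feature_id))
  for (ct in .CONTRASTS)
    if (!all(feats %in% names(wide[[ct]])))
      stop("contrast ", ct, " does not cover every feature", call. = FALSE)

  ir <- wide$IR_vs_Sham[feats]
  ipc <- wide$IPC_vs_IR[feats]
  r <- wide$IPoCR_vs_IR[feats]
  nr <- wide$IPoCNR_vs_IR[feats]

  c1 <- ir != "unchanged"
  c2 <- .opposite(ir, r)
  c3 <- if (require_ipc) .opposite(ir, ipc) else rep(TRUE, length(feats))
  c4 <- !.opposite(ir, nr)
  sel <- c1 & c2 & c3 & c4
  rationale <- paste0(
    "ir_regulated=", c1, ";r_reverses=", c2,
    ";ipc_reverses=", .opposite(ir, ipc),
    if (require_ipc) "(required)" else "(not required)",
    ";nr_non_protective=", c4)
  data.frame(feature_id = feats, ir_direction = unname(ir),
             selected = unname(sel), rationale = rationale,
             row.names = NULL, stringsAsFactors = FALSE)
}

.PATTERN_LEVELS <- c("ALL3", "R_AND_NR", "R_AND_IPC", "R_ONLY", "NR_ONLY",
                     "IPC_ONLY", "NONE", "OTHER")

#' Classify features into conditioning-regulation pattern categories
#'
#' Partitions features by which conditioning arms significantly regulate
#' them relative to I/R: regulated by all three (\code{ALL3}), by the
#' responder and non-responder arms but not pre-conditioning
#' (\code{R_AND_NR}), by the responder arm and pre-conditioning but not
#' non-responders (\code{R_AND_IPC}), by exactly one arm (\code{R_ONLY},
#' \code{NR_ONLY}, \code{IPC_ONLY}), by none (\code{NONE}), or the
#' remaining combination NR and IPC without R (\code{OTHER}). The
#' categories are mutually exclusive and exhaustive.
#'
#' @param sig_flags data.frame with columns \code{feature_id},
#'   \code{sig_ipc}, \code{sig_ipocr}, \code{sig_ipocnr} (logical:
#'   significant vs I/R).
#' @return data.frame: \code{feature_id}, \code{category} (factor over the
#'   eight pattern levels).
#' @export
classifyMrnaPattern <- function(sig_flags) {
  need <- c("feature_id", "sig_ipc", "sig_ipocr", "sig_ipocnr")
  stopifnot(is.data.frame(sig_flags), all(need %in% names(sig_flags)))
  for (cl in need[-1])
    if (anyNA(sig_flags[[cl]]))
      stop("missing significance flags in ", cl, call. = FALSE)
  ipc <- sig_flags$sig_ipc; r <- sig_flags$sig_ipocr
  nr <- sig_flags$sig_ipocnr
  cat_ <- ifelse(r & nr & ipc, "ALL3",
          ifelse(r & nr & !ipc, "R_AND_NR",
          ifelse(r & !nr & ipc, "R_AND_IPC",
          ifelse(r & !nr & !ipc, "R_ONLY",
          ifelse(!r & nr & !ipc, "NR_ONLY",
          ifelse(!r & !nr & ipc, "IPC_ONLY",
          ifelse(!r & !nr & !ipc, "NONE", "OTHER")))))))
  data.frame(feature_id = sig_flags$feature_id,
             category = factor(cat_, levels = .PATTERN_LEVELS),
             stringsAsFactors = FALSE)
}
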