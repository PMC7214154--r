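#' Split a post-conditioned arm into responders and non-responders
#'
#' Stratifies the IPoC arm from plasma troponin I. The \code{mixture} method
#' fits a two-component Gaussian mixture on log TnI by EM (free component
#' variances, deterministic initialization at the 25th/75th percentiles) and
#' assigns each animal to the lower-mean component ("responder") when its
#' posterior is at least 0.5. A degenerate fit — component means closer than
#' \code{min_separation} pooled component SDs, non-convergence, or a
#' vanishing component — triggers the \code{threshold} fallback and sets the
#' degeneracy flag. The \code{threshold} method labels an animal responder
#' iff its log TnI lies below the midpoint of the median log TnI of the IPC
#' and I/R reference arms (the geometric midpoint on the original scale).
#'
#' Labels are invariant under rescaling of all concentrations by a positive
#' constant (the split operates on log-scale differences only).
#'
#' @param ipoc_tni positive TnI concentrations (ng/mL) of the IPoC animals;
#'   names, if present, become animal ids.
#' @param reference_ir,reference_ipc TnI vectors of the I/R and IPC arms
#'   (required for the threshold method and the mixture fallback).
#' @param method \code{"mixture"} (default) or \code{"threshold"}.
#' @param min_separation degeneracy guard: minimum |difference of component
#'   means| in units of pooled component SD.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return a [TniStratification-class] object.
#' @examples
#' set.seed(1)
#' tni <- c(rlnorm(8, log(5), 0.3), rlnorm(12, log(50), 0.3))
#' splitResponders(tni, reference_ir = rlnorm(20, log(50), 0.3),
#'                 reference_ipc = rlnorm(20, log(5), 0.3))
#' @export
splitResponders <- function(ipoc_tni, reference_ir = NULL,
                            reference_ipc = NULL,
                            method = c("mixture", "threshold"),
                            min_separation = 0.5, max_iter = 500L,
                            tol = 1e-10) {
  method <- match.arg(method)
  if (length(ipoc_tni) == 0L) stop("empty IPoC TnI vector", call. = FALSE)
  if (any(!is.finite(ipoc_tni)) || any(ipoc_tni <= 0))
    stop("TnI concentrations must be positive and finite", call. = FALSE)
  ids <- if (!is.null(names(ipoc_tni))) names(ipoc_tni)
    else sprintf("IPoC%02d", seq_along(ipoc_tni))
  x <- log(as.numeric(ipoc_tni))

  thresholdSplit <- function(degenerate) {
    if (is.null(reference_ir) || length(reference_ir) == 0L ||
        is.null(reference_ipc) || length(reference_ipc) == 0L)
      stop("threshold method requires non-empty I/R and IPC references",
           call. = FALSE)
    if (any(reference_ir <= 0) || any(reference_ipc <= 0))
      stop("TnI concentrations must be positive and finite", call. = FALSE)
    cut_log <- (stats::median(log(reference_ipc)) +
                stats::median(log(reference_ir))) / 2
    lab <- ifelse(x < cut_log, "responder", "non_responder")
    methods::new("TniStratification",
        labels = stats::setNames(lab, ids), method = "threshold",
        threshold = exp(cut_log),
        posterior = stats::setNames(rep(NA_real_, length(x)), ids),
        mixture = list(), degenerate = degenerate)
  }

  if (method == "threshold") return(thresholdSplit(FALSE))
  if (length(x) < 4L)
    stop("mixture method needs at least 4 IPoC values", call. = FALSE)

  # two-component EM on log TnI, deterministic quartile initialization
  mu <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  sd0 <- max(stats::sd(x), 1e-6)
  sigma <- c(sd0, sd0)
  pi1 <- 0.5
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- pi1 * stats::dnorm(x, mu[1], sigma[1])
    d2 <- (1 - pi1) * stats::dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    if (any(tot == 0) || any(!is.finite(tot))) break
    g <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    n1 <- sum(g); n2 <- length(x) - n1
    if (n1 < 1e-8 || n2 < 1e-8) break
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    sigma <- sqrt(c(sum(g * (x - mu[1])^2) / n1,
                    sum((1 - g) * (x - mu[2])^2) / n2))
    sigma <- pmax(sigma, 1e-6)
    pi1 <- n1 / length(x)
  }

  pooled_sd <- sqrt((sigma[1]^2 + sigma[2]^2) / 2)
  if (!converged || abs(mu[1] - mu[2]) < min_separation * pooled_sd ||
      pi1 < 1e-6 || pi1 > 1 - 1e-6)
    return(thresholdSplit(TRUE))

  low <- which.min(mu)
  post_resp <- if (low == 1L) d1 / tot else d2 / tot
  # posterior tie at exactly 0.5 assigned responder (>= semantics)
  lab <- ifelse(post_resp >= 0.5, "responder", "non_responder")
  methods::new("TniStratification",
      labels = stats::setNames(lab, ids), method = "mixture",
      threshold = NA_real_,
      posterior = stats::setNames(post_resp, ids),
      mixture = list(meanlog = mu, sdlog = sigma,
                     weights = c(pi1, 1 - pi1)),
      degenerate = FALSE)
}

#' Per-group mean and SD summary of animal records
#'
#' Summarizes every numeric field of an animal table as mean and sample SD
#' (denominator n-1) per reported group. When a stratification result is
#' supplied, the IPoC arm is split into its responder / non-responder
#' groups, giving the usual five-group layout. Groups of size one report an
#' undefined (NA) SD; fields entirely missing in a group are omitted rather
#' than imputed.
#'
#' @param records data.frame with columns \code{animal_id}, \code{arm} and
#'   numeric measurement columns (e.g. \code{tni}, \code{hw_bw}, echo
#'   fields).
#' @param stratification optional [TniStratification-class] labelling the
#'   IPoC animals.
#' @return long data.frame: \code{group}, \code{variable}, \code{n},
#'   \code{mean}, \code{sd}.
#' @export
summarizeGroups <- function(records, stratification = NULL) {
  stopifnot(is.data.frame(records),
            all(c("animal_id", "arm") %in% names(records)))
  grp <- records$arm
  if (!is.null(stratification)) {
    lab <- responderLabels(stratification)
    idx <- match(records$animal_id, names(lab))
    hit <- !is.na(idx)
    grp[hit] <- ifelse(lab[idx[hit]] == "responder", "IPoC_R", "IPoC_NR")
  }
  num_cols <- names(records)[vapply(records, is.numeric, logical(1))]
  out <- list()
  for (g in unique(grp)) {
    sub <- records[grp == g, , drop = FALSE]
    for (v in num_cols) {
      vals <- sub[[v]][!is.na(sub[[v]])]
      if (length(vals) == 0L) next  # omit, never impute
      out[[length(out) + 1L]] <- data.frame(
        group = g, variable = v, n = length(vals), mean = mean(vals),
        sd = if (length(vals) >= 2L) stats::sd(vals) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Percent change of a treated mean relative to a baseline mean
#'
#' \code{100 * (treated - baseline) / baseline}, reported at one decimal
#' place — the convention used for relative functional changes such as
#' load-free cell shortening.
#'
#' @param baseline_mean positive baseline mean.
#' @param treated_mean treated mean.
#' @return numeric percent change, rounded to one decimal.
#' @examples
#' relativeChange(10.30, 11.16)  # 8.3
#' @export
relativeChange <- function(baseline_mean, treated_mean) {
  if (!is.numeric(baseline_mean) || baseline_mean <= 0)
    stop("baseline mean must be positive", call. = FALSE)
  round(100 * (treated_mean - baseline_mean) / baseline_mean, 1)
}
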