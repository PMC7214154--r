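#' @import methods
NULL

#' Signed bipartite miR-target network
#'
#' Container for a signed bipartite interaction network between regulated
#' miRs and their (predicted or validated) target genes. Each edge carries a
#' weight of +1 or -1 encoding the expected direction of the target's
#' expression change under miR-mediated repression (see
#' [buildNetwork()] for the two weight conventions). miR nodes carry the
#' direction of their own regulation (\code{"up"} or \code{"down"}).
#'
#' @slot edges data.frame with columns \code{mir_id}, \code{target_id},
#'   \code{weight} (+1/-1) and \code{sources} (comma-joined provenance).
#' @slot mirDirections named character vector mapping every miR node to
#'   \code{"up"} or \code{"down"}.
#'
#' @seealso [buildNetwork()], [nodeStrength()], [extractSubnetwork()]
#' @export
setClass("SignedBipartiteNet",
  representation(edges = "data.frame", mirDirections = "character"))

setValidity("SignedBipartiteNet", function(object) {
  ed <- object@edges
  msgs <- character()
  need <- c("mir_id", "target_id", "weight", "sources")
  if (!all(need %in% names(ed)))
    msgs <- c(msgs, paste("edges must have columns:",
                          paste(need, collapse = ", ")))
  else {
    if (nrow(ed) > 0 && !all(ed$weight %in% c(-1, 1)))
      msgs <- c(msgs, "edge weights must be +1 or -1")
    if (anyDuplicated(paste(ed$mir_id, ed$target_id, sep = "\r")))
      msgs <- c(msgs, "duplicate (mir, target) edges are not allowed")
    if (nrow(ed) > 0 && !all(ed$mir_id %in% names(object@mirDirections)))
      msgs <- c(msgs, "every edge miR must have a recorded direction")
  }
  dirs <- object@mirDirections
  if (length(dirs) && !all(dirs %in% c("up", "down")))
    msgs <- c(msgs, "miR directions must be 'up' or 'down'")
  if (length(dirs) && is.null(names(dirs)))
    msgs <- c(msgs, "miR directions must be named by miR id")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SignedBipartiteNet compact display
#' @param object a \code{SignedBipartiteNet}
#' @export
setMethod("show", "SignedBipartiteNet", function(object) {
  cat("SignedBipartiteNet with", length(mirNodes(object)), "miR node(s),",
      length(targetNodes(object)), "target node(s),",
      nrow(object@edges), "edge(s)\n")
  if (nrow(object@edges) > 0) {
    s <- nodeStrength(object)
    cat("  top target by |strength|:", s$target_id[1],
        sprintf("(strength %+d)\n", s$strength[1]))
  }
  invisible(NULL)
})

#' @rdname SignedBipartiteNet
#' @param x a \code{SignedBipartiteNet}
#' @export
setGeneric("mirNodes", function(x) standardGeneric("mirNodes"))

#' @rdname SignedBipartiteNet
#' @export
setMethod("mirNodes", "SignedBipartiteNet",
          function(x) sort(names(x@mirDirections)))

#' @rdname SignedBipartiteNet
#' @export
setGeneric("targetNodes", function(x) standardGeneric("targetNodes"))

#' @rdname SignedBipartiteNet
#' @export
setMethod("targetNodes", "SignedBipartiteNet",
          function(x) sort(unique(x@edges$target_id)))

#' @rdname SignedBipartiteNet
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname SignedBipartiteNet
#' @export
setMethod("edgeTable", "SignedBipartiteNet", function(x) x@edges)

#' @rdname SignedBipartiteNet
#' @export
setGeneric("mirDirections", function(x) standardGeneric("mirDirections"))

#' @rdname SignedBipartiteNet
#' @export
setMethod("mirDirections", "SignedBipartiteNet",
          function(x) x@mirDirections)

#' Troponin-based responder stratification result
#'
#' Result of splitting a post-conditioned arm into responders and
#' non-responders from plasma troponin I. Produced by [splitResponders()].
#'
#' @slot labels named character vector, one of \code{"responder"} /
#'   \code{"non_responder"} per animal.
#' @slot method \code{"mixture"} or \code{"threshold"} (the method that
#'   produced the labels; a degenerate mixture records the fallback).
#' @slot threshold numeric, the TnI concentration (ng/mL) separating the
#'   classes under the threshold method (NA for a pure mixture assignment).
#' @slot posterior named numeric vector of responder-component posterior
#'   probabilities (NA under the threshold method).
#' @slot mixture list of fitted mixture parameters (means, sds, weights on
#'   the log scale), empty for the threshold method.
#' @slot degenerate logical; TRUE when the mixture collapsed (components
#'   closer than the separation guard, or non-convergence) and the
#'   threshold fallback was applied.
#' @export
setClass("TniStratification",
  representation(labels = "character", method = "character",
                 threshold = "numeric", posterior = "numeric",
                 mixture = "list", degenerate = "logical"))

setValidity("TniStratification", function(object) {
  msgs <- character()
  if (!all(object@labels %in% c("responder", "non_responder")))
    msgs <- c(msgs, "labels must be 'responder' or 'non_responder'")
  if (length(object@labels) && is.null(names(object@labels)))
    msgs <- c(msgs, "labels must be named by animal id")
  if (!object@method %in% c("mixture", "threshold"))
    msgs <- c(msgs, "method must be 'mixture' or 'threshold'")
  if (!is.na(object@threshold) && object@threshold <= 0)
    msgs <- c(msgs, "threshold must be strictly positive")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn TniStratification compact display
#' @param object a \code{TniStratification}
#' @export
setMethod("show", "TniStratification", function(object) {
  tab <- table(factor(object@labels,
                      levels = c("responder", "non_responder")))
  cat("TniStratification:", tab[["responder"]], "responder(s),",
      tab[["non_responder"]], "non-responder(s)\n")
  cat("  method:", object@method,
      if (object@degenerate) "(degenerate mixture, fallback applied)" else "",
      "\n")
  if (!is.na(object@threshold))
    cat(sprintf("  threshold: %.3g ng/mL\n", object@threshold))
  invisible(NULL)
})

#' @rdname TniStratification
#' @param x a \code{TniStratification}
#' @export
setGeneric("responderLabels", function(x) standardGeneric("responderLabels"))

#' @rdname TniStratification
#' @export
setMethod("responderLabels", "TniStratification", function(x) x@labels)

#' @rdname TniStratification
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))

#' @rdname TniStratification
#' @export
setMethod("isDegenerate", "TniStratification", function(x) x@degenerate)
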