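#' Filter and merge miR-target interaction records
#'
#' Applies the standard per-dialect thresholds and collapses duplicates:
#' validated records are kept unconditionally; prediction-score records are
#' kept iff \code{score > score_min} (strictly); mirSVR-style records are
#' kept iff \code{score < mirsvr_max} (strictly; more negative = stronger
#' predicted repression). Records sharing the same (miR, target) pair are
#' collapsed to a single edge whose provenance is the union of the
#' contributing sources.
#'
#' @param records data.frame with columns \code{mir_id}, \code{target_id},
#'   \code{source} (\code{validated}, \code{predicted_score} or
#'   \code{predicted_mirsvr}) and \code{score} (NA for validated records).
#' @param score_min strict lower bound for prediction scores (default 80).
#' @param mirsvr_max strict upper bound for mirSVR scores (default -1.2).
#' @return data.frame of kept unique interactions: \code{mir_id},
#'   \code{target_id}, \code{sources} (comma-joined, sorted).
#' @export
filterInteractions <- function(records, score_min = 80.0,
                               mirsvr_max = -1.2) {
  need <- c("mir_id", "target_id", "source")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  if (!"score" %in% names(records)) records$score <- NA_real_
  if (nrow(records) == 0L)
    return(data.frame(mir_id = character(0), target_id = character(0),
                      sources = character(0), stringsAsFactors = FALSE))
  ok_src <- c("validated", "predicted_score", "predicted_mirsvr")
  if (!all(records$source %in% ok_src))
    stop("unknown interaction source(s): ",
         paste(setdiff(unique(records$source), ok_src), collapse = ", "),
         call. = FALSE)
  bad <- (records$source == "validated" & !is.na(records$score)) |
    (records$source == "predicted_score" & is.na(records$score)) |
    (records$source == "predicted_mirsvr" &
       (is.na(records$score) | records$score > 0))
  if (any(bad))
    stop("malformed source/score combination in ", sum(bad), " record(s)",
         call. = FALSE)

  keep <- records$source == "validated" |
    (records$source == "predicted_score" & records$score > score_min) |
    (records$source == "predicted_mirsvr" & records$score < mirsvr_max)
  kept <- records[keep, , drop = FALSE]
  if (nrow(kept) == 0L)
    return(data.frame(mir_id = character(0), target_id = character(0),
                      sources = character(0), stringsAsFactors = FALSE))
  key <- paste(kept$mir_id, kept$target_id, sep = "\r")
  agg <- tapply(kept$source, key,
                function(s) paste(sort(unique(s)), collapse = ","))
  first <- kept[!duplicated(key), c("mir_id", "target_id")]
  first$sources <- unname(agg[paste(first$mir_id, first$target_id,
                                    sep = "\r")])
  ord <- order(first$mir_id, first$target_id)
  out <- first[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the signed bipartite miR-target network
#'
#' Restricts the filtered interactions to the selected miRs and assigns
#' each edge a weight of +1 or -1. Under the default \code{"repression"}
#' convention the weight encodes the expected change of the target under
#' miR-mediated repression: an up-regulated miR predicts target
#' down-regulation (weight -1), a down-regulated miR predicts target
#' up-regulation (weight +1). The \code{"literal"} convention inverts the
#' mapping (weights follow the miR direction); the two conventions yield
#' sign-flipped strengths, so rankings by |strength| are identical.
#' Targets without any edge do not appear in the network.
#'
#' @param selected_mirs data.frame with columns \code{mir_id} and
#'   \code{direction} (\code{"up"}/\code{"down"}: the miR's own regulation
#'   direction after injury).
#' @param interactions filtered interaction table (from
#'   [filterInteractions()]).
#' @param convention \code{"repression"} (default) or \code{"literal"}.
#' @return a [SignedBipartiteNet-class].
#' @export
buildNetwork <- function(selected_mirs, interactions,
                         convention = c("repression", "literal")) {
  convention <- match.arg(convention)
  stopifnot(is.data.frame(selected_mirs),
            all(c("mir_id", "direction") %in% names(selected_mirs)))
  if (anyNA(selected_mirs$direction) ||
      !all(selected_mirs$direction %in% c("up", "down")))
    stop("every selected miR needs a direction ('up' or 'down')",
         call. = FALSE)
  if (anyDuplicated(selected_mirs$mir_id))
    stop("duplicate selected miRs", call. = FALSE)
  dirs <- stats::setNames(selected_mirs$direction, selected_mirs$mir_id)

  ed <- interactions[interactions$mir_id %in% names(dirs), , drop = FALSE]
  if (!"sources" %in% names(ed)) ed$sources <- "unspecified"
  w_up <- if (convention == "repression") -1 else 1
  edges <- data.frame(
    mir_id = ed$mir_id, target_id = ed$target_id,
    weight = ifelse(dirs[ed$mir_id] == "up", w_up, -w_up),
    sources = ed$sources, row.names = NULL, stringsAsFactors = FALSE)
  # miR nodes with no surviving edge are dropped from the node set
  dirs <- dirs[names(dirs) %in% edges$mir_id]
  methods::new("SignedBipartiteNet", edges = edges, mirDirections = dirs)
}

#' Per-target node strength and ranking
#'
#' The node strength of a target is the sum of the +1/-1 weights of its
#' incident edges; its sign predicts the direction of the target's
#' expression change under the network's weight convention, its magnitude
#' how unanimously the connected miRs push that way. Targets are ranked by
#' |strength| descending, ties by strength descending, then
#' lexicographically by target id.
#'
#' @param x a [SignedBipartiteNet-class].
#' @return data.frame: \code{target_id}, \code{strength}, \code{degree},
#'   \code{rank}.
#' @export
setGeneric("nodeStrength", function(x) standardGeneric("nodeStrength"))

#' @rdname nodeStrength
#' @export
setMethod("nodeStrength", "SignedBipartiteNet", function(x) {
  ed <- x@edges
  if (nrow(ed) == 0L)
    return(data.frame(target_id = character(0), strength = integer(0),
                      degree = integer(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  strength <- tapply(ed$weight, ed$target_id, sum)
  degree <- tapply(ed$weight, ed$target_id, length)
  out <- data.frame(target_id = names(strength),
                    strength = as.integer(strength),
                    degree = as.integer(degree),
                    stringsAsFactors = FALSE)
  ord <- order(-abs(out$strength), -out$strength, out$target_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
})

#' Export a signed bipartite network to file
#'
#' Three formats: a round-trip-safe edge-list TSV (read back with
#' [readNetworkEdgeList()]), SIF with the relation name encoding the edge
#' sign (\code{predicts_down} / \code{predicts_up}), and GraphML with node
#' type/direction and edge weight/provenance attributes.
#'
#' @param network a [SignedBipartiteNet-class].
#' @param path output file path.
#' @param format \code{"edgelist"}, \code{"sif"} or \code{"graphml"}.
#' @return invisibly, \code{path}.
#' @export
exportNetwork <- function(network, path,
                          format = c("edgelist", "sif", "graphml")) {
  format <- match.arg(format)
  ed <- network@edges
  dirs <- network@mirDirections
  if (format == "edgelist") {
    df <- data.frame(
      mir_id = ed$mir_id, target_id = ed$target_id, weight = ed$weight,
      mir_direction = if (nrow(ed)) unname(dirs[ed$mir_id]) else character(0),
      sources = ed$sources, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "sif") {
    rel <- ifelse(ed$weight < 0, "predicts_down", "predicts_up")
    lines <- if (nrow(ed)) paste(ed$mir_id, rel, ed$target_id, sep = "\t")
      else character(0)
    writeLines(lines, path)
  } else {
    g <- .asIgraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

.asIgraph <- function(network) {
  ed <- network@edges
  dirs <- network@mirDirections
  mirs <- sort(names(dirs))
  tgts <- sort(unique(ed$target_id))
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(mirs), name = mirs, kind = "mir",
                            direction = unname(dirs[mirs]))
  if (length(tgts))
    g <- igraph::add_vertices(g, length(tgts), name = tgts, kind = "target",
                              direction = NA_character_)
  if (nrow(ed))
    g <- igraph::add_edges(g, rbind(match(ed$mir_id, c(mirs, tgts)),
                                    match(ed$target_id, c(mirs, tgts))),
                           weight = ed$weight, sources = ed$sources)
  g
}

#' Read a network edge-list TSV back into a SignedBipartiteNet
#'
#' Inverse of [exportNetwork()] with \code{format = "edgelist"}.
#'
#' @param path file written by the edge-list exporter.
#' @return a [SignedBipartiteNet-class].
#' @export
readNetworkEdgeList <- function(path) {
  df <- .readTable(path)
  dirs <- df$mir_direction[!duplicated(df$mir_id)]
  names(dirs) <- df$mir_id[!duplicated(df$mir_id)]
  methods::new("SignedBipartiteNet",
      edges = data.frame(mir_id = as.character(df$mir_id),
                         target_id = as.character(df$target_id),
                         weight = df$weight,
                         sources = as.character(df$sources),
                         stringsAsFactors = FALSE),
      mirDirections = if (length(dirs)) dirs else
        stats::setNames(character(0), character(0)))
}
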