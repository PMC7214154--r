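#' Load and restrict a mitochondrial annotation table
#'
#' Reads (or accepts) an IMPI-style annotation with one row per gene:
#' identifier columns (\code{ensembl_id}, \code{rgd_id}, \code{ncbi_id},
#' \code{symbol}, \code{description}), a numeric \code{impi_score} in
#' \code{[0, 1]}, a logical \code{go_mito} flag and an \code{impi_class}
#' (\code{known} / \code{predicted} / \code{other}). Rows whose class lies
#' outside \code{restrict_classes} are dropped.
#'
#' @param table data.frame or path to a TSV with the columns above.
#' @param restrict_classes classes to keep (default: known + predicted).
#' @return the restricted annotation data.frame.
#' @export
loadAnnotation <- function(table, restrict_classes = c("known",
                                                       "predicted")) {
  if (is.character(table) && length(table) == 1L) {
    if (!file.exists(table))
      stop("annotation file not found: ", table, call. = FALSE)
    table <- .readTable(table)
  }
  need <- c("ensembl_id", "rgd_id", "ncbi_id", "symbol", "description",
            "impi_score", "go_mito", "impi_class")
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("annotation lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  score <- suppressWarnings(as.numeric(table$impi_score))
  if (anyNA(score) || any(score < 0) || any(score > 1))
    stop("malformed IMPI scores: must be numeric in [0, 1]", call. = FALSE)
  table$impi_score <- score
  table$go_mito <- as.logical(table$go_mito)
  ids_empty <- (is.na(table$ensembl_id) | table$ensembl_id == "") &
    (is.na(table$rgd_id) | table$rgd_id == "") &
    (is.na(table$ncbi_id) | table$ncbi_id == "") &
    (is.na(table$symbol) | table$symbol == "")
  if (any(ids_empty))
    stop("annotation row(s) without any identifier", call. = FALSE)
  out <- table[table$impi_class %in% restrict_classes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reconcile target identifiers against the annotation by cascade
#'
#' For each query identifier the cascade tries, in fixed priority order:
#' exact Ensembl id, exact RGD id, exact NCBI id, case-insensitive symbol,
#' exact description. The first level with a unique hit wins and is
#' recorded. A symbol level matching two or more annotation rows is
#' ambiguous: the target is left unmatched and flagged, rather than
#' resolved arbitrarily (silent mis-mapping would corrupt the downstream
#' subnetwork). Blank or missing annotation cells never match. Results do
#' not depend on annotation row order for unambiguous queries.
#'
#' @param targets character vector of query gene identifiers.
#' @param annotation annotation data.frame (from [loadAnnotation()]).
#' @return data.frame: \code{target_id}, \code{row} (matched annotation row
#'   index or NA), \code{match_level} (\code{ensembl}, \code{rgd},
#'   \code{ncbi_id}, \code{symbol}, \code{description} or
#'   \code{unmatched}), \code{ambiguous}.
#' @export
reconcileIds <- function(targets, annotation) {
  stopifnot(is.character(targets) || length(targets) == 0L,
            is.data.frame(annotation))
  clean <- function(v) {
    v <- as.character(v)
    v[is.na(v) | v == ""] <- NA_character_
    v
  }
  cols <- list(
    ensembl = clean(annotation$ensembl_id),
    rgd = clean(annotation$rgd_id),
    ncbi_id = clean(annotation$ncbi_id),
    symbol = tolower(clean(annotation$symbol)),
    description = clean(annotation$description))

  n <- length(targets)
  row_idx <- rep(NA_integer_, n)
  level <- rep("unmatched", n)
  ambiguous <- rep(FALSE, n)
  for (i in seq_len(n)) {
    q <- targets[i]
    for (lv in names(cols)) {
      qv <- if (lv == "symbol") tolower(q) else q
      hits <- which(!is.na(cols[[lv]]) & cols[[lv]] == qv)
      if (length(hits) == 1L) {
        row_idx[i] <- hits
        level[i] <- lv
        break
      }
      if (length(hits) >= 2L) {
        ambiguous[i] <- TRUE   # unmatched-ambiguous: excluded, reported
        break
      }
    }
  }
  data.frame(target_id = targets, row = row_idx, match_level = level,
             ambiguous = ambiguous, stringsAsFactors = FALSE)
}

#' Select mitochondria-related targets
#'
#' A matched target is kept iff its annotation row carries a Gene Ontology
#' mitochondrial flag or an IMPI score strictly above \code{impi_min}.
#' Unmatched (including ambiguous) targets are dropped. The selection is a
#' pure predicate: applying it twice equals applying it once.
#'
#' @param matches output of [reconcileIds()].
#' @param annotation the annotation the matches refer to.
#' @param impi_min strict lower IMPI-score bound (default 0.7).
#' @return character vector of kept target identifiers.
#' @export
mitoSelect <- function(matches, annotation, impi_min = 0.7) {
  stopifnot(is.data.frame(matches),
            all(c("target_id", "row") %in% names(matches)))
  hit <- !is.na(matches$row)
  keep <- hit
  keep[hit] <- annotation$go_mito[matches$row[hit]] |
    annotation$impi_score[matches$row[hit]] > impi_min
  matches$target_id[keep]
}

#' Extract the subnetwork induced by a set of kept targets
#'
#' Restricts a signed bipartite network to the kept targets and to the miRs
#' retaining at least one edge to a kept target; edges are the induced
#' subset and node strengths are those recomputed on the subnetwork (via
#' [nodeStrength()] on the result).
#'
#' @param network a [SignedBipartiteNet-class].
#' @param kept_targets character vector of target ids to keep.
#' @return a [SignedBipartiteNet-class].
#' @export
extractSubnetwork <- function(network, kept_targets) {
  stopifnot(methods::is(network, "SignedBipartiteNet"))
  ed <- network@edges
  sub <- ed[ed$target_id %in% kept_targets, , drop = FALSE]
  rownames(sub) <- NULL
  dirs <- network@mirDirections
  dirs <- dirs[names(dirs) %in% sub$mir_id]
  methods::new("SignedBipartiteNet", edges = sub, mirDirections = dirs)
}
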