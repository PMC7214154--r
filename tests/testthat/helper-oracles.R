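# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Benjamini-Hochberg by direct definition: q_i = min_{j: p_j >= p_i}
# (m * p_(j) / j), capped at 1.
bhOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, m * p[ord] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  out <- numeric(m)
  out[ord] <- q_sorted
  out
}

# node strength by explicit edge-list summation
strengthOracle <- function(edges) {
  tg <- unique(edges$target_id)
  vapply(tg, function(t) sum(edges$weight[edges$target_id == t]),
         numeric(1))
}

# protective-pattern rule as an independent hand-coded decision tree
protectiveOracle <- function(ir, ipc, r, nr, require_ipc = TRUE) {
  if (ir == "unchanged") return(FALSE)
  if (ir == "up") {
    if (r != "down") return(FALSE)
    if (require_ipc && ipc != "down") return(FALSE)
    if (nr == "down") return(FALSE)
    return(TRUE)
  }
  # ir == "down"
  if (r != "up") return(FALSE)
  if (require_ipc && ipc != "up") return(FALSE)
  if (nr == "up") return(FALSE)
  TRUE
}

# induced subnetwork by neighbor sets
inducedOracle <- function(edges, kept) {
  sub <- edges[edges$target_id %in% kept, , drop = FALSE]
  list(mirs = sort(unique(sub$mir_id)),
       targets = sort(unique(sub$target_id)),
       edge_keys = sort(paste(sub$mir_id, sub$target_id, sub$weight)))
}

# small random signed bipartite network builder for property tests
randomNet <- function(n_mir = 10, n_target = 10, n_edges = 30) {
  mirs <- paste0("m", seq_len(n_mir))
  tgts <- paste0("t", seq_len(n_target))
  pairs <- unique(data.frame(
    mir_id = sample(mirs, n_edges, replace = TRUE),
    target_id = sample(tgts, n_edges, replace = TRUE),
    stringsAsFactors = FALSE))
  dirs <- setNames(sample(c("up", "down"), n_mir, replace = TRUE), mirs)
  sel <- data.frame(mir_id = mirs, direction = unname(dirs),
                    stringsAsFactors = FALSE)
  pairs$sources <- "validated"
  buildNetwork(sel, pairs)
}
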