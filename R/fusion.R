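## Evidence fusion: functional (DMN) weights and literature text-mining
## scores are combined per edge with the noisy-OR rule
## 1 - (1 - a)(1 - b), treating the two channels as independent sources
## of evidence.  A channel without the edge contributes 0.

#' Fuse one edge's functional and text-mining weights
#'
#' Noisy-OR combination `1 - (1 - dmn_w)(1 - st_w)`.  Symmetric,
#' monotone non-decreasing in each argument, and dominates both inputs.
#'
#' @param dmn_w,st_w numeric weights in `[0, 1]` (vectorized).
#' @return fused weight(s) in `[0, 1]`.
#' @export
fuse_edge <- function(dmn_w, st_w) {
  if (any(!is.finite(dmn_w)) || any(dmn_w < 0) || any(dmn_w > 1) ||
      any(!is.finite(st_w)) || any(st_w < 0) || any(st_w > 1)) {
    stop("fuse_edge: weights must be in [0,1]")
  }
  1 - (1 - dmn_w) * (1 - st_w)
}

#' Build the fused metabolite network (FLDMN)
#'
#' Edge set is the union of the DMN edges and the text-mining pairs whose
#' endpoints are both DMN nodes; each edge weight is the noisy-OR fusion
#' of the two channels.  Text-mining pairs touching a node outside the
#' DMN are skipped (count reported via `message()`).  The node set is the
#' DMN node set.
#'
#' @param dmn a `metabolite_network` of kind `"DMN"`.
#' @param st a [textmining_scores()].
#' @return a `metabolite_network` of kind `"FLDMN"`.
#' @export
build_fldmn <- function(dmn, st) {
  dmn_w <- edge_lookup(dmn)
  st_in <- st$edges[st$edges$node_a %in% dmn$nodes &
                      st$edges$node_b %in% dmn$nodes, , drop = FALSE]
  n_skip <- nrow(st$edges) - nrow(st_in)
  if (n_skip > 0L) {
    message("build_fldmn: skipped ", n_skip,
            " text-mining pair(s) with endpoints outside the DMN node set")
  }
  st_w <- stats::setNames(st_in$weight, pair_key(st_in$node_a, st_in$node_b))
  keys <- union(names(dmn_w), names(st_w))
  a <- vapply(strsplit(keys, "\t", fixed = TRUE), `[[`, character(1), 1L)
  b <- vapply(strsplit(keys, "\t", fixed = TRUE), `[[`, character(1), 2L)
  wa <- ifelse(keys %in% names(dmn_w), dmn_w[keys], 0)
  wb <- ifelse(keys %in% names(st_w), st_w[keys], 0)
  fused <- fuse_edge(as.numeric(wa), as.numeric(wb))
  keep <- fused > 0
  edges <- data.frame(node_a = a[keep], node_b = b[keep],
                      weight = fused[keep], stringsAsFactors = FALSE)
  metabolite_network(dmn$nodes, edges, "FLDMN")
}

#' Restrict text-mining scores to a node set
#'
#' Keeps the text-mining pairs with both endpoints in `nodes` and wraps
#' them as a standalone network (the literature-only baseline).
#'
#' @param st a [textmining_scores()].
#' @param nodes character vector of metabolite identifiers.
#' @return a `metabolite_network` of kind `"ST_SUBNET"` whose node set is
#'   `nodes` (isolated nodes retained).
#' @export
extract_st_subnet <- function(st, nodes) {
  keep <- st$edges$node_a %in% nodes & st$edges$node_b %in% nodes &
    st$edges$weight > 0
  metabolite_network(nodes, st$edges[keep, , drop = FALSE], "ST_SUBNET")
}
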