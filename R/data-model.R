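#' @keywords internal
"_PACKAGE"

## Canonical unordered-pair key used by every edge store.  Identifiers are
## opaque strings; tabs cannot occur in them (TSV transport), so "\t" is a
## safe separator.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}

## Canonical edge table: node_a < node_b lexicographically, one row per
## unordered pair, deterministic row order.
new_edge_table <- function(node_a, node_b, weight) {
  stopifnot(length(node_a) == length(node_b), length(node_b) == length(weight))
  a <- pmin(node_a, node_b)
  b <- pmax(node_a, node_b)
  df <- data.frame(node_a = a, node_b = b, weight = as.numeric(weight),
                   stringsAsFactors = FALSE)
  df <- df[order(df$node_a, df$node_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

validate_edge_table <- function(df, what = "edge table", allow_zero = TRUE) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$node_a == df$node_b)) {
    stop(what, ": self-loops are not allowed in the canonical store")
  }
  key <- pair_key(df$node_a, df$node_b)
  if (anyDuplicated(key)) {
    stop(what, ": duplicate unordered pair '",
         key[duplicated(key)][1L], "'")
  }
  lo <- if (allow_zero) df$weight < 0 else df$weight <= 0
  if (any(!is.finite(df$weight)) || any(lo) || any(df$weight > 1)) {
    stop(what, ": weights must be finite and in ",
         if (allow_zero) "[0,1]" else "(0,1]")
  }
  invisible(df)
}

#' Gene functional network
#'
#' A symmetric store of gene-gene functional association weights in
#' `[0, 1]`, as produced by fused functional networks (e.g. co-expression,
#' co-citation, orthology evidence combined into a single confidence).
#' Edges are kept as unordered pairs; there are no self-loops.
#'
#' @param edges data.frame with columns `node_a`, `node_b`, `weight`.
#' @return An object of class `gene_network`.
#' @export
gene_network <- function(edges) {
  edges <- new_edge_table(edges$node_a, edges$node_b, edges$weight)
  validate_edge_table(edges, "gene_network")
  structure(list(edges = edges), class = "gene_network")
}

#' Text-mining score store
#'
#' Symmetric metabolite-pair scores in `[0, 1]` derived from literature
#' co-occurrence (STITCH-style text-mining channel, rescaled on ingest).
#'
#' @param edges data.frame with columns `node_a`, `node_b`, `weight`.
#' @return An object of class `textmining_scores`.
#' @export
textmining_scores <- function(edges) {
  edges <- new_edge_table(edges$node_a, edges$node_b, edges$weight)
  validate_edge_table(edges, "textmining_scores")
  structure(list(edges = edges), class = "textmining_scores")
}

#' Weighted metabolite network
#'
#' An undirected weighted graph over metabolites.  `kind` tags which stage
#' produced it: `"DMN"` (cosine-similarity network from disease-relevance
#' profiles), `"ST_SUBNET"` (text-mining edges restricted to the study's
#' metabolites) or `"FLDMN"` (noisy-OR fusion of the two).  Stored edge
#' weights are in `(0, 1]`; zero-weight pairs are never stored.  Isolated
#' nodes are legal: `nodes` may exceed the endpoints of `edges`.
#'
#' @param nodes character vector of metabolite identifiers.
#' @param edges data.frame with columns `node_a`, `node_b`, `weight`.
#' @param kind one of `"DMN"`, `"ST_SUBNET"`, `"FLDMN"`.
#' @return An object of class `metabolite_network`.
#' @export
metabolite_network <- function(nodes, edges, kind = c("DMN", "ST_SUBNET", "FLDMN")) {
  kind <- match.arg(kind)
  edges <- new_edge_table(edges$node_a, edges$node_b, edges$weight)
  validate_edge_table(edges, "metabolite_network", allow_zero = FALSE)
  nodes <- sort(unique(c(nodes, edges$node_a, edges$node_b)))
  structure(list(nodes = nodes, edges = edges, kind = kind),
            class = "metabolite_network")
}

#' @export
print.metabolite_network <- function(x, ...) {
  cat(sprintf("<metabolite_network kind=%s: %d nodes, %d edges>\n",
              x$kind, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

## Fast unordered-pair weight lookup (named numeric vector).
edge_lookup <- function(x) {
  edges <- x$edges
  stats::setNames(edges$weight, pair_key(edges$node_a, edges$node_b))
}

#' Disease ontology DAG
#'
#' Directed acyclic graph of disease terms linked by IS_A relations, with
#' primary names and synonyms.  Validation enforces acyclicity, resolvable
#' parent references and the existence of at least one root.
#'
#' @param terms character vector of term identifiers.
#' @param parents named list: term -> character vector of parent terms.
#' @param labels named character vector: term -> primary name.
#' @param synonyms named list: term -> character vector of alternative names.
#' @return An object of class `ontology_dag`.
#' @export
ontology_dag <- function(terms, parents = list(), labels = character(),
                         synonyms = list()) {
  terms <- unique(as.character(terms))
  parents <- parents[intersect(names(parents), terms)]
  dangling <- setdiff(unlist(parents, use.names = FALSE), terms)
  if (length(dangling)) {
    stop("ontology_dag: is_a target(s) not defined as terms: ",
         paste(utils::head(dangling, 3L), collapse = ", "))
  }
  dag <- structure(list(terms = terms, parents = parents,
                        labels = labels, synonyms = synonyms),
                   class = "ontology_dag")
  cyc <- find_cycle_edge(dag)
  if (!is.null(cyc)) {
    stop("ontology_dag: cycle detected (edge ", cyc[1L], " IS_A ", cyc[2L], ")")
  }
  if (length(ontology_roots(dag)) == 0L) {
    stop("ontology_dag: no root term (every term has a parent)")
  }
  dag
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag: %d terms, %d root(s)>\n",
              length(x$terms), length(ontology_roots(x))))
  invisible(x)
}

#' Root terms of an ontology DAG
#' @param dag an `ontology_dag`.
#' @return character vector of terms with no parents.
#' @export
ontology_roots <- function(dag) {
  has_parent <- vapply(dag$terms, function(t) {
    length(dag$parents[[t]]) > 0L
  }, logical(1))
  dag$terms[!has_parent]
}

## Kahn's algorithm; returns c(child, parent) for one edge on a cycle,
## or NULL if acyclic.
find_cycle_edge <- function(dag) {
  indeg <- stats::setNames(integer(length(dag$terms)), dag$terms)
  out <- list()
  for (t in names(dag$parents)) {
    for (p in dag$parents[[t]]) {
      indeg[[p]] <- indeg[[p]] + 1L       # edge t -> p (child to parent)
      out[[t]] <- c(out[[t]], p)
    }
  }
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    u <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (v in out[[u]]) {
      indeg[[v]] <- indeg[[v]] - 1L
      if (indeg[[v]] == 0L) queue <- c(queue, v)
    }
  }
  if (seen == length(dag$terms)) return(NULL)
  remaining <- names(indeg)[indeg > 0L]
  for (bad in remaining) {   # a cycle member always has a remaining parent
    p <- intersect(dag$parents[[bad]], remaining)
    if (length(p)) return(c(bad, p[1L]))
  }
  c(remaining[1L], remaining[1L])
}

#' Ancestors of a term
#'
#' All terms reachable from `term` by following IS_A links upward.
#'
#' @param dag an `ontology_dag`.
#' @param term a term identifier in `dag`.
#' @param include_self include `term` itself (default `TRUE`).
#' @return character vector of ancestor terms (sorted).
#' @export
ontology_ancestors <- function(dag, term, include_self = TRUE) {
  stopifnot(term %in% dag$terms)
  out <- character()
  frontier <- term
  while (length(frontier)) {
    nxt <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  sort(unique(if (include_self) c(term, out) else out))
}

#' Descendants of a term
#' @inheritParams ontology_ancestors
#' @return character vector of descendant terms (sorted).
#' @export
ontology_descendants <- function(dag, term, include_self = TRUE) {
  stopifnot(term %in% dag$terms)
  children <- list()
  for (t in names(dag$parents)) {
    for (p in dag$parents[[t]]) children[[p]] <- c(children[[p]], t)
  }
  out <- character()
  frontier <- term
  while (length(frontier)) {
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  sort(unique(if (include_self) c(term, out) else out))
}

#' Disease-to-gene annotation store
#'
#' @param disease2genes named list: disease term -> character vector of gene
#'   identifiers.  Empty gene sets are legal.
#' @return An object of class `gene_annotation`.
#' @export
gene_annotation <- function(disease2genes) {
  stopifnot(is.list(disease2genes))
  disease2genes <- lapply(disease2genes, function(g) sort(unique(as.character(g))))
  structure(list(disease2genes = disease2genes), class = "gene_annotation")
}

#' Bipartite disease-metabolite association table
#'
#' @param records data.frame with columns `disease_id`, `metabolite_id`;
#'   duplicate pairs are collapsed.
#' @param version_tag free-text snapshot tag (e.g. a release date).
#' @return An object of class `association_table`.
#' @export
association_table <- function(records, version_tag = "") {
  stopifnot(all(c("disease_id", "metabolite_id") %in% names(records)))
  records <- data.frame(disease_id = as.character(records$disease_id),
                        metabolite_id = as.character(records$metabolite_id),
                        stringsAsFactors = FALSE)
  records <- unique(records)
  records <- records[order(records$disease_id, records$metabolite_id), ,
                     drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, version_tag = version_tag),
            class = "association_table")
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("<association_table [%s]: %d records, %d diseases, %d metabolites>\n",
              x$version_tag, nrow(x$records),
              length(unique(x$records$disease_id)),
              length(unique(x$records$metabolite_id))))
  invisible(x)
}

## Diseases directly related to each metabolite (DR_m as a named list).
metabolite_diseases <- function(assoc) {
  split(assoc$records$disease_id, assoc$records$metabolite_id)
}

## Metabolites directly related to each disease.
disease_metabolites <- function(assoc) {
  split(assoc$records$metabolite_id, assoc$records$disease_id)
}
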