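## Disease-disease functional similarity.
##
## Two diseases are similar when their annotated gene sets are strongly
## cross-connected in a gene functional network, discounted by how specific
## their most informative common ancestor (MICA) in the disease ontology
## is.  The raw score is
##
##   DiseaseFunSim(Ga, Gb) * (|Ga| |Gb|) / |G_MICA|^2
##
## where DiseaseFunSim averages best-match connection weights between the
## two gene sets and |G_MICA| counts the genes annotated (after DAG
## propagation) to the common ancestor with the highest information
## content.  Raw scores can exceed 1; the all-pairs matrix is rescaled by
## its off-diagonal maximum.

## gene -> (neighbour -> weight) adjacency, built once per network.
gene_adjacency <- function(net) {
  adj <- new.env(parent = emptyenv(), hash = TRUE)
  edges <- net$edges
  add <- function(g, h, w) {
    cur <- if (exists(g, envir = adj, inherits = FALSE)) get(g, envir = adj) else numeric()
    cur[h] <- w
    assign(g, cur, envir = adj)
  }
  for (i in seq_len(nrow(edges))) {
    add(edges$node_a[i], edges$node_b[i], edges$weight[i])
    add(edges$node_b[i], edges$node_a[i], edges$weight[i])
  }
  adj
}

#' Best-match connection weight of a gene into a gene set
#'
#' Returns 1 if `g` is a member of `genes`; otherwise the maximum
#' functional-network edge weight from `g` to any member, and 0 when no
#' such edge exists.
#'
#' @param g a gene identifier.
#' @param genes character vector (the target gene set).
#' @param net a [gene_network()].
#' @return a score in `[0, 1]`.
#' @export
gene_to_set_weight <- function(g, genes, net) {
  gene_to_set_weight_adj(g, genes, gene_adjacency(net))
}

gene_to_set_weight_adj <- function(g, genes, adj) {
  if (g %in% genes) return(1)
  if (!exists(g, envir = adj, inherits = FALSE)) return(0)
  nb <- get(g, envir = adj)
  hits <- nb[names(nb) %in% genes]
  if (length(hits) == 0L) return(0)
  max(hits)
}

#' Functional similarity of two gene sets
#'
#' Mean best-match connection weight over both directions:
#' `(sum_i R_Gb(g_ai) + sum_j R_Ga(g_bj)) / (|Ga| + |Gb|)`, where `R_G(g)`
#' is [gene_to_set_weight()].  Always in `[0, 1]`; identical nonempty sets
#' score exactly 1.  Two empty sets score 0 with a warning.
#'
#' @param Ga,Gb character vectors of gene identifiers.
#' @param net a [gene_network()].
#' @return a score in `[0, 1]`.
#' @export
disease_fun_sim <- function(Ga, Gb, net) {
  disease_fun_sim_adj(Ga, Gb, gene_adjacency(net))
}

disease_fun_sim_adj <- function(Ga, Gb, adj) {
  Ga <- unique(Ga); Gb <- unique(Gb)
  if (length(Ga) + length(Gb) == 0L) {
    warning("disease_fun_sim: both gene sets empty; similarity defined as 0")
    return(0)
  }
  s <- 0
  for (g in Ga) s <- s + gene_to_set_weight_adj(g, Gb, adj)
  for (g in Gb) s <- s + gene_to_set_weight_adj(g, Ga, adj)
  s / (length(Ga) + length(Gb))
}

#' Propagated gene counts per ontology term
#'
#' `|G_t|` for every term: the size of the union of the gene sets annotated
#' to `t` and to all of its descendants.  Propagation makes the count
#' monotone non-decreasing along IS_A paths, so a root aggregates every
#' annotated gene and is always a valid (least informative) common
#' ancestor.
#'
#' @param dag an [ontology_dag()].
#' @param ann a [gene_annotation()].
#' @return named integer vector: term -> propagated gene count.
#' @export
propagated_gene_counts <- function(dag, ann) {
  sets <- propagated_gene_sets(dag, ann)
  vapply(sets, length, integer(1))
}

propagated_gene_sets <- function(dag, ann) {
  out <- stats::setNames(vector("list", length(dag$terms)), dag$terms)
  for (t in dag$terms) {
    desc <- ontology_descendants(dag, t, include_self = TRUE)
    out[[t]] <- sort(unique(unlist(ann$disease2genes[desc], use.names = FALSE)))
  }
  out
}

#' Most informative common ancestor of two disease terms
#'
#' Among the common ancestors of `da` and `db` (the terms themselves
#' included), returns the one with maximal information content
#' `IC(t) = -log(|G_t| / |G_root|)` under propagated annotation counts.
#' Since IC is strictly decreasing in `|G_t|`, this is the common ancestor
#' with the fewest propagated genes; ties break by lexicographic term id.
#'
#' @param da,db disease term identifiers.
#' @param dag an [ontology_dag()].
#' @param ann a [gene_annotation()].
#' @param counts optional precomputed [propagated_gene_counts()].
#' @return list with elements `term` and `n_genes` (propagated `|G_MICA|`).
#' @export
find_mica <- function(da, db, dag, ann, counts = NULL) {
  if (is.null(counts)) counts <- propagated_gene_counts(dag, ann)
  common <- intersect(ontology_ancestors(dag, da), ontology_ancestors(dag, db))
  if (length(common) == 0L) {
    stop("find_mica: '", da, "' and '", db,
         "' share no common ancestor (forest input)")
  }
  n <- counts[common]
  ord <- order(n, common)     # min |G_t| == max IC; then lexicographic id
  pick <- common[ord[1L]]
  list(term = pick, n_genes = as.integer(n[[ord[1L]]]))
}

#' Disease-disease functional-semantic similarity (raw)
#'
#' `DiseaseFunSim(Ga, Gb) * (|Ga| |Gb|) / |G_MICA|^2` with `Ga`, `Gb` the
#' gene sets of the two diseases and `|G_MICA|` the propagated gene count
#' of their most informative common ancestor.  The raw value is
#' nonnegative but may exceed 1; see [all_pairs_similarity()] for the
#' normalized matrix.  `|G_MICA| = 0` (only possible when both gene sets
#' are empty) yields 0 with a warning.
#'
#' @param da,db disease term identifiers.
#' @param dag an [ontology_dag()].
#' @param ann a [gene_annotation()].
#' @param net a [gene_network()].
#' @param annotation use `"direct"` (default) or `"propagated"` gene sets
#'   for `Ga` and `Gb`; `|G_MICA|` always uses propagated counts.
#' @param cache optional list with precomputed `adj` (gene adjacency) and
#'   `counts` (propagated counts), used by the all-pairs driver.
#' @return a nonnegative score.
#' @export
fnsemsim <- function(da, db, dag, ann, net,
                     annotation = c("direct", "propagated"), cache = NULL) {
  annotation <- match.arg(annotation)
  adj <- if (is.null(cache)) gene_adjacency(net) else cache$adj
  counts <- if (is.null(cache)) propagated_gene_counts(dag, ann) else cache$counts
  psets <- if (!is.null(cache)) cache$psets else NULL
  get_set <- function(d) {
    if (annotation == "direct") {
      gs <- ann$disease2genes[[d]]
      if (is.null(gs)) character() else gs
    } else {
      if (is.null(psets)) psets <- propagated_gene_sets(dag, ann)
      psets[[d]]
    }
  }
  Ga <- get_set(da); Gb <- get_set(db)
  if (length(Ga) == 0L && length(Gb) == 0L) return(0)
  mica <- find_mica(da, db, dag, ann, counts)
  if (mica$n_genes == 0L) {
    warning("fnsemsim: |G_MICA| = 0 for pair (", da, ", ", db,
            "); similarity defined as 0")
    return(0)
  }
  fun <- disease_fun_sim_adj(Ga, Gb, adj)
  fun * (length(Ga) * length(Gb)) / (mica$n_genes^2)
}

#' All-pairs normalized disease similarity matrix
#'
#' Computes the raw functional-semantic similarity for every unordered
#' disease pair, then rescales by the maximum off-diagonal raw value so
#' all entries land in `[0, 1]` with ratios preserved.  The diagonal is
#' set to 1.  If every raw value is 0 the off-diagonal stays 0 (with a
#' warning).
#'
#' @param diseases character vector of disease terms (>= 2).
#' @param dag an [ontology_dag()].
#' @param ann a [gene_annotation()].
#' @param net a [gene_network()].
#' @param annotation passed to [fnsemsim()].
#' @param normalize `"max"` (divide by the off-diagonal maximum) or
#'   `"none"` (keep raw values, diagonal still forced to 1).
#' @return An object of class `disease_similarity`: list with `diseases`,
#'   `sim` (normalized symmetric matrix) and `raw` (unnormalized matrix).
#' @export
all_pairs_similarity <- function(diseases, dag, ann, net,
                                 annotation = c("direct", "propagated"),
                                 normalize = c("max", "none")) {
  annotation <- match.arg(annotation)
  normalize <- match.arg(normalize)
  diseases <- unique(as.character(diseases))
  stopifnot(length(diseases) >= 2L, all(diseases %in% dag$terms))
  cache <- list(adj = gene_adjacency(net),
                counts = propagated_gene_counts(dag, ann),
                psets = if (annotation == "propagated")
                  propagated_gene_sets(dag, ann) else NULL)
  n <- length(diseases)
  raw <- matrix(0, n, n, dimnames = list(diseases, diseases))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      v <- fnsemsim(diseases[i], diseases[j], dag, ann, net,
                    annotation = annotation, cache = cache)
      raw[i, j] <- v
      raw[j, i] <- v
    }
  }
  sim <- raw
  if (normalize == "max") {
    mx <- max(raw[upper.tri(raw)])
    if (mx > 0) {
      sim <- raw / mx
    } else {
      warning("all_pairs_similarity: all raw similarities are zero")
    }
  }
  diag(sim) <- 1
  structure(list(diseases = diseases, sim = sim, raw = raw),
            class = "disease_similarity")
}

#' @export
print.disease_similarity <- function(x, ...) {
  cat(sprintf("<disease_similarity: %d diseases, off-diagonal max raw = %.4g>\n",
              length(x$diseases), max(x$raw[upper.tri(x$raw)], 0)))
  invisible(x)
}

#' Write a disease similarity matrix as TSV
#'
#' One row per unordered pair: `disease_a`, `disease_b`, `raw_sim`,
#' `normalized_sim`.
#'
#' @param dsim a `disease_similarity`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_disease_similarity <- function(dsim, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("disease_a\tdisease_b\traw_sim\tnormalized_sim", con)
  d <- sort(dsim$diseases)
  for (i in seq_len(length(d) - 1L)) {
    for (j in seq((i + 1L), length(d))) {
      writeLines(paste(d[i], d[j],
                       sprintf("%.15g", dsim$raw[d[i], d[j]]),
                       sprintf("%.15g", dsim$sim[d[i], d[j]]),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a disease similarity TSV written by [write_disease_similarity()]
#' @param path path to the TSV file.
#' @return a `disease_similarity` (raw and normalized matrices).
#' @export
read_disease_similarity <- function(path) {
  tl <- read_tsv_lines(path)
  fields <- strsplit(tl$lines[[1L]], "\t", fixed = TRUE)[[1L]]
  idx <- tsv_header_index(fields, c("disease_a", "disease_b", "raw_sim",
                                    "normalized_sim"), path)
  parts <- strsplit(tl$lines[-1L], "\t", fixed = TRUE)
  a <- vapply(parts, `[[`, character(1), idx[1L])
  b <- vapply(parts, `[[`, character(1), idx[2L])
  raw_v <- as.numeric(vapply(parts, `[[`, character(1), idx[3L]))
  nrm_v <- as.numeric(vapply(parts, `[[`, character(1), idx[4L]))
  diseases <- sort(unique(c(a, b)))
  n <- length(diseases)
  raw <- matrix(0, n, n, dimnames = list(diseases, diseases))
  sim <- raw
  raw[cbind(a, b)] <- raw_v; raw[cbind(b, a)] <- raw_v
  sim[cbind(a, b)] <- nrm_v; sim[cbind(b, a)] <- nrm_v
  diag(sim) <- 1
  structure(list(diseases = diseases, sim = sim, raw = raw),
            class = "disease_similarity")
}
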