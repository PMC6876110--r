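# Brute-force oracles, written independently of the package internals:
# naive loops and direct formula substitution only.  They take plain R
# structures (parent lists, data.frames, matrices).

ora_ancestors <- function(parents, term) {
  out <- term
  repeat {
    nxt <- setdiff(unique(unlist(parents[out], use.names = FALSE)), out)
    if (!length(nxt)) break
    out <- c(out, nxt)
  }
  sort(out)
}

ora_descendants <- function(parents, terms, term) {
  sort(terms[vapply(terms, function(t) term %in% ora_ancestors(parents, t),
                    logical(1))])
}

# best-match weight of gene g into set G, scanning the raw edge data.frame
ora_R <- function(g, G, edf) {
  if (g %in% G) return(1)
  w <- c(edf$weight[edf$node_a == g & edf$node_b %in% G],
         edf$weight[edf$node_b == g & edf$node_a %in% G])
  if (!length(w)) 0 else max(w)
}

ora_dfs <- function(Ga, Gb, edf) {
  Ga <- unique(Ga); Gb <- unique(Gb)
  if (!length(Ga) && !length(Gb)) return(0)
  s <- 0
  for (g in Ga) s <- s + ora_R(g, Gb, edf)
  for (g in Gb) s <- s + ora_R(g, Ga, edf)
  s / (length(Ga) + length(Gb))
}

ora_prop_count <- function(parents, terms, d2g, t) {
  length(unique(unlist(d2g[ora_descendants(parents, terms, t)],
                       use.names = FALSE)))
}

ora_fnsemsim <- function(da, db, parents, terms, d2g, edf) {
  Ga <- unique(d2g[[da]]); Gb <- unique(d2g[[db]])
  if (!length(Ga) && !length(Gb)) return(0)
  common <- intersect(ora_ancestors(parents, da), ora_ancestors(parents, db))
  n <- vapply(common, function(t) ora_prop_count(parents, terms, d2g, t),
              numeric(1))
  ord <- order(n, common)
  n_mica <- n[[ord[1L]]]
  if (n_mica == 0) return(0)
  ora_dfs(Ga, Gb, edf) * length(Ga) * length(Gb) / n_mica^2
}

ora_all_pairs <- function(diseases, parents, terms, d2g, edf) {
  n <- length(diseases)
  raw <- matrix(0, n, n, dimnames = list(diseases, diseases))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      v <- ora_fnsemsim(diseases[i], diseases[j], parents, terms, d2g, edf)
      raw[i, j] <- v; raw[j, i] <- v
    }
  }
  mx <- max(raw)
  sim <- if (mx > 0) raw / mx else raw
  diag(sim) <- 1
  list(raw = raw, sim = sim)
}

# direct nested-loop profile matrix + cosine network
ora_dmn <- function(assoc_df, sim, threshold) {
  mets <- sort(unique(assoc_df$metabolite_id))
  ds <- sort(unique(assoc_df$disease_id))
  PA <- matrix(0, length(mets), length(ds), dimnames = list(mets, ds))
  for (m in mets) {
    dr <- unique(assoc_df$disease_id[assoc_df$metabolite_id == m])
    for (d in ds) {
      PA[m, d] <- if (d %in% dr) 1 else max(vapply(dr, function(di) sim[di, d],
                                                   numeric(1)))
    }
  }
  W <- matrix(0, length(mets), length(mets), dimnames = list(mets, mets))
  edges <- list()
  for (i in seq_len(length(mets) - 1)) {
    for (j in seq(i + 1, length(mets))) {
      num <- sum(PA[i, ] * PA[j, ])
      den <- sqrt(sum(PA[i, ]^2)) * sqrt(sum(PA[j, ]^2))
      w <- num / den
      W[i, j] <- w; W[j, i] <- w
      if (w > threshold) {
        edges[[length(edges) + 1L]] <- data.frame(
          node_a = mets[i], node_b = mets[j], weight = w)
      }
    }
  }
  list(PA = PA, W = W,
       edges = if (length(edges)) do.call(rbind, edges) else
         data.frame(node_a = character(), node_b = character(),
                    weight = numeric()))
}

# all-pairs Mann-Whitney AUC with half-credit ties
ora_auc <- function(pos_scores, neg_scores) {
  s <- 0
  for (p in pos_scores) {
    for (q in neg_scores) {
      s <- s + (p > q) + 0.5 * (p == q)
    }
  }
  s / (length(pos_scores) * length(neg_scores))
}

# --- random fixture builders (deterministic given the RNG state) --------

rand_dag <- function(n_terms) {
  terms <- sprintf("t%02d", seq_len(n_terms))
  parents <- list()
  for (i in seq_len(n_terms)[-1]) {
    parents[[terms[i]]] <- terms[sample.int(i - 1L, 1L)]
  }
  list(terms = terms, parents = parents)
}

rand_gene_fixture <- function(n_diseases = 4, n_terms = 8, n_genes = 8,
                              p_edge = 0.4) {
  stopifnot(n_diseases <= n_terms)
  dg <- rand_dag(n_terms)
  diseases <- sample(dg$terms, n_diseases)
  genes <- sprintf("g%02d", seq_len(n_genes))
  d2g <- lapply(dg$terms, function(t) {
    if (t %in% diseases) sample(genes, sample.int(max(1, n_genes %/% 2), 1L))
    else character()
  })
  names(d2g) <- dg$terms
  ee <- t(combn(genes, 2))
  keep <- runif(nrow(ee)) < p_edge
  edf <- data.frame(node_a = ee[keep, 1L], node_b = ee[keep, 2L],
                    weight = round(runif(sum(keep)), 4),
                    stringsAsFactors = FALSE)
  list(dag_terms = dg$terms, parents = dg$parents, diseases = diseases,
       d2g = d2g, edf = edf)
}

rand_metabolite_net <- function(n_nodes = 20, p_edge = 0.3) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  ee <- t(combn(nodes, 2))
  keep <- runif(nrow(ee)) < p_edge
  edf <- data.frame(node_a = ee[keep, 1L], node_b = ee[keep, 2L],
                    weight = round(runif(sum(keep), 0.05, 1), 4),
                    stringsAsFactors = FALSE)
  metabolite_network(nodes, edf, "DMN")
}

# disease_similarity stand-in built directly from a matrix
make_dsim <- function(sim) {
  structure(list(diseases = rownames(sim), sim = sim, raw = sim),
            class = "disease_similarity")
}
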