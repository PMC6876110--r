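## Synthetic fixture generator.
##
## The generative model mirrors the premise the pipeline exploits:
## functionally related metabolites tend to associate with the same or
## similar diseases.  Diseases, genes and metabolites are partitioned
## into modules; diseases of a module draw overlapping gene sets from the
## module's gene pool (making their functional similarity high), and
## metabolites associate preferentially with their module's diseases.
## The later association snapshot adds back a chosen number of withheld
## within-module associations, which form the ground-truth positives for
## the two-snapshot evaluation.

#' Specification of a synthetic fixture
#'
#' Defaults describe a benchmark with clear planted structure: 3 modules,
#' 12 diseases, 60 metabolites, 60 genes, strong within-module
#' association probability (0.6) against a weak cross-module floor
#' (0.05), mostly concordant text mining (0.9) and 15 withheld
#' associations forming the later snapshot's novelties.
#'
#' @param n_diseases,n_metabolites,n_genes positive integers.
#' @param n_modules number of planted modules.
#' @param within_module_assoc_prob,cross_module_assoc_prob association
#'   probabilities inside/outside a metabolite's module.
#' @param textmining_concordance probability that a text-mining pair links
#'   two truly co-associated metabolites (sharing a disease in the full
#'   association set, withheld associations included); `NA` samples pairs
#'   uniformly (structure-free).
#' @param n_textmining number of text-mining pairs.
#' @param snapshot_delta associations withheld from the earlier snapshot
#'   and present only in the later one.
#' @param seed integer seed; generation is fully reproducible.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_diseases = 12L, n_metabolites = 60L, n_genes = 60L,
                         n_modules = 3L,
                         within_module_assoc_prob = 0.6,
                         cross_module_assoc_prob = 0.05,
                         textmining_concordance = 0.9,
                         n_textmining = 2L * n_metabolites,
                         snapshot_delta = 15L, seed = 1L) {
  stopifnot(n_diseases >= n_modules, n_metabolites >= n_modules,
            n_genes >= n_modules, n_modules >= 1,
            within_module_assoc_prob >= 0, within_module_assoc_prob <= 1,
            cross_module_assoc_prob >= 0, cross_module_assoc_prob <= 1,
            is.na(textmining_concordance) ||
              (textmining_concordance >= 0 && textmining_concordance <= 1),
            snapshot_delta >= 0)
  structure(list(n_diseases = as.integer(n_diseases),
                 n_metabolites = as.integer(n_metabolites),
                 n_genes = as.integer(n_genes),
                 n_modules = as.integer(n_modules),
                 within_module_assoc_prob = within_module_assoc_prob,
                 cross_module_assoc_prob = cross_module_assoc_prob,
                 textmining_concordance = textmining_concordance,
                 n_textmining = as.integer(n_textmining),
                 snapshot_delta = as.integer(snapshot_delta),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

with_fixture_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic fixture bundle
#'
#' Builds all pipeline inputs in memory and (optionally) writes them to
#' `dir` as plain-text files: `ontology.obo`, `disease_genes.tsv`,
#' `gene_network.tsv`, `associations_earlier.tsv`,
#' `associations_later.tsv`, `stitch.tsv`, `medic.tsv`,
#' `associations_earlier_names.tsv` (free-text disease names for the
#' mapping stage) and `truth.tsv` (one row per withheld association,
#' columns disease/metabolite/split).
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created); `NULL` keeps everything in memory.
#' @return list with `spec`, `paths` (or `NULL`), and `objects`: `dag`,
#'   `ann` ([gene_annotation()]), `gnet` ([gene_network()]), `earlier`,
#'   `later` ([association_table()]), `st` ([textmining_scores()]),
#'   `medic`, `truth` (data.frame), and the module assignments
#'   `disease_module`, `metabolite_module`.
#' @export
generate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_seed(spec$seed, {
    k <- spec$n_modules
    diseases <- sprintf("SYND:%04d", seq_len(spec$n_diseases))
    metabolites <- sprintf("SYNM%04d", seq_len(spec$n_metabolites))
    genes <- sprintf("SYNG%04d", seq_len(spec$n_genes))
    d_mod <- rep_len(seq_len(k), spec$n_diseases)
    m_mod <- rep_len(seq_len(k), spec$n_metabolites)
    g_mod <- rep_len(seq_len(k), spec$n_genes)

    ## ontology: root <- module terms <- disease leaves
    root <- "SYND:0000"
    mod_terms <- sprintf("SYND:M%02d", seq_len(k))
    terms <- c(root, mod_terms, diseases)
    parents <- c(stats::setNames(lapply(mod_terms, function(x) root), mod_terms),
                 stats::setNames(lapply(d_mod, function(mm) mod_terms[mm]), diseases))
    labels <- c(stats::setNames("synthetic disease root", root),
                stats::setNames(sprintf("synthetic module %d", seq_len(k)), mod_terms),
                stats::setNames(sprintf("synthetic disease %d", seq_len(spec$n_diseases)),
                                diseases))
    synonyms <- stats::setNames(
      lapply(seq_len(spec$n_diseases), function(i) sprintf("syndrome sd-%d", i)),
      diseases)
    dag <- ontology_dag(terms, parents, labels, synonyms)

    ## gene annotations: each disease samples ~60% of its module's pool
    d2g <- lapply(seq_len(spec$n_diseases), function(i) {
      pool <- genes[g_mod == d_mod[i]]
      n <- max(2L, round(0.6 * length(pool)))
      sort(sample(pool, min(n, length(pool))))
    })
    ann <- gene_annotation(stats::setNames(d2g, diseases))

    ## gene network: dense strong edges within modules, sparse weak across
    ge <- list()
    for (i in seq_len(spec$n_genes - 1L)) {
      for (j in seq((i + 1L), spec$n_genes)) {
        same <- g_mod[i] == g_mod[j]
        p <- if (same) 0.5 else 0.03
        if (stats::runif(1) < p) {
          w <- if (same) stats::runif(1, 0.6, 0.95) else stats::runif(1, 0.05, 0.2)
          ge[[length(ge) + 1L]] <- data.frame(node_a = genes[i], node_b = genes[j],
                                              weight = w)
        }
      }
    }
    gnet <- gene_network(if (length(ge)) do.call(rbind, ge) else
      data.frame(node_a = character(), node_b = character(), weight = numeric()))

    ## associations: module-biased bipartite sampling
    pairs <- expand.grid(mi = seq_len(spec$n_metabolites),
                         di = seq_len(spec$n_diseases))
    same <- m_mod[pairs$mi] == d_mod[pairs$di]
    p <- ifelse(same, spec$within_module_assoc_prob, spec$cross_module_assoc_prob)
    drawn <- stats::runif(nrow(pairs)) < p
    # guarantee every metabolite has at least one association (within module)
    for (mi in seq_len(spec$n_metabolites)) {
      if (!any(drawn[pairs$mi == mi])) {
        cand <- which(pairs$mi == mi & same)
        if (length(cand) == 0L) cand <- which(pairs$mi == mi)
        drawn[cand[sample.int(length(cand), 1L)]] <- TRUE
      }
    }
    all_assoc <- data.frame(disease_id = diseases[pairs$di[drawn]],
                            metabolite_id = metabolites[pairs$mi[drawn]],
                            same_module = same[drawn],
                            stringsAsFactors = FALSE)

    ## withhold snapshot_delta within-module associations for the later
    ## snapshot, keeping every disease/metabolite represented in earlier
    hidden_idx <- integer()
    if (spec$snapshot_delta > 0L) {
      eligible <- which(all_assoc$same_module)
      eligible <- sample(eligible)   # random order
      d_count <- table(all_assoc$disease_id)
      m_count <- table(all_assoc$metabolite_id)
      for (i in eligible) {
        if (length(hidden_idx) >= spec$snapshot_delta) break
        d <- all_assoc$disease_id[i]; m <- all_assoc$metabolite_id[i]
        if (d_count[[d]] > 1L && m_count[[m]] > 1L) {
          hidden_idx <- c(hidden_idx, i)
          d_count[[d]] <- d_count[[d]] - 1L
          m_count[[m]] <- m_count[[m]] - 1L
        }
      }
      if (length(hidden_idx) < spec$snapshot_delta) {
        stop("generate_fixture: snapshot_delta = ", spec$snapshot_delta,
             " exceeds the ", length(hidden_idx),
             " withholdable within-module associations")
      }
    }
    earlier_df <- all_assoc[setdiff(seq_len(nrow(all_assoc)), hidden_idx),
                            c("disease_id", "metabolite_id")]
    later_df <- all_assoc[, c("disease_id", "metabolite_id")]
    earlier <- association_table(earlier_df, "earlier")
    later <- association_table(later_df, "later")
    truth <- data.frame(disease_id = all_assoc$disease_id[hidden_idx],
                        metabolite_id = all_assoc$metabolite_id[hidden_idx],
                        split = rep("positive", length(hidden_idx)),
                        stringsAsFactors = FALSE)
    truth <- truth[order(truth$disease_id, truth$metabolite_id), , drop = FALSE]
    rownames(truth) <- NULL

    ## text-mining pairs.  A concordant pair links two metabolites that
    ## are truly co-associated (share a disease in the full association
    ## set, withheld pairs included) -- emulating literature that reports
    ## co-studied metabolites independently of the earlier snapshot.
    ## Non-concordant pairs are uniform noise.
    m_index <- stats::setNames(seq_along(metabolites), metabolites)
    by_d <- split(m_index[all_assoc$metabolite_id], all_assoc$disease_id)
    co_pairs <- unique(do.call(rbind, lapply(by_d, function(ms) {
      ms <- sort(unique(ms))
      if (length(ms) < 2L) return(NULL)
      t(utils::combn(ms, 2L))
    })))
    st_keys <- character(); st_rows <- list()
    n_try <- 0L
    while (length(st_rows) < spec$n_textmining && n_try < 50L * spec$n_textmining) {
      n_try <- n_try + 1L
      if (!is.na(spec$textmining_concordance) &&
          !is.null(co_pairs) && nrow(co_pairs) > 0L &&
          stats::runif(1) < spec$textmining_concordance) {
        ij <- co_pairs[sample.int(nrow(co_pairs), 1L), ]
      } else {
        ij <- sample.int(spec$n_metabolites, 2L)
      }
      key <- pair_key(metabolites[ij[1L]], metabolites[ij[2L]])
      if (key %in% st_keys) next
      st_keys <- c(st_keys, key)
      st_rows[[length(st_rows) + 1L]] <- data.frame(
        node_a = metabolites[ij[1L]], node_b = metabolites[ij[2L]],
        weight = round(stats::runif(1, 0.2, 0.9), 6))
    }
    st <- textmining_scores(if (length(st_rows)) do.call(rbind, st_rows) else
      data.frame(node_a = character(), node_b = character(), weight = numeric()))

    ## MEDIC-style vocabulary rows pointing at the ontology leaves
    medic <- data.frame(
      DiseaseName = sprintf("medic name %d", seq_len(spec$n_diseases)),
      Synonyms = sprintf("medic synonym %da|medic synonym %db",
                         seq_len(spec$n_diseases), seq_len(spec$n_diseases)),
      DOxref = diseases, stringsAsFactors = FALSE)

    out <- list(spec = spec, paths = NULL,
                objects = list(dag = dag, ann = ann, gnet = gnet,
                               earlier = earlier, later = later, st = st,
                               medic = medic, truth = truth,
                               disease_module = stats::setNames(d_mod, diseases),
                               metabolite_module = stats::setNames(m_mod, metabolites)))
    if (!is.null(dir)) out$paths <- write_fixture_bundle(out$objects, dag, dir)
    out
  })
}

write_fixture_bundle <- function(objects, dag, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    ontology = file.path(dir, "ontology.obo"),
    disease_genes = file.path(dir, "disease_genes.tsv"),
    gene_network = file.path(dir, "gene_network.tsv"),
    earlier = file.path(dir, "associations_earlier.tsv"),
    later = file.path(dir, "associations_later.tsv"),
    stitch = file.path(dir, "stitch.tsv"),
    medic = file.path(dir, "medic.tsv"),
    earlier_names = file.path(dir, "associations_earlier_names.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_ontology(dag, paths$ontology)
  write_gene_annotation(objects$ann, paths$disease_genes)
  write_weighted_edges(objects$gnet, paths$gene_network)
  write_association_table(objects$earlier, paths$earlier)
  write_association_table(objects$later, paths$later)
  write_weighted_edges(objects$st, paths$stitch)
  utils::write.table(objects$medic, paths$medic, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ## the earlier snapshot keyed by primary disease *names*, for map stage
  nm <- dag$labels[objects$earlier$records$disease_id]
  utils::write.table(
    data.frame(disease_name = as.character(nm),
               metabolite_id = objects$earlier$records$metabolite_id),
    paths$earlier_names, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(objects$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

#' Hand-verifiable worked example
#'
#' A fixed tiny instance: 4 diseases in two ontology branches, 6 genes,
#' 5 metabolites, 3 gene-network edges, 3 text-mining pairs and one
#' association gained in the later snapshot.  Every downstream quantity
#' (disease similarities, profile matrix, DMN, FLDMN, RWR ranking) is
#' small enough to derive by hand; the derivations and frozen values live
#' in the package vignette and test suite.
#'
#' @param dir optional output directory for the plain-text bundle.
#' @return same shape as [generate_fixture()].
#' @export
generate_worked_example <- function(dir = NULL) {
  dag <- ontology_dag(
    terms = c("WD:ROOT", "WD:B1", "WD:B2", "WD:D1", "WD:D2", "WD:D3", "WD:D4"),
    parents = list("WD:B1" = "WD:ROOT", "WD:B2" = "WD:ROOT",
                   "WD:D1" = "WD:B1", "WD:D2" = "WD:B1",
                   "WD:D3" = "WD:B2", "WD:D4" = "WD:B2"),
    labels = c("WD:ROOT" = "worked root", "WD:B1" = "worked branch one",
               "WD:B2" = "worked branch two", "WD:D1" = "worked disease one",
               "WD:D2" = "worked disease two", "WD:D3" = "worked disease three",
               "WD:D4" = "worked disease four"),
    synonyms = list("WD:D1" = "wd one"))
  ann <- gene_annotation(list(
    "WD:D1" = c("g1", "g2"), "WD:D2" = c("g2", "g3"),
    "WD:D3" = c("g4", "g5"), "WD:D4" = c("g5", "g6")))
  gnet <- gene_network(data.frame(
    node_a = c("g1", "g4", "g2"), node_b = c("g3", "g6", "g5"),
    weight = c(0.5, 0.8, 0.4)))
  earlier <- association_table(data.frame(
    disease_id = c("WD:D1", "WD:D1", "WD:D2", "WD:D2", "WD:D3", "WD:D3", "WD:D4"),
    metabolite_id = c("m1", "m2", "m2", "m3", "m4", "m5", "m5")), "earlier")
  later <- association_table(rbind(
    earlier$records,
    data.frame(disease_id = "WD:D4", metabolite_id = "m4")), "later")
  st <- textmining_scores(data.frame(
    node_a = c("m1", "m4", "m2"), node_b = c("m2", "m5", "m4"),
    weight = c(0.5, 0.9, 0.2)))
  medic <- data.frame(DiseaseName = "worked disease one (medic)",
                      Synonyms = "wd medic one",
                      DOxref = "WD:D1", stringsAsFactors = FALSE)
  truth <- data.frame(disease_id = "WD:D4", metabolite_id = "m4",
                      split = "positive", stringsAsFactors = FALSE)
  objects <- list(dag = dag, ann = ann, gnet = gnet, earlier = earlier,
                  later = later, st = st, medic = medic, truth = truth)
  out <- list(spec = NULL, paths = NULL, objects = objects)
  if (!is.null(dir)) out$paths <- write_fixture_bundle(objects, dag, dir)
  out
}
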