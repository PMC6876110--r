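## Two-snapshot validation.
##
## Seeds come from the earlier association snapshot; positives are the
## associations a disease gains in the later snapshot (restricted to
## network nodes); the candidate pool is every non-seed network node.
## Ranking quality per disease is the Mann-Whitney AUC of positives vs
## the remaining pool, and the headline statistic is the unweighted mean
## across diseases.

#' Build per-disease validation cases from two association snapshots
#'
#' One case per disease with at least one earlier-snapshot seed present
#' in the network and at least one later-snapshot novel metabolite that
#' is a network node.  Associations already present in the earlier
#' snapshot are never positives.  Diseases failing the criteria are
#' skipped (reported via `message()`).
#'
#' @param earlier,later [association_table()] snapshots over the same
#'   identifier spaces.
#' @param net a `metabolite_network`.
#' @return list of `validation_case` objects, each with `disease`,
#'   `seed_metabolites`, `positive_metabolites`, `candidate_pool`.
#' @export
build_validation_cases <- function(earlier, later, net) {
  e_by_d <- disease_metabolites(earlier)
  l_by_d <- disease_metabolites(later)
  cases <- list()
  skipped <- 0L
  for (d in sort(unique(c(names(e_by_d), names(l_by_d))))) {
    seeds <- intersect(unique(e_by_d[[d]]), net$nodes)
    novel <- setdiff(unique(l_by_d[[d]]), unique(e_by_d[[d]]))
    positives <- intersect(novel, net$nodes)
    if (length(seeds) == 0L || length(positives) == 0L) {
      skipped <- skipped + 1L
      next
    }
    pool <- setdiff(net$nodes, seeds)
    cases[[length(cases) + 1L]] <- structure(
      list(disease = d, seed_metabolites = sort(seeds),
           positive_metabolites = sort(positives),
           candidate_pool = sort(pool)),
      class = "validation_case")
  }
  if (skipped) {
    message("build_validation_cases: skipped ", skipped,
            " disease(s) without seeds or novel network-node positives")
  }
  cases
}

#' Mann-Whitney AUC of a score ranking
#'
#' Probability that a random positive outranks a random negative, ties
#' counted half: `(#concordant + 0.5 #tied) / (n_pos * n_neg)` with
#' negatives = `pool` minus `positives`.  Computed via the rank-sum
#' identity with midranks.
#'
#' @param scores named numeric vector covering `pool`.
#' @param positives nonempty character vector, a subset of `pool`.
#' @param pool character vector of ranked candidates.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, positives, pool) {
  positives <- unique(positives)
  negatives <- setdiff(pool, positives)
  if (length(positives) == 0L) stop("auc_score: empty positive set")
  if (length(negatives) == 0L) stop("auc_score: empty negative set")
  stopifnot(all(positives %in% pool), all(pool %in% names(scores)))
  s <- scores[c(positives, negatives)]
  rk <- rank(s, ties.method = "average")
  np <- length(positives); nn <- length(negatives)
  (sum(rk[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Evaluate a network on a set of validation cases
#'
#' Runs RWR seeded on each case's earlier-snapshot metabolites and scores
#' the candidate pool; reports per-disease AUC and the unweighted mean.
#' Cases whose seeds or positives are absent from this network (possible
#' when cases were built against a different network, e.g. in a threshold
#' sweep) are restricted to the network's nodes and skipped when nothing
#' usable remains.
#'
#' @param net a `metabolite_network`.
#' @param cases list of `validation_case` objects.
#' @param cfg an [rwr_config()].
#' @return An object of class `evaluation_report`: list with `per_case`
#'   (data.frame: disease, n_seeds, n_positives, n_pool, auc),
#'   `mean_auc` and `skipped` (character vector of skipped diseases).
#' @export
evaluate_network <- function(net, cases, cfg = rwr_config()) {
  stopifnot(length(cases) > 0L)
  rows <- list()
  skipped <- character()
  for (case in cases) {
    seeds <- intersect(case$seed_metabolites, net$nodes)
    positives <- intersect(case$positive_metabolites, net$nodes)
    pool <- setdiff(net$nodes, seeds)
    if (length(seeds) == 0L || length(positives) == 0L ||
        length(setdiff(pool, positives)) == 0L) {
      skipped <- c(skipped, case$disease)
      next
    }
    res <- rwr_scores(net, seeds, cfg)
    a <- auc_score(res$scores, positives, pool)
    rows[[length(rows) + 1L]] <- data.frame(
      disease = case$disease, n_seeds = length(seeds),
      n_positives = length(positives), n_pool = length(pool),
      auc = a, stringsAsFactors = FALSE)
  }
  per_case <- if (length(rows)) do.call(rbind, rows) else
    data.frame(disease = character(), n_seeds = integer(),
               n_positives = integer(), n_pool = integer(), auc = numeric())
  structure(list(per_case = per_case,
                 mean_auc = if (nrow(per_case)) mean(per_case$auc) else NA_real_,
                 skipped = skipped),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report: %d case(s), mean AUC %s%s>\n",
              nrow(x$per_case),
              if (is.na(x$mean_auc)) "NA" else sprintf("%.4f", x$mean_auc),
              if (length(x$skipped)) sprintf(", %d skipped", length(x$skipped)) else ""))
  invisible(x)
}

#' Metabolite-seeded evaluation
#'
#' Seeds RWR at a single target metabolite and measures how well the
#' metabolites co-associated with it (sharing at least one disease) are
#' ranked among all other nodes.
#'
#' @param net a `metabolite_network`.
#' @param target a metabolite identifier in `net`.
#' @param co_associated nonempty character vector of metabolites sharing
#'   a disease with `target` (the positives); restricted to network nodes.
#' @param cfg an [rwr_config()].
#' @return the AUC.
#' @export
metabolite_seed_evaluation <- function(net, target, co_associated,
                                       cfg = rwr_config()) {
  stopifnot(length(target) == 1L, target %in% net$nodes)
  positives <- setdiff(intersect(unique(co_associated), net$nodes), target)
  if (length(positives) == 0L) {
    stop("metabolite_seed_evaluation: no co-associated metabolite in the network")
  }
  res <- rwr_scores(net, target, cfg)
  pool <- setdiff(net$nodes, target)
  auc_score(res$scores, positives, pool)
}

#' Mean AUC across a DMN threshold sweep
#'
#' Rebuilds the DMN at each threshold (optionally fusing text-mining
#' scores into an FLDMN) and evaluates the given cases.  Thresholds whose
#' network supports no case report `NA`.
#'
#' @param profiles a `metabolite_profiles`.
#' @param thresholds ascending numeric vector of edge thresholds.
#' @param cases list of `validation_case` objects.
#' @param cfg an [rwr_config()].
#' @param st optional [textmining_scores()]; when given each network is
#'   the FLDMN fusion instead of the bare DMN.
#' @return data.frame: threshold, n_edges, n_cases, mean_auc.
#' @export
threshold_sweep <- function(profiles, thresholds, cases, cfg = rwr_config(),
                            st = NULL) {
  stopifnot(!is.unsorted(thresholds))
  rows <- lapply(thresholds, function(th) {
    net <- build_dmn(profiles, th)
    if (!is.null(st)) net <- build_fldmn(net, st)
    rep <- evaluate_network(net, cases, cfg)
    data.frame(threshold = th, n_edges = nrow(net$edges),
               n_cases = nrow(rep$per_case), mean_auc = rep$mean_auc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an evaluation report as TSV
#' @param report an `evaluation_report`.
#' @param path output path.
#' @param header_lines extra comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path, header_lines = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (h in header_lines) writeLines(paste0("# ", h), con)
  writeLines(paste0("# mean_auc: ", sprintf("%.15g", report$mean_auc)), con)
  if (length(report$skipped)) {
    writeLines(paste0("# skipped: ", paste(report$skipped, collapse = ",")), con)
  }
  writeLines("disease\tn_seeds\tn_positives\tn_pool\tauc", con)
  pc <- report$per_case
  if (nrow(pc)) {
    writeLines(paste(pc$disease, pc$n_seeds, pc$n_positives, pc$n_pool,
                     sprintf("%.15g", pc$auc), sep = "\t"), con)
  }
  invisible(path)
}
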