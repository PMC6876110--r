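## Random walk with restart (RWR) over a weighted metabolite network.
##
## Convention: column-stochastic transition matrix W (column j holds the
## out-probabilities of node j, proportional to edge weights); isolated
## nodes are self-absorbing.  The walker iterates
##
##   p <- (1 - r) W p + r p0
##
## with p0 uniform over the seed set, until the L1 change drops below the
## tolerance.  For r > 0 the fixed point is unique:
## p = r (I - (1 - r) W)^{-1} p0.

#' RWR configuration
#'
#' @param restart restart probability `r` in `(0, 1]`; default 0.7
#'   (standard in disease-gene network propagation).
#' @param tolerance L1 convergence tolerance; default 1e-10.
#' @param max_iterations iteration cap; default 10000.
#' @return An object of class `rwr_config`.
#' @export
rwr_config <- function(restart = 0.7, tolerance = 1e-10,
                       max_iterations = 10000L) {
  stopifnot(restart > 0, restart <= 1, tolerance > 0, max_iterations >= 1)
  structure(list(restart = restart, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations)),
            class = "rwr_config")
}

#' Column-stochastic transition matrix of a metabolite network
#'
#' Adjacency weights normalized so every column sums to 1; an isolated
#' node becomes self-absorbing (unit self-transition), keeping the matrix
#' stochastic.
#'
#' @param net a `metabolite_network`.
#' @return a dense column-stochastic matrix with node dimnames.
#' @export
column_normalize <- function(net) {
  nodes <- net$nodes
  stopifnot(length(nodes) > 0L)
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  e <- net$edges
  if (nrow(e)) {
    A[cbind(e$node_a, e$node_b)] <- e$weight
    A[cbind(e$node_b, e$node_a)] <- e$weight
  }
  deg <- colSums(A)
  iso <- deg == 0
  if (any(iso)) {
    A[cbind(which(iso), which(iso))] <- 1
    deg[iso] <- 1
  }
  sweep(A, 2L, deg, "/")
}

#' Random walk with restart scores and ranking
#'
#' Iterates the RWR update from a uniform distribution over `seeds` until
#' the L1 residual falls below the configured tolerance.  Non-seed nodes
#' are ranked by descending stationary score, ties broken by sorted
#' metabolite id.
#'
#' @param net a `metabolite_network`.
#' @param seeds nonempty character vector of seed nodes (all in `net`).
#' @param cfg an [rwr_config()].
#' @return An object of class `rwr_result`: list with `scores` (named
#'   numeric over all nodes, sums to 1), `rank` (named integer over
#'   non-seed nodes, 1 = best), `iterations_used` and `residual`.
#' @export
rwr_scores <- function(net, seeds, cfg = rwr_config()) {
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) stop("rwr_scores: empty seed set")
  unknown <- setdiff(seeds, net$nodes)
  if (length(unknown)) {
    stop("rwr_scores: seed(s) not in network: ",
         paste(utils::head(unknown, 3L), collapse = ", "))
  }
  W <- column_normalize(net)
  p0 <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  p0[seeds] <- 1 / length(seeds)
  r <- cfg$restart
  p <- p0
  iters <- 0L
  repeat {
    p_new <- (1 - r) * as.numeric(W %*% p) + r * p0
    names(p_new) <- names(p0)
    res <- sum(abs(p_new - p))
    p <- p_new
    iters <- iters + 1L
    if (res < cfg$tolerance) break
    if (iters >= cfg$max_iterations) {
      stop("rwr_scores: no convergence after ", iters,
           " iterations (last L1 residual ", format(res), ")")
    }
  }
  non_seed <- setdiff(net$nodes, seeds)
  ord <- non_seed[order(-p[non_seed], non_seed)]
  structure(list(scores = p,
                 rank = stats::setNames(seq_along(ord), ord),
                 iterations_used = iters,
                 residual = res),
            class = "rwr_result")
}

#' @export
print.rwr_result <- function(x, ...) {
  cat(sprintf("<rwr_result: %d nodes, %d ranked, %d iterations (L1 residual %.2e)>\n",
              length(x$scores), length(x$rank), x$iterations_used, x$residual))
  invisible(x)
}

#' Closed-form RWR solution (dense linear solve)
#'
#' Exact fixed point `p = r (I - (1 - r) W)^{-1} p0`, used as an
#' independent oracle for the iterative solver on small networks.
#'
#' @inheritParams rwr_scores
#' @return named numeric vector of stationary scores.
#' @export
rwr_solve_oracle <- function(net, seeds, cfg = rwr_config()) {
  seeds <- unique(as.character(seeds))
  stopifnot(length(seeds) > 0L, all(seeds %in% net$nodes),
            length(net$nodes) <= 2000L)
  W <- column_normalize(net)
  p0 <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  p0[seeds] <- 1 / length(seeds)
  r <- cfg$restart
  p <- r * solve(diag(length(p0)) - (1 - r) * W, p0)
  stats::setNames(as.numeric(p), net$nodes)
}

#' Write an RWR ranking as TSV
#'
#' Columns: `metabolite`, `score`, `rank` (empty for seeds), `is_seed`.
#'
#' @param result an `rwr_result`.
#' @param seeds the seed set used.
#' @param path output path.
#' @param header_lines extra comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_ranking <- function(result, seeds, path, header_lines = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (h in header_lines) writeLines(paste0("# ", h), con)
  writeLines("metabolite\tscore\trank\tis_seed", con)
  ranked <- names(result$rank)
  for (m in ranked) {
    writeLines(paste(m, sprintf("%.15g", result$scores[m]),
                     result$rank[m], "FALSE", sep = "\t"), con)
  }
  for (m in sort(intersect(names(result$scores), seeds))) {
    writeLines(paste(m, sprintf("%.15g", result$scores[m]),
                     "", "TRUE", sep = "\t"), con)
  }
  invisible(path)
}
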