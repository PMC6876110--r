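## Metabolite profile vectors and the disease-associated metabolite
## network (DMN).
##
## Each metabolite m is represented by a |D|-dimensional relevance vector
## over the disease set D.  A dimension scores 1 when the disease is
## directly associated with m, otherwise the maximum similarity from that
## disease to any disease in DR_m (the diseases directly related to m) --
## an item-based collaborative-filtering imputation.  Metabolite-metabolite
## weights are cosine similarities of these vectors; edges at or below the
## threshold are filtered out.

#' Predicted relevance of a disease to a metabolite
#'
#' 1 when `(d, m)` is a direct association; otherwise the maximum
#' normalized disease similarity between `d` and any disease directly
#' associated with `m`.  Undefined (hard error) when `m` has no
#' associated disease.
#'
#' @param d a disease term identifier.
#' @param m a metabolite identifier.
#' @param assoc an [association_table()].
#' @param dsim a `disease_similarity` from [all_pairs_similarity()].
#' @return a score in `[0, 1]`.
#' @export
relevance_score <- function(d, m, assoc, dsim) {
  dr <- metabolite_diseases(assoc)[[m]]
  if (is.null(dr) || length(dr) == 0L) {
    stop("relevance_score: metabolite '", m, "' has no associated disease")
  }
  if (d %in% dr) return(1)
  stopifnot(d %in% dsim$diseases, all(dr %in% dsim$diseases))
  max(dsim$sim[dr, d])
}

#' Build the metabolite profile matrix
#'
#' Dense `|M| x |D|` matrix of relevance scores.  `M` is every metabolite
#' with at least one associated disease (others are excluded with a
#' warning: their relevance is undefined); `D` is the set of diseases
#' appearing in the association table, which all must be covered by the
#' disease similarity matrix.
#'
#' @param assoc an [association_table()].
#' @param dsim a `disease_similarity`.
#' @return An object of class `metabolite_profiles`: list with
#'   `metabolites`, `diseases` and the score matrix `PA` (rows =
#'   metabolites, columns = diseases).
#' @export
build_profiles <- function(assoc, dsim) {
  stopifnot(nrow(assoc$records) > 0L)
  diseases <- sort(unique(assoc$records$disease_id))
  missing <- setdiff(diseases, dsim$diseases)
  if (length(missing)) {
    stop("build_profiles: disease(s) absent from the similarity matrix: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  }
  dr_by_m <- metabolite_diseases(assoc)
  metabolites <- sort(names(dr_by_m)[lengths(dr_by_m) > 0L])
  dropped <- setdiff(names(dr_by_m), metabolites)
  if (length(dropped)) {
    warning("build_profiles: excluded ", length(dropped),
            " metabolite(s) with no associated disease")
  }
  PA <- matrix(0, length(metabolites), length(diseases),
               dimnames = list(metabolites, diseases))
  S <- dsim$sim[diseases, diseases, drop = FALSE]
  for (m in metabolites) {
    dr <- unique(dr_by_m[[m]])
    # max over DR_m rows of the similarity to each candidate disease
    prof <- apply(S[dr, , drop = FALSE], 2L, max)
    prof[dr] <- 1
    PA[m, ] <- prof
  }
  structure(list(metabolites = metabolites, diseases = diseases, PA = PA),
            class = "metabolite_profiles")
}

#' @export
print.metabolite_profiles <- function(x, ...) {
  cat(sprintf("<metabolite_profiles: %d metabolites x %d diseases>\n",
              length(x$metabolites), length(x$diseases)))
  invisible(x)
}

#' Cosine similarity of two nonnegative profile vectors
#'
#' `dot(a, b) / (||a|| ||b||)`; in `[0, 1]` for nonnegative entries.
#' A zero vector is a hard error (cannot occur for retained metabolites,
#' whose own-disease dimensions are 1).
#'
#' @param a,b numeric vectors of identical length.
#' @return a score in `[0, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine_similarity: zero vector")
  min(1, sum(a * b) / (na * nb))   # clamp 1 + eps roundoff
}

#' Build the disease-associated metabolite network (DMN)
#'
#' Computes cosine similarity for every unordered metabolite pair and
#' keeps edges strictly above `threshold` (default 0.01, the value at
#' which the edge-count decline levels off on real association data).
#' All profiled metabolites stay in the node set, so nodes can be
#' isolated.
#'
#' @param profiles a `metabolite_profiles` from [build_profiles()].
#' @param threshold keep edges with similarity `> threshold`; in `[0, 1)`.
#' @return a `metabolite_network` with kind `"DMN"`.
#' @export
build_dmn <- function(profiles, threshold = 0.01) {
  stopifnot(threshold >= 0, threshold < 1)
  PA <- profiles$PA
  # full cosine matrix via normalized cross product
  nrm <- sqrt(rowSums(PA^2))
  if (any(nrm == 0)) stop("build_dmn: zero profile vector")
  C <- tcrossprod(PA / nrm)
  C[C > 1] <- 1
  keep <- which(upper.tri(C) & C > threshold, arr.ind = TRUE)
  edges <- data.frame(
    node_a = rownames(C)[keep[, 1L]],
    node_b = rownames(C)[keep[, 2L]],
    weight = C[keep],
    stringsAsFactors = FALSE)
  metabolite_network(profiles$metabolites, edges, "DMN")
}

#' Write a profile matrix as TSV (metabolite x disease)
#' @param profiles a `metabolite_profiles`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("metabolite_id", profiles$diseases), collapse = "\t"), con)
  for (m in profiles$metabolites) {
    writeLines(paste(c(m, sprintf("%.15g", profiles$PA[m, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a profile matrix TSV written by [write_profiles()]
#' @param path path to the TSV file.
#' @return a `metabolite_profiles`.
#' @export
read_profiles <- function(path) {
  tl <- read_tsv_lines(path)
  header <- strsplit(tl$lines[[1L]], "\t", fixed = TRUE)[[1L]]
  stopifnot(header[1L] == "metabolite_id")
  diseases <- header[-1L]
  parts <- strsplit(tl$lines[-1L], "\t", fixed = TRUE)
  metabolites <- vapply(parts, `[[`, character(1), 1L)
  PA <- t(vapply(parts, function(p) as.numeric(p[-1L]),
                 numeric(length(diseases))))
  dimnames(PA) <- list(metabolites, diseases)
  ord <- order(metabolites)
  structure(list(metabolites = metabolites[ord], diseases = diseases,
                 PA = PA[ord, , drop = FALSE]),
            class = "metabolite_profiles")
}
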