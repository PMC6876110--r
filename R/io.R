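## File formats: OBO flat files for the ontology, tab-separated UTF-8 for
## everything else.  '#' lines are comments.  All writers emit sorted,
## deterministic row order so fixtures diff cleanly.

read_tsv_lines <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

tsv_header_index <- function(fields, required, path) {
  idx <- match(required, fields)
  if (anyNA(idx)) {
    stop("'", path, "': missing required column '",
         required[which(is.na(idx))[1L]], "'")
  }
  idx
}

#' Read an OBO-format ontology file
#'
#' Parses `[Term]` stanzas with `id`, `name`, `synonym` and `is_a` fields
#' into a validated [ontology_dag()].  Obsolete terms (`is_obsolete: true`)
#' are skipped, together with any IS_A links pointing at them.  A cycle or
#' a dangling `is_a` target is a hard error.
#'
#' @param path path to an OBO flat file.
#' @return An [ontology_dag()].
#' @export
read_ontology <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  stanzas <- list()
  cur <- NULL
  in_term <- FALSE
  flush_term <- function() {
    if (!is.null(cur) && !is.null(cur$id)) stanzas[[length(stanzas) + 1L]] <<- cur
  }
  for (line in lines) {
    line <- trimws(line)
    if (line == "[Term]") {
      flush_term()
      cur <- list(); in_term <- TRUE
      next
    }
    if (grepl("^\\[", line)) {       # other stanza type ([Typedef], ...)
      flush_term()
      cur <- NULL; in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(line)) next
    if (startsWith(line, "id:")) {
      cur$id <- trimws(sub("^id:", "", line))
    } else if (startsWith(line, "name:")) {
      cur$name <- trimws(sub("^name:", "", line))
    } else if (startsWith(line, "is_obsolete:")) {
      cur$obsolete <- grepl("true", line, fixed = TRUE)
    } else if (startsWith(line, "is_a:")) {
      target <- trimws(sub("!.*$", "", sub("^is_a:", "", line)))
      cur$is_a <- c(cur$is_a, target)
    } else if (startsWith(line, "synonym:")) {
      m <- regmatches(line, regexpr('"[^"]*"', line))
      if (length(m)) cur$synonyms <- c(cur$synonyms, gsub('"', "", m))
    }
  }
  flush_term()
  if (length(stanzas) == 0L) stop("'", path, "': no [Term] stanzas found")
  obsolete <- vapply(stanzas, function(s) isTRUE(s$obsolete), logical(1))
  obsolete_ids <- vapply(stanzas[obsolete], `[[`, character(1), "id")
  terms <- character(); parents <- list()
  labels <- character(); synonyms <- list()
  for (s in stanzas[!obsolete]) {
    terms <- c(terms, s$id)
    is_a <- setdiff(unique(s$is_a), obsolete_ids)   # links into obsolete: drop
    if (length(is_a)) parents[[s$id]] <- is_a
    if (!is.null(s$name)) labels[[s$id]] <- s$name
    if (length(s$synonyms)) synonyms[[s$id]] <- unique(s$synonyms)
  }
  if (length(terms) == 0L) stop("'", path, "': all terms obsolete")
  ontology_dag(terms, parents, labels, synonyms)
}

#' Write an ontology DAG as an OBO flat file
#' @param dag an [ontology_dag()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(dag, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in sort(dag$terms)) {
    writeLines(c("", "[Term]", paste0("id: ", t)), con)
    if (!is.na(dag$labels[t]) && !is.null(dag$labels[[t]])) {
      writeLines(paste0("name: ", dag$labels[[t]]), con)
    }
    for (s in dag$synonyms[[t]]) {
      writeLines(sprintf('synonym: "%s" EXACT []', s), con)
    }
    for (p in sort(dag$parents[[t]])) {
      writeLines(paste0("is_a: ", p), con)
    }
  }
  invisible(path)
}

#' Read a disease-metabolite association table
#'
#' TSV with a header naming at least `disease_id` and `metabolite_id`.
#' Duplicate rows are collapsed; the record count is reported via `message()`.
#'
#' @param path path to the TSV file.
#' @param version_tag snapshot tag stored on the result.
#' @return An [association_table()].
#' @export
read_association_table <- function(path, version_tag = "") {
  tl <- read_tsv_lines(path)
  if (length(tl$lines) == 0L) stop("'", path, "': empty file (no header)")
  fields <- strsplit(tl$lines[[1L]], "\t", fixed = TRUE)[[1L]]
  idx <- tsv_header_index(fields, c("disease_id", "metabolite_id"), path)
  body <- tl$lines[-1L]
  if (length(body) == 0L) {
    out <- association_table(data.frame(disease_id = character(),
                                        metabolite_id = character()),
                             version_tag)
    message("read_association_table: 0 records from '", path, "'")
    return(out)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  df <- data.frame(
    disease_id = vapply(parts, `[[`, character(1), idx[1L]),
    metabolite_id = vapply(parts, `[[`, character(1), idx[2L]),
    stringsAsFactors = FALSE)
  out <- association_table(df, version_tag)
  message("read_association_table: ", nrow(out$records), " records (",
          length(body) - nrow(out$records), " duplicates collapsed) from '",
          path, "'")
  out
}

#' Write an association table
#' @param assoc an [association_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(assoc, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# version_tag: ", assoc$version_tag), con)
  writeLines("disease_id\tmetabolite_id", con)
  writeLines(paste(assoc$records$disease_id, assoc$records$metabolite_id,
                   sep = "\t"), con)
  invisible(path)
}

#' Read a weighted edge list
#'
#' TSV with header columns `node_a`, `node_b`, `weight`.  Weights must
#' parse as decimals in `[0, 1]` after optional rescaling (`scale`,
#' e.g. `1000` for raw STITCH channel scores stored as 0-1000 integers).
#' Self-loop rows are skipped with a warning.  A pair appearing twice with
#' different weights is a hard error; identical repeats collapse silently.
#'
#' @param path path to the TSV file.
#' @param kind what the edges represent: `"gene"` (a [gene_network()]),
#'   `"textmining"` (a [textmining_scores()]) or `"metabolite"`
#'   (a [metabolite_network()]).
#' @param scale divide raw weights by this on ingest (default 1).
#' @param metabolite_kind passed to [metabolite_network()] when
#'   `kind = "metabolite"`.
#' @return A `gene_network`, `textmining_scores` or `metabolite_network`.
#' @export
read_weighted_edges <- function(path, kind = c("gene", "textmining", "metabolite"),
                                scale = 1, metabolite_kind = "DMN") {
  kind <- match.arg(kind)
  tl <- read_tsv_lines(path)
  if (length(tl$lines) == 0L) stop("'", path, "': empty file (no header)")
  fields <- strsplit(tl$lines[[1L]], "\t", fixed = TRUE)[[1L]]
  idx <- tsv_header_index(fields, c("node_a", "node_b", "weight"), path)
  body <- tl$lines[-1L]
  lineno <- tl$lineno[-1L]
  a <- character(0); b <- character(0); w <- numeric(0)
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    a <- vapply(parts, `[[`, character(1), idx[1L])
    b <- vapply(parts, `[[`, character(1), idx[2L])
    wraw <- vapply(parts, `[[`, character(1), idx[3L])
    w <- suppressWarnings(as.numeric(wraw)) / scale
    bad <- which(is.na(w) | w < 0 | w > 1)
    if (length(bad)) {
      stop("'", path, "' line ", lineno[bad[1L]], ": weight '",
           wraw[bad[1L]], "' is not a decimal in [0,1]",
           if (scale != 1) paste0(" after /", scale) else "")
    }
    self <- a == b
    if (any(self)) {
      warning("'", path, "': skipped ", sum(self), " self-loop row(s) (first at line ",
              lineno[self][1L], ")")
      a <- a[!self]; b <- b[!self]; w <- w[!self]
    }
    key <- pair_key(a, b)
    if (anyDuplicated(key)) {
      for (k in unique(key[duplicated(key)])) {
        ws <- w[key == k]
        if (length(unique(ws)) > 1L) {
          stop("'", path, "': conflicting weights for pair '",
               gsub("\t", " -- ", k), "': ",
               paste(unique(ws), collapse = " vs "))
        }
      }
      first <- !duplicated(key)
      a <- a[first]; b <- b[first]; w <- w[first]
    }
  }
  df <- data.frame(node_a = a, node_b = b, weight = w, stringsAsFactors = FALSE)
  switch(kind,
         gene = gene_network(df),
         textmining = textmining_scores(df),
         metabolite = metabolite_network(character(), df, metabolite_kind))
}

#' Write a weighted edge list
#'
#' Emits a deterministic sorted TSV; weights are serialized with 15
#' significant digits so a write/read round trip is exact.  For a
#' `metabolite_network` the full node set (including isolated nodes) is
#' recorded in `# node:` comment lines so round trips preserve it.
#'
#' @param x a `gene_network`, `textmining_scores` or `metabolite_network`.
#' @param path output path.
#' @param header_lines extra comment lines (without `#`) to prepend.
#' @return `path`, invisibly.
#' @export
write_weighted_edges <- function(x, path, header_lines = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (h in header_lines) writeLines(paste0("# ", h), con)
  if (inherits(x, "metabolite_network")) {
    writeLines(paste0("# kind: ", x$kind), con)
    isolated <- setdiff(x$nodes, c(x$edges$node_a, x$edges$node_b))
    for (n in isolated) writeLines(paste0("# node: ", n), con)
  }
  writeLines("node_a\tnode_b\tweight", con)
  if (nrow(x$edges)) {
    writeLines(paste(x$edges$node_a, x$edges$node_b,
                     sprintf("%.15g", x$edges$weight),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a metabolite network written by [write_weighted_edges()]
#'
#' Restores the `kind` tag and isolated nodes from the comment header.
#'
#' @param path path to the TSV file.
#' @return A `metabolite_network`.
#' @export
read_metabolite_network <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  kind_line <- grep("^# kind: ", lines, value = TRUE)
  kind <- if (length(kind_line)) sub("^# kind: ", "", kind_line[1L]) else "DMN"
  iso <- sub("^# node: ", "", grep("^# node: ", lines, value = TRUE))
  net <- read_weighted_edges(path, kind = "metabolite", metabolite_kind = kind)
  metabolite_network(c(net$nodes, iso), net$edges, kind)
}

#' Read a disease-to-gene annotation TSV
#'
#' TSV with header columns `disease_id`, `gene_id`, one gene per row.
#'
#' @param path path to the TSV file.
#' @return A [gene_annotation()].
#' @export
read_gene_annotation <- function(path) {
  tl <- read_tsv_lines(path)
  if (length(tl$lines) == 0L) stop("'", path, "': empty file (no header)")
  fields <- strsplit(tl$lines[[1L]], "\t", fixed = TRUE)[[1L]]
  idx <- tsv_header_index(fields, c("disease_id", "gene_id"), path)
  body <- tl$lines[-1L]
  if (length(body) == 0L) return(gene_annotation(list()))
  parts <- strsplit(body, "\t", fixed = TRUE)
  d <- vapply(parts, `[[`, character(1), idx[1L])
  g <- vapply(parts, `[[`, character(1), idx[2L])
  gene_annotation(split(g, d))
}

#' Write a gene annotation TSV
#' @param ann a [gene_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(ann, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("disease_id\tgene_id", con)
  for (d in sort(names(ann$disease2genes))) {
    for (g in ann$disease2genes[[d]]) writeLines(paste(d, g, sep = "\t"), con)
  }
  invisible(path)
}
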