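#' Normalize a disease name
#'
#' Lowercases, replaces runs of punctuation/whitespace with single spaces
#' and trims.  The transform is idempotent, so vocabulary keys and query
#' names normalize to the same representative.
#'
#' @param raw character vector of raw names.
#' @return character vector of normalized names.
#' @export
normalize_name <- function(raw) {
  x <- tolower(as.character(raw))
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}

#' Build a combined disease-name vocabulary
#'
#' Unions ontology primary names and synonyms with MEDIC-style names and
#' synonyms, all keyed by normalized name.  A name carried by several
#' ontology terms stays ambiguous: the key maps to the full term set.
#' MEDIC rows referencing a term absent from the DAG are skipped with a
#' warning.
#'
#' @param dag an [ontology_dag()].
#' @param medic optional data.frame with columns `DiseaseName`,
#'   `Synonyms` (pipe-separated, may be empty) and `DOxref` (the ontology
#'   term the entry maps to).
#' @return An object of class `combined_vocabulary` with elements
#'   `name2term` (named list: normalized name -> character vector of terms)
#'   and `provenance` (named list: normalized name -> source tags).
#' @export
build_vocabulary <- function(dag, medic = NULL) {
  name2term <- list()
  provenance <- list()
  add <- function(name, term, source) {
    key <- normalize_name(name)
    if (!nzchar(key)) return()
    name2term[[key]] <<- sort(unique(c(name2term[[key]], term)))
    provenance[[key]] <<- sort(unique(c(provenance[[key]], source)))
  }
  for (t in dag$terms) {
    if (!is.null(dag$labels[[t]])) add(dag$labels[[t]], t, "DO_NAME")
    for (s in dag$synonyms[[t]]) add(s, t, "DO_SYNONYM")
  }
  if (!is.null(medic) && nrow(medic)) {
    stopifnot(all(c("DiseaseName", "DOxref") %in% names(medic)))
    skipped <- 0L
    for (i in seq_len(nrow(medic))) {
      term <- as.character(medic$DOxref[i])
      if (!term %in% dag$terms) {
        skipped <- skipped + 1L
        next
      }
      add(medic$DiseaseName[i], term, "MEDIC_NAME")
      syn <- medic$Synonyms[i]
      if (!is.null(syn) && !is.na(syn) && nzchar(syn)) {
        for (s in strsplit(as.character(syn), "|", fixed = TRUE)[[1L]]) {
          if (nzchar(trimws(s))) add(s, term, "MEDIC_SYNONYM")
        }
      }
    }
    if (skipped) {
      warning("build_vocabulary: skipped ", skipped,
              " MEDIC row(s) referencing unknown ontology terms")
    }
  }
  structure(list(name2term = name2term, provenance = provenance),
            class = "combined_vocabulary")
}

#' Read a MEDIC-style vocabulary TSV
#'
#' TSV with header columns `DiseaseName`, `Synonyms` (pipe-separated,
#' possibly empty) and `DOxref`.
#'
#' @param path path to the TSV file.
#' @return data.frame suitable for [build_vocabulary()].
#' @export
read_medic <- function(path) {
  tl <- read_tsv_lines(path)
  if (length(tl$lines) == 0L) stop("'", path, "': empty file (no header)")
  fields <- strsplit(tl$lines[[1L]], "\t", fixed = TRUE)[[1L]]
  idx <- tsv_header_index(fields, c("DiseaseName", "Synonyms", "DOxref"), path)
  body <- tl$lines[-1L]
  if (length(body) == 0L) {
    return(data.frame(DiseaseName = character(), Synonyms = character(),
                      DOxref = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  pick <- function(p, i) if (length(p) >= i) p[[i]] else ""
  data.frame(
    DiseaseName = vapply(parts, pick, character(1), idx[1L]),
    Synonyms = vapply(parts, pick, character(1), idx[2L]),
    DOxref = vapply(parts, pick, character(1), idx[3L]),
    stringsAsFactors = FALSE)
}

#' Map free-text disease names to ontology terms
#'
#' Resolves each (disease name, metabolite) row against the combined
#' vocabulary by exact match on normalized names.  Names that resolve to a
#' single term become association records.  Ambiguous names (one name,
#' several terms) are handled per `ambiguity`: `"drop"` discards them
#' (reported), `"first"` picks the lexicographically smallest term id.
#' Unmatched names land in the unmapped report.  Mapping failure is data,
#' not an error.
#'
#' @param raw data.frame with columns `disease_name`, `metabolite_id`.
#' @param vocab a `combined_vocabulary` from [build_vocabulary()].
#' @param ambiguity `"drop"` (default) or `"first"`.
#' @param version_tag tag for the resulting [association_table()].
#' @return list with elements `assoc` ([association_table()]),
#'   `unmapped` (data.frame: disease_name, metabolite_id),
#'   `ambiguous` (data.frame: disease_name, metabolite_id, candidate_terms).
#' @export
map_associations <- function(raw, vocab, ambiguity = c("drop", "first"),
                             version_tag = "") {
  ambiguity <- match.arg(ambiguity)
  stopifnot(all(c("disease_name", "metabolite_id") %in% names(raw)))
  raw <- unique(data.frame(disease_name = as.character(raw$disease_name),
                           metabolite_id = as.character(raw$metabolite_id),
                           stringsAsFactors = FALSE))
  mapped <- list()
  unmapped <- list()
  ambiguous <- list()
  for (i in seq_len(nrow(raw))) {
    key <- normalize_name(raw$disease_name[i])
    terms <- vocab$name2term[[key]]
    if (is.null(terms)) {
      unmapped[[length(unmapped) + 1L]] <- raw[i, , drop = FALSE]
    } else if (length(terms) == 1L || ambiguity == "first") {
      mapped[[length(mapped) + 1L]] <- data.frame(
        disease_id = sort(terms)[1L],
        metabolite_id = raw$metabolite_id[i],
        stringsAsFactors = FALSE)
      if (length(terms) > 1L) {
        ambiguous[[length(ambiguous) + 1L]] <- data.frame(
          disease_name = raw$disease_name[i],
          metabolite_id = raw$metabolite_id[i],
          candidate_terms = paste(terms, collapse = "|"),
          stringsAsFactors = FALSE)
      }
    } else {
      ambiguous[[length(ambiguous) + 1L]] <- data.frame(
        disease_name = raw$disease_name[i],
        metabolite_id = raw$metabolite_id[i],
        candidate_terms = paste(terms, collapse = "|"),
        stringsAsFactors = FALSE)
    }
  }
  bind <- function(lst, proto) {
    if (length(lst)) do.call(rbind, lst) else proto
  }
  list(
    assoc = association_table(
      bind(mapped, data.frame(disease_id = character(),
                              metabolite_id = character())),
      version_tag),
    unmapped = bind(unmapped, data.frame(disease_name = character(),
                                         metabolite_id = character())),
    ambiguous = bind(ambiguous, data.frame(disease_name = character(),
                                           metabolite_id = character(),
                                           candidate_terms = character())))
}
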