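## End-to-end pipeline: vocabulary mapping -> disease similarity ->
## profile matrix -> DMN -> FLDMN fusion -> ranking / two-snapshot
## evaluation, with provenance headers on every artifact.

#' Pipeline configuration
#'
#' Collects all stage inputs/outputs and tunables.  Defaults reproduce
#' the reference parameterization: edge threshold 0.01, restart
#' probability 0.7.
#'
#' @param ontology,gene_annotation,gene_network,assoc_earlier paths to the
#'   required inputs (OBO / TSV, see the reader documentation).
#' @param out_dir output directory.
#' @param assoc_later optional later-snapshot TSV; enables evaluation.
#' @param stitch optional text-mining TSV; enables fusion.
#' @param medic,assoc_earlier_names optional MEDIC vocabulary TSV plus a
#'   name-keyed association TSV (`disease_name`, `metabolite_id`); when
#'   both are given the earlier snapshot is produced by vocabulary
#'   mapping instead of being read id-keyed.
#' @param seeds optional character vector of seed metabolites for a
#'   ranking run.
#' @param threshold DMN edge threshold (default 0.01).
#' @param restart,tolerance,max_iterations RWR parameters.
#' @param stitch_scale divide raw text-mining scores by this (e.g. 1000).
#' @param normalization_mode disease-similarity normalization
#'   (`"max"`/`"none"`).
#' @param ambiguity_policy name-mapping ambiguity policy
#'   (`"drop"`/`"first"`).
#' @param no_fusion evaluate/rank the bare DMN even when `stitch` is set.
#' @return An object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(ontology, gene_annotation, gene_network,
                            assoc_earlier, out_dir,
                            assoc_later = NULL, stitch = NULL,
                            medic = NULL, assoc_earlier_names = NULL,
                            seeds = NULL,
                            threshold = 0.01, restart = 0.7,
                            tolerance = 1e-10, max_iterations = 10000L,
                            stitch_scale = 1,
                            normalization_mode = "max",
                            ambiguity_policy = "drop",
                            no_fusion = FALSE) {
  cfg <- list(ontology = ontology, gene_annotation = gene_annotation,
              gene_network = gene_network, assoc_earlier = assoc_earlier,
              out_dir = out_dir, assoc_later = assoc_later, stitch = stitch,
              medic = medic, assoc_earlier_names = assoc_earlier_names,
              seeds = seeds, threshold = threshold, restart = restart,
              tolerance = tolerance, max_iterations = as.integer(max_iterations),
              stitch_scale = stitch_scale,
              normalization_mode = normalization_mode,
              ambiguity_policy = ambiguity_policy, no_fusion = isTRUE(no_fusion))
  stopifnot(threshold >= 0, threshold < 1, restart > 0, restart <= 1)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path path to a YAML file whose keys match [pipeline_config()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

## Provenance header lines: config echo + md5 of every input file.
provenance_header <- function(cfg) {
  scalar <- vapply(cfg, function(v) {
    if (is.null(v)) "NULL" else paste(as.character(v), collapse = ",")
  }, character(1))
  cfg_lines <- paste0("cfg ", names(scalar), ": ", scalar)
  inputs <- c(cfg$ontology, cfg$gene_annotation, cfg$gene_network,
              cfg$assoc_earlier, cfg$assoc_later, cfg$stitch, cfg$medic,
              cfg$assoc_earlier_names)
  inputs <- inputs[!is.null(inputs) & file.exists(inputs)]
  md5 <- tools::md5sum(inputs)
  c(paste0("tool: metabonet ",
           as.character(utils::packageVersion("metabonet"))),
    cfg_lines,
    paste0("input md5 ", names(md5), ": ", md5))
}

#' Run the full pipeline
#'
#' Stages: (1) load inputs (optionally mapping free-text disease names
#' through the combined vocabulary); (2) all-pairs disease similarity
#' over the diseases of the earlier snapshot; (3) profile matrix and DMN
#' at the configured threshold; (4) noisy-OR fusion with text-mining
#' scores when available; (5) RWR ranking for a seed set and/or the
#' two-snapshot evaluation when a later snapshot is given.  Every output
#' carries a provenance header (tool version, config echo, input md5s).
#' Identical inputs and config produce byte-identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list of the key in-memory artifacts (`dsim`,
#'   `profiles`, `dmn`, `net`, `ranking`, `report`) plus `paths` of the
#'   written files.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_header(cfg)
  paths <- list()

  dag <- stage("read-ontology", read_ontology(cfg$ontology))
  ann <- stage("read-annotation", read_gene_annotation(cfg$gene_annotation))
  gnet <- stage("read-gene-network", read_weighted_edges(cfg$gene_network, "gene"))

  if (!is.null(cfg$medic) && !is.null(cfg$assoc_earlier_names)) {
    earlier <- stage("map", {
      medic <- read_medic(cfg$medic)
      vocab <- build_vocabulary(dag, medic)
      raw <- utils::read.delim(cfg$assoc_earlier_names, sep = "\t",
                               comment.char = "#", stringsAsFactors = FALSE)
      mapped <- map_associations(raw, vocab, ambiguity = cfg$ambiguity_policy,
                                 version_tag = "earlier")
      paths$unmapped <- file.path(cfg$out_dir, "unmapped.tsv")
      utils::write.table(mapped$unmapped, paths$unmapped, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      mapped$assoc
    })
  } else {
    earlier <- stage("read-associations",
                     read_association_table(cfg$assoc_earlier, "earlier"))
  }
  if (nrow(earlier$records) == 0L) stop("pipeline: earlier snapshot is empty")

  dsim <- stage("dsim", {
    diseases <- sort(unique(earlier$records$disease_id))
    missing <- setdiff(diseases, dag$terms)
    if (length(missing)) {
      stop("association disease(s) absent from the ontology: ",
           paste(utils::head(missing, 3L), collapse = ", "))
    }
    all_pairs_similarity(diseases, dag, ann, gnet,
                         normalize = cfg$normalization_mode)
  })
  paths$dsim <- file.path(cfg$out_dir, "disease_similarity.tsv")
  write_disease_similarity(dsim, paths$dsim)

  profiles <- stage("profiles", build_profiles(earlier, dsim))
  paths$profiles <- file.path(cfg$out_dir, "profiles.tsv")
  write_profiles(profiles, paths$profiles)

  dmn <- stage("build-dmn", build_dmn(profiles, cfg$threshold))
  paths$dmn <- file.path(cfg$out_dir, "dmn.tsv")
  write_weighted_edges(dmn, paths$dmn, hdr)

  net <- dmn
  if (!is.null(cfg$stitch) && !cfg$no_fusion) {
    net <- stage("fuse", {
      st <- read_weighted_edges(cfg$stitch, "textmining",
                                scale = cfg$stitch_scale)
      build_fldmn(dmn, st)
    })
    paths$fldmn <- file.path(cfg$out_dir, "fldmn.tsv")
    write_weighted_edges(net, paths$fldmn, hdr)
  }

  cfg_rwr <- rwr_config(cfg$restart, cfg$tolerance, cfg$max_iterations)
  ranking <- NULL
  if (!is.null(cfg$seeds)) {
    ranking <- stage("rank", rwr_scores(net, cfg$seeds, cfg_rwr))
    paths$ranking <- file.path(cfg$out_dir, "ranking.tsv")
    write_ranking(ranking, cfg$seeds, paths$ranking, hdr)
  }
  report <- NULL
  if (!is.null(cfg$assoc_later)) {
    report <- stage("evaluate", {
      later <- read_association_table(cfg$assoc_later, "later")
      cases <- build_validation_cases(earlier, later, net)
      if (length(cases) == 0L) stop("no evaluable disease cases")
      evaluate_network(net, cases, cfg_rwr)
    })
    paths$report <- file.path(cfg$out_dir, "evaluation.tsv")
    write_evaluation_report(report, paths$report, hdr)
  }
  invisible(list(dsim = dsim, profiles = profiles, dmn = dmn, net = net,
                 ranking = ranking, report = report, paths = paths))
}
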