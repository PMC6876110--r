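obo_text <- function(...) {
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(c(...), path)
  path
}

test_that("read_ontology parses chains, synonyms and obsolete terms", {
  p <- obo_text(
    "[Term]", "id: a", "name: alpha",
    "", "[Term]", "id: b", "name: beta", "is_a: a ! alpha",
    "", "[Term]", "id: c", 'synonym: "gamma one" EXACT []',
    'synonym: "gamma two" RELATED []', "is_a: b",
    "", "[Term]", "id: old", "is_a: a", "is_obsolete: true",
    "", "[Term]", "id: d", "is_a: old", "is_a: a")
  dag <- read_ontology(p)
  expect_setequal(dag$terms, c("a", "b", "c", "d"))
  expect_equal(ontology_roots(dag), "a")
  expect_equal(ontology_ancestors(dag, "c"), c("a", "b", "c"))
  expect_length(dag$synonyms[["c"]], 2L)        # both synonym lines kept
  expect_equal(dag$parents[["d"]], "a")         # link to obsolete dropped
})

test_that("read_ontology rejects cycles and dangling is_a targets", {
  cyc <- obo_text("[Term]", "id: a", "is_a: b",
                  "", "[Term]", "id: b", "is_a: a")
  expect_error(read_ontology(cyc), "cycle")
  dangling <- obo_text("[Term]", "id: a", "is_a: ghost")
  expect_error(read_ontology(dangling), "ghost")
})

test_that("ontology round-trips through write_ontology", {
  dag <- generate_worked_example()$objects$dag
  p <- withr::local_tempfile(fileext = ".obo")
  write_ontology(dag, p)
  dag2 <- read_ontology(p)
  expect_setequal(dag2$terms, dag$terms)
  expect_equal(dag2$parents[sort(names(dag2$parents))],
               lapply(dag$parents[sort(names(dag$parents))], sort))
  expect_equal(ontology_roots(dag2), "WD:ROOT")
})

test_that("read_association_table dedups, handles empty input, validates header", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("disease_id\tmetabolite_id",
               "d1\tm1", "d1\tm2", "d2\tm1", "d1\tm1", "d3\tm3"), p)
  at <- suppressMessages(read_association_table(p, "v1"))
  expect_equal(nrow(at$records), 4L)
  expect_equal(at$version_tag, "v1")

  writeLines("disease_id\tmetabolite_id", p)
  expect_equal(nrow(suppressMessages(read_association_table(p))$records), 0L)

  writeLines(c("disease\tmetabolite_id", "d1\tm1"), p)
  expect_error(read_association_table(p), "disease_id")
})

test_that("a generated association table of known size reads back in full", {
  n <- 1406L
  df <- data.frame(disease_id = sprintf("d%03d", ((seq_len(n) - 1L) %% 250L) + 1L),
                   metabolite_id = sprintf("m%04d", seq_len(n)))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_association_table(association_table(df, "gen"), p)
  at <- suppressMessages(read_association_table(p, "gen"))
  expect_equal(nrow(at$records), n)
})

test_that("read_weighted_edges collapses symmetry, skips self-loops, flags conflicts", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node_a\tnode_b\tweight", "a\tb\t0.5", "b\ta\t0.5"), p)
  net <- read_weighted_edges(p, "gene")
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 0.5)

  writeLines(c("node_a\tnode_b\tweight", "a\ta\t0.3", "a\tb\t0.2"), p)
  expect_warning(net <- read_weighted_edges(p, "gene"), "self-loop")
  expect_equal(nrow(net$edges), 1L)

  writeLines(c("node_a\tnode_b\tweight", "a\tb\t0.5", "b\ta\t0.6"), p)
  expect_error(read_weighted_edges(p, "gene"), "conflicting")

  writeLines(c("node_a\tnode_b\tweight", "a\tb\t0.5", "b\tc\t1.5"), p)
  expect_error(read_weighted_edges(p, "gene"), "line 3")

  writeLines(c("node_a\tnode_b\tweight", "a\tb\t500"), p)
  st <- read_weighted_edges(p, "textmining", scale = 1000)
  expect_equal(st$edges$weight, 0.5)
})

test_that("metabolite networks round-trip exactly, isolated nodes included", {
  set.seed(42)
  for (rep in 1:5) {
    net <- rand_metabolite_net(12, 0.3)
    net <- metabolite_network(c(net$nodes, "isolated_x"), net$edges, "FLDMN")
    p <- withr::local_tempfile(fileext = ".tsv")
    write_weighted_edges(net, p)
    back <- read_metabolite_network(p)
    expect_identical(back$kind, "FLDMN")
    expect_identical(back$nodes, net$nodes)
    expect_identical(back$edges$node_a, net$edges$node_a)
    expect_identical(back$edges$weight, net$edges$weight)  # exact round trip
  }
})

test_that("readers reject their own output after weight corruption", {
  set.seed(7)
  net <- rand_metabolite_net(8, 0.5)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_weighted_edges(net, p)
  lines <- readLines(p)
  i <- grep("\t", lines)[2L]   # first data row (after header)
  lines[i] <- sub("\t[0-9.]+$", "\t1.5", lines[i])
  writeLines(lines, p)
  expect_error(read_metabolite_network(p), "\\[0,1\\]")
})

test_that("constructors enforce their invariants", {
  expect_error(metabolite_network("a", data.frame(node_a = "a", node_b = "a",
                                                  weight = 0.5)), "self-loop")
  expect_error(gene_network(data.frame(node_a = "a", node_b = "b",
                                       weight = 1.2)), "\\[0,1\\]")
  expect_error(metabolite_network("a", data.frame(node_a = "a", node_b = "b",
                                                  weight = 0)), "\\(0,1\\]")
  expect_error(ontology_dag(c("a", "b"),
                            list(a = "b", b = "a")), "cycle")
  expect_error(ontology_dag("a", list(a = "zz")), "zz")
})
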