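test_that("auc_score matches hand-enumerated pair counts", {
  pool <- c("p1", "p2", "n1", "n2")
  # positives {0.9, 0.4} vs negatives {0.6, 0.1}: 3 concordant of 4 pairs
  s <- c(p1 = 0.9, p2 = 0.4, n1 = 0.6, n2 = 0.1)
  expect_equal(auc_score(s, c("p1", "p2"), pool), 0.75)
  # perfect separation
  expect_equal(auc_score(c(p1 = 1, p2 = 0.9, n1 = 0.5, n2 = 0), c("p1", "p2"),
                         pool), 1)
  # pure ties
  expect_equal(auc_score(c(p1 = 1, p2 = 1, n1 = 1, n2 = 1), c("p1", "p2"),
                         pool), 0.5)
  expect_error(auc_score(s, character(), pool), "positive")
  expect_error(auc_score(s, pool, pool), "negative")
})

test_that("auc_score equals the all-pairs counting oracle, ties included", {
  set.seed(111)
  for (rep in 1:100) {
    n <- sample(5:25, 1)
    # coarse grid forces ties
    scores <- setNames(sample(seq(0, 1, 0.1), n, replace = TRUE),
                       sprintf("x%02d", seq_len(n)))
    np <- sample.int(n - 1L, 1)
    pos <- names(scores)[seq_len(np)]
    neg <- setdiff(names(scores), pos)
    expect_identical(auc_score(scores, pos, names(scores)),
                     ora_auc(scores[pos], scores[neg]))
  }
})

test_that("auc_score is invariant under strictly monotone transforms", {
  set.seed(121)
  scores <- setNames(runif(20), sprintf("x%02d", 1:20))
  pos <- names(scores)[1:6]
  base <- auc_score(scores, pos, names(scores))
  expect_equal(auc_score(exp(4 * scores), pos, names(scores)), base)
  expect_equal(auc_score(rank(scores), pos, names(scores)), base)
})

test_that("build_validation_cases extracts the snapshot delta", {
  net <- metabolite_network(c("m1", "m2", "m3", "m4"),
                            data.frame(node_a = "m1", node_b = "m2",
                                       weight = 0.5), "DMN")
  earlier <- association_table(data.frame(
    disease_id = c("d1", "d2"), metabolite_id = c("m1", "m2")), "earlier")
  # identical snapshots: no cases
  expect_length(suppressMessages(
    build_validation_cases(earlier, earlier, net)), 0L)
  # d1 gains m3 (a node) and mX (not a node): one case, one positive
  later <- association_table(rbind(earlier$records, data.frame(
    disease_id = c("d1", "d1", "d9"),
    metabolite_id = c("m3", "mX", "m4"))), "later")
  cases <- suppressMessages(build_validation_cases(earlier, later, net))
  expect_length(cases, 1L)   # d9 skipped: present only in later, no seeds
  expect_equal(cases[[1]]$disease, "d1")
  expect_equal(cases[[1]]$seed_metabolites, "m1")
  expect_equal(cases[[1]]$positive_metabolites, "m3")
  expect_setequal(cases[[1]]$candidate_pool, c("m2", "m3", "m4"))
  # invariants
  expect_true(all(cases[[1]]$positive_metabolites %in%
                    cases[[1]]$candidate_pool))
  expect_length(intersect(cases[[1]]$seed_metabolites,
                          cases[[1]]$positive_metabolites), 0L)
})

test_that("evaluate_network scores planted cases and is deterministic", {
  # single case whose positive is the seed's only strong neighbour
  net <- metabolite_network(
    character(),
    data.frame(node_a = c("s", "s", "a"), node_b = c("p", "a", "b"),
               weight = c(0.9, 0.05, 0.6)), "DMN")
  case <- structure(list(disease = "d", seed_metabolites = "s",
                         positive_metabolites = "p",
                         candidate_pool = c("p", "a", "b")),
                    class = "validation_case")
  rep1 <- evaluate_network(net, list(case))
  expect_equal(rep1$mean_auc, 1)
  expect_equal(rep1$per_case$n_pool, 3L)
  rep2 <- evaluate_network(net, list(case))
  expect_identical(rep1, rep2)
})

test_that("random networks with random positives give chance-level AUC", {
  set.seed(131)
  aucs <- replicate(60, {
    net <- rand_metabolite_net(15, 0.4)
    seeds <- sample(net$nodes, 2)
    pos <- sample(setdiff(net$nodes, seeds), 3)
    case <- structure(list(disease = "d", seed_metabolites = seeds,
                           positive_metabolites = pos,
                           candidate_pool = setdiff(net$nodes, seeds)),
                      class = "validation_case")
    evaluate_network(net, list(case))$mean_auc
  })
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("metabolite-seeded evaluation favours direct strong neighbours", {
  net <- metabolite_network(
    character(),
    data.frame(node_a = c("t", "t", "t", "a"),
               node_b = c("a", "b", "c", "d"),
               weight = c(0.95, 0.9, 0.1, 0.2)), "DMN")
  expect_equal(metabolite_seed_evaluation(net, "t", c("a", "b")), 1)
})

test_that("metabolite_seed_evaluation edge cases", {
  # single-edge graph plus one isolated node, the neighbour is the positive
  tiny <- metabolite_network(c("t", "u", "v"),
                             data.frame(node_a = "t", node_b = "u",
                                        weight = 0.5), "DMN")
  expect_equal(metabolite_seed_evaluation(tiny, "t", "u"), 1)
  expect_error(metabolite_seed_evaluation(tiny, "t", "zz"), "co-associated")
})

test_that("threshold_sweep reduces to evaluate_network and reports empties", {
  fx <- generate_fixture(fixture_spec(n_diseases = 6, n_metabolites = 20,
                                      n_genes = 18, snapshot_delta = 6,
                                      seed = 9))
  o <- fx$objects
  ds <- suppressWarnings(all_pairs_similarity(
    sort(unique(o$earlier$records$disease_id)), o$dag, o$ann, o$gnet))
  profiles <- build_profiles(o$earlier, ds)
  dmn <- build_dmn(profiles, 0.01)
  cases <- suppressMessages(build_validation_cases(o$earlier, o$later, dmn))
  expect_gt(length(cases), 0L)
  single <- threshold_sweep(profiles, 0.01, cases)
  expect_equal(single$mean_auc, evaluate_network(dmn, cases)$mean_auc)
  expect_equal(single$n_edges, nrow(dmn$edges))
  # a threshold so high the network loses (almost) all edges: since the
  # node set is retained, an edgeless network degenerates to pure ties
  sweep2 <- threshold_sweep(profiles, c(0.01, 0.999999), cases)
  expect_lte(sweep2$n_edges[2], sweep2$n_edges[1])
  if (sweep2$n_edges[2] == 0L) expect_equal(sweep2$mean_auc[2], 0.5)
})
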