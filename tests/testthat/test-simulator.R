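test_that("simulation is seed-deterministic", {
  s <- doubling_schedule(c(0.3, 0.6), M1 = 5)
  t1 <- simulate_schedule(s, seed = 11)
  t2 <- simulate_schedule(s, seed = 11)
  expect_identical(tibble::as_tibble(t1), tibble::as_tibble(t2))
  expect_identical(tibble::as_tibble(count_pairs(t1)),
                   tibble::as_tibble(count_pairs(t2)))
  t3 <- simulate_schedule(s, seed = 12)
  expect_false(identical(tibble::as_tibble(t1), tibble::as_tibble(t3)))

  sims1 <- simulate_pair_counts(s, n_rep = 50, seed = 3)
  sims2 <- simulate_pair_counts(s, n_rep = 50, seed = 3)
  expect_identical(sims1, sims2)
})

test_that("deterministic survival gives complete r-ary trees", {
  # complete binary tree over two doublings: M_n = 4, N_1 = 4, N_2 = 2
  sch <- event_schedule(1, wgd_event(10, c(0, 0, 1)), wgd_event(5, c(0, 0, 1)))
  cp <- count_pairs(simulate_schedule(sch, seed = 1))
  expect_equal(cp$expected_pairs, c(4L, 2L))
  expect_equal(total_genes(cp), 4)
  expect_equal(unpaired_count(cp), 0)

  # tripling: 3^2 leaves
  sch3 <- event_schedule(2, wgd_event(10, c(0, 0, 0, 1)), wgd_event(5, c(0, 0, 0, 1)))
  cp3 <- count_pairs(simulate_schedule(sch3, seed = 1))
  expect_equal(total_genes(cp3), 2 * 9)
  expect_equal(sum(cp3$expected_pairs), 2 * choose(9, 2))

  # extinction after one generation
  sch0 <- event_schedule(3, wgd_event(10, c(1, 0, 0)))
  cp0 <- count_pairs(simulate_schedule(sch0, seed = 1))
  expect_equal(total_genes(cp0), 0)
  expect_equal(cp0$expected_pairs, 0L)

  # single lineage throughout: no pairs, one unpaired gene
  sch1 <- event_schedule(1, wgd_event(10, c(0, 1, 0)))
  cp1 <- count_pairs(simulate_schedule(sch1, seed = 1))
  expect_equal(cp1$expected_pairs, 0L)
  expect_equal(unpaired_count(cp1), 1)
})

test_that("replicate means agree with closed-form expectations", {
  sch <- event_schedule(2, wgd_event(100, u2_dist(0.35)),
                        wgd_event(40, u3_dist(0.25, 0.06)))
  sims <- simulate_pair_counts(sch, n_rep = 30000, seed = 5)
  ep <- expected_paralog_pairs(sch)
  for (i in ep$origin_event) {
    x <- sims$pairs[sims$origin_event == i]
    ms <- mc_mean_se(x)
    expect_lt(abs(ms["mean"] - ep$expected_pairs[i]), 3 * ms["se"])
  }
  genes <- attr(sims, "genes")
  ms <- mc_mean_se(genes$total_genes)
  expect_lt(abs(ms["mean"] - expected_gene_count(sch)), 3 * ms["se"])
  ms <- mc_mean_se(genes$unpaired)
  expect_lt(abs(ms["mean"] - expected_unpaired(sch)), 3 * ms["se"])
})

test_that("scenario replicate means agree with ortholog expectations", {
  sc <- speciation_scenario(1, shared = list(wgd_event(100, u2_dist(0.4))),
                            speciation = speciation_event(60, c(0, 0.3, 0.7)),
                            branch_a = list(wgd_event(30, u2_dist(0.5))))
  sims <- simulate_pair_counts(sc, n_rep = 30000, seed = 6)
  eo <- expected_ortholog_pairs(sc)
  for (i in eo$origin_event) {
    x <- sims$pairs[sims$origin_event == i]
    ms <- mc_mean_se(x)
    expect_lt(abs(ms["mean"] - eo$expected_pairs[i]), 3 * ms["se"])
  }
  genes <- attr(sims, "genes")
  ms <- mc_mean_se(genes$unpaired)
  expect_lt(abs(ms["mean"] - expected_ortholog_unpaired(sc)), 3 * ms["se"])
})

test_that("single-tree and replicated counting agree in distribution", {
  sc <- speciation_scenario(500, shared = list(wgd_event(100, u2_dist(0.4))),
                            speciation = speciation_event(60, c(0, 0.3, 0.7)))
  cp <- count_pairs(simulate_scenario(sc, seed = 21))
  eo <- expected_ortholog_pairs(sc)
  # a single M1 = 500 realisation stays within 5 sd of the expectation
  expect_true(all(abs(cp$expected_pairs - eo$expected_pairs) <
                    5 * sqrt(pmax(eo$expected_pairs, 1))))
})

test_that("structural scenario properties hold", {
  # speciation that never keeps both copies yields no s-origin pairs;
  # WGD-sibling genes can still land in different genomes (origin 1 pairs)
  sc <- speciation_scenario(50, shared = list(wgd_event(20, u2_dist(0.5))),
                            speciation = speciation_event(10, c(0, 1, 0)))
  cp <- count_pairs(simulate_scenario(sc, seed = 2))
  expect_equal(cp$expected_pairs[2], 0L)
  expect_equal(expected_ortholog_pairs(sc)$expected_pairs[2], 0)

  # without any shared WGD the same speciation leaves every gene unpaired
  sc1 <- speciation_scenario(50, speciation = speciation_event(10, c(0, 1, 0)))
  cp1 <- count_pairs(simulate_scenario(sc1, seed = 2))
  expect_equal(sum(cp1$expected_pairs), 0L)
  expect_equal(unpaired_count(cp1), total_genes(cp1))

  # deterministic speciation, no WGDs: one s-pair per root gene
  sc2 <- speciation_scenario(25, speciation = speciation_event(10, c(0, 0, 1)))
  cp2 <- count_pairs(simulate_scenario(sc2, seed = 2))
  expect_equal(cp2$expected_pairs, 25L)
})

test_that("long-horizon extinction frequency approaches the fixed point", {
  d <- survival_dist(2, c(0.25, 0.25, 0.5))
  sch <- event_schedule(1, purrr::map(seq(100, 4, length.out = 25),
                                      function(t) wgd_event(t, d)))
  sims <- simulate_pair_counts(sch, n_rep = 20000, seed = 8)
  genes <- attr(sims, "genes")
  p_hat <- mean(genes$total_genes == 0)
  q <- extinction_probability(d)
  se <- sqrt(q * (1 - q) / nrow(genes))
  expect_lt(abs(p_hat - q), 3 * se)
})

test_that("enumerated pairs are consistent with pair counts", {
  sch <- event_schedule(30, wgd_event(10, u2_dist(0.5)), wgd_event(5, u2_dist(0.4)))
  tree <- simulate_schedule(sch, seed = 13)
  prs <- enumerate_pairs(tree)
  cp <- count_pairs(tree)
  expect_equal(as.vector(table(factor(prs$origin_event, levels = 1:2))),
               cp$expected_pairs)
  expect_true(all(prs$gene_1 != prs$gene_2))

  sc <- speciation_scenario(30, shared = list(wgd_event(10, u2_dist(0.5))),
                            speciation = speciation_event(5, c(0, 0.3, 0.7)))
  trs <- simulate_scenario(sc, seed = 13)
  po <- enumerate_pairs(trs)
  co <- count_pairs(trs)
  expect_equal(as.vector(table(factor(po$origin_event, levels = 1:2))),
               co$expected_pairs)
  expect_true(all(po$genome_1 != po$genome_2))
})

test_that("Newick export round-trips through ape", {
  skip_if_not_installed("ape")
  sch <- event_schedule(2, wgd_event(10, c(0, 0, 1)), wgd_event(4, c(0, 0, 1)))
  tree <- simulate_schedule(sch, seed = 1)
  nwk <- tree_newick(tree)
  expect_length(nwk, 2)
  ph <- ape::read.tree(text = nwk[1])
  expect_equal(ape::Ntip(ph), 4)
  expect_equal(sort(unique(ph$edge.length)), c(4, 6))
})
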