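test_that("expected gene count: products of moments, enumeration agreement", {
  expect_equal(expected_gene_count(event_schedule(1, wgd_event(10, c(0, 0, 1)))), 2)
  expect_equal(expected_gene_count(doubling_schedule(c(0.3, 0.3))), 1.3^2)
  expect_equal(expected_gene_count(event_schedule(5)), 5)

  s <- doubling_schedule(c(0.3, 0.3))
  expect_equal(expected_gene_count(s),
               enum_E_Mn(1, wgdfrac:::wgd_survivals(s)), tolerance = 1e-12)
})

test_that("history probabilities: single terms and normalisation", {
  s <- event_schedule(1, wgd_event(10, c(0, 0.4, 0.6)))
  expect_equal(history_probability(s, list(c(0, 1, 0))), 0.4)
  expect_equal(history_probability(s, list(c(0, 0, 1))), 0.6)

  s2 <- event_schedule(2, wgd_event(10, c(0, 0.4, 0.6)))
  expect_equal(history_probability(s2, list(c(0, 1, 1))), 2 * 0.4 * 0.6)

  expect_error(history_probability(s, list(c(1, 1, 0))), class = "wgdfrac_error")
  expect_error(history_probability(s, list(c(0, 1))), class = "wgdfrac_error")

  # all histories of two-generation schedules sum to 1 (incl. u0 > 0)
  for (d in list(survival_dist(2, c(0.1, 0.4, 0.5)),
                 survival_dist(3, c(0.1, 0.3, 0.4, 0.2)))) {
    for (M1 in 1:2) {
      sch <- event_schedule(M1, wgd_event(10, d), wgd_event(5, d))
      total <- 0
      for (r1 in seq_len(nrow(a1 <- compositions(M1, d$r + 1L)))) {
        M2 <- sum((0:d$r) * a1[r1, ])
        a2 <- compositions(M2, d$r + 1L)
        for (r2 in seq_len(nrow(a2)))
          total <- total + history_probability(sch, list(a1[r1, ], a2[r2, ]))
      }
      expect_equal(total, 1, tolerance = 1e-12)
    }
  }
})

test_that("paralog pair expectations reduce to the doubling/tripling closed forms", {
  # single deterministic doubling: exactly one surviving pair
  expect_equal(expected_paralog_pairs(
    event_schedule(1, wgd_event(10, c(0, 0, 1))))$expected_pairs, 1)

  # ploidy-2 closed form: prod(1+u) u_i prod(1+u)^2 over a random grid
  set.seed(7)
  for (rep in 1:10) {
    u2s <- round(stats::runif(sample(2:4, 1), 0.05, 0.9), 3)
    got <- expected_paralog_pairs(doubling_schedule(u2s))$expected_pairs
    K <- length(u2s)
    want <- vapply(seq_len(K), function(i)
      prod(1 + u2s[seq_len(i - 1)]) * u2s[i] * prod((1 + u2s[seq(i + 1, length.out = K - i)])^2),
      numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }

  # constant u: u (1+u)^(2n - i - 1) with n the number of WGDs
  for (u in c(0.2, 0.6)) for (n in 2:4) {
    got <- expected_paralog_pairs(doubling_schedule(rep(u, n)))$expected_pairs
    expect_equal(got, u * (1 + u)^(2 * n - seq_len(n) - 1), tolerance = 1e-12)
  }

  # tripling closed form in (u2 + 3 u3) and (1 + u2 + 2 u3)
  u2 <- 0.2; u3 <- 0.04
  sch <- event_schedule(1, wgd_event(10, u3_dist(u2, u3)), wgd_event(5, u3_dist(u2, u3)))
  got <- expected_paralog_pairs(sch)$expected_pairs
  expect_equal(got, c((3 * u3 + u2) * (1 + 2 * u3 + u2)^2,
                      (1 + 2 * u3 + u2) * (3 * u3 + u2)), tolerance = 1e-12)
})

test_that("paralog pair expectations agree with exhaustive history enumeration", {
  cases <- list(
    list(M1 = 1, survs = list(survival_dist(2, c(0.1, 0.4, 0.5)),
                              u3_dist(0.3, 0.1))),
    list(M1 = 1, survs = list(u3_dist(0.2, 0.04), u3_dist(0.2, 0.04))),
    list(M1 = 2, survs = list(u2_dist(0.4), u2_dist(0.7))),
    list(M1 = 1, survs = list(u2_dist(0.5), u3_dist(0.25, 0.05), u2_dist(0.3))),
    list(M1 = 2, survs = list(u2_dist(0.3), u2_dist(0.5), u2_dist(0.4)))
  )
  for (cs in cases) {
    K <- length(cs$survs)
    times <- seq(100, 10, length.out = K)
    sch <- event_schedule(cs$M1, purrr::map2(times, cs$survs, wgd_event))
    expect_equal(expected_gene_count(sch), enum_E_Mn(cs$M1, cs$survs),
                 tolerance = 1e-9)
    got <- expected_paralog_pairs(sch)$expected_pairs
    want <- vapply(seq_len(K), function(i) enum_E_Ni(cs$M1, cs$survs, i), numeric(1))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("unpaired-gene expectation is the product of single-survivor terms", {
  sch <- event_schedule(1000, wgd_event(10, c(0, 0.7, 0.3)),
                        wgd_event(5, c(0, 0.5, 0.5)))
  expect_equal(expected_unpaired(sch), 1000 * 0.7 * 0.5)
  expect_equal(expected_unpaired(event_schedule(7)), 7)
  expect_equal(expected_unpaired(
    event_schedule(10, wgd_event(5, c(0, 0, 1)))), 0)
  # enumeration oracle (u0 = 0): P(single observed descendant)
  survs <- list(u2_dist(0.3), u2_dist(0.6))
  sch2 <- event_schedule(2, purrr::map2(c(10, 5), survs, wgd_event))
  expect_equal(expected_unpaired(sch2), 2 * enum_P_single(survs), tolerance = 1e-9)
})

test_that("ortholog expectations reproduce the speciation constants", {
  # tripling-tripling-speciation: O_i carry 1/2 * (1 + u2_spec)^2 via 2 m^2
  d3 <- u3_dist(0.2, 0.04)
  sc <- speciation_scenario(1, shared = list(wgd_event(120, d3), wgd_event(70, d3)),
                            speciation = speciation_event(40, c(0, 0.3, 0.7)))
  eo <- expected_ortholog_pairs(sc)$expected_pairs
  expect_equal(eo[1], 0.5 * (3 * 0.04 + 0.2) * (1 + 2 * 0.04 + 0.2)^2 * (1 + 0.7)^2)
  expect_equal(eo[2], 0.5 * (1 + 2 * 0.04 + 0.2) * (3 * 0.04 + 0.2) * (1 + 0.7)^2)
  expect_equal(eo[3], 0.7 * (1 + 2 * 0.04 + 0.2)^2)

  # doubling case with a post-speciation WGD in A only: F_A = 2 * 1.5, F_B = 2
  sc2 <- speciation_scenario(1, shared = list(wgd_event(100, u2_dist(0.4))),
                             speciation = speciation_event(60, c(0, 0, 1)),
                             branch_a = list(wgd_event(30, u2_dist(0.5))))
  eo2 <- expected_ortholog_pairs(sc2)$expected_pairs
  expect_equal(eo2, c(0.5 * 0.4 * (2 * 1.5) * 2, 0.25 * 1.4 * (2 * 1.5) * 2))

  # binomial speciation survival realises the independent-genomes 1/4
  scq <- speciation_scenario(1, shared = list(wgd_event(100, u2_dist(0.4))),
                             speciation = binom_speciation(60, 0.5))
  expect_equal(expected_ortholog_pairs(scq)$expected_pairs[2], 0.25 * 1.4)

  # empty amplification products: no post-speciation WGDs
  expect_equal(expected_ortholog_pairs(
    speciation_scenario(1, speciation = speciation_event(10, c(0, 0, 1))))$expected_pairs,
    1)
})

test_that("pair expectations are monotone in survival", {
  base <- c(0.3, 0.5, 0.4)
  for (j in 1:3) {
    lo <- expected_paralog_pairs(doubling_schedule(base))$expected_pairs
    up <- base; up[j] <- up[j] + 0.1
    hi <- expected_paralog_pairs(doubling_schedule(up))$expected_pairs
    expect_true(all(hi >= lo))
  }
  # tripling: shifting mass from u1 to u3 raises every N_i
  lo <- expected_paralog_pairs(event_schedule(1,
    wgd_event(10, u3_dist(0.2, 0.05)), wgd_event(5, u3_dist(0.2, 0.05))))$expected_pairs
  hi <- expected_paralog_pairs(event_schedule(1,
    wgd_event(10, u3_dist(0.2, 0.15)), wgd_event(5, u3_dist(0.2, 0.15))))$expected_pairs
  expect_true(all(hi >= lo))
})

test_that("deterministic survival accounts for every pair of a common root", {
  # all u_r = 1: the M_n = r^K genes of one root are pairwise related
  sch <- event_schedule(1, wgd_event(10, c(0, 0, 1)), wgd_event(5, c(0, 0, 1)))
  ep <- expected_paralog_pairs(sch)
  expect_equal(sum(ep$expected_pairs), choose(4, 2))
  expect_equal(ep$expected_pairs, c(4, 2))  # hand enumeration of the binary tree
})

test_that("ortholog-unpaired expectation matches structural limits", {
  # no shared WGD: singletons are exactly the u1 speciation survivors
  sc <- speciation_scenario(100, speciation = speciation_event(10, c(0, 0.4, 0.6)))
  expect_equal(expected_ortholog_unpaired(sc), 100 * 0.4)
  # deterministic speciation: every gene pairs across genomes
  sc2 <- speciation_scenario(50, shared = list(wgd_event(20, u2_dist(0.5))),
                             speciation = speciation_event(10, c(0, 0, 1)))
  expect_equal(expected_ortholog_unpaired(sc2), 0)
})
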