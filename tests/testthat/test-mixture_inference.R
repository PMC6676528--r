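test_that("mode configuration is validated", {
  expect_error(mode_config(bin_width = 0.5), class = "wgdfrac_error")
  expect_error(mode_config(window = 4), class = "wgdfrac_error")
  expect_error(mode_config(min_prominence = 2), class = "wgdfrac_error")
})

test_that("local modes land on the component means", {
  # single tight component: exactly one mode within one bin of the mean
  one <- generate_similarities(mixture_model(0.62, 0.03, 1), 5000, seed = 5)
  m1 <- find_local_modes(one, mode_config())
  expect_equal(nrow(m1), 1)
  expect_lt(abs(m1$mean - 0.62), 0.011)

  # two well-separated components at equal weights
  two <- generate_similarities(
    mixture_model(c(0.55, 0.85), c(0.05, 0.05), c(0.5, 0.5)), 10000, seed = 6)
  m2 <- find_local_modes(two, mode_config())
  expect_equal(nrow(m2), 2)
  expect_lt(abs(m2$mean[1] - 0.55), 0.011)
  expect_lt(abs(m2$mean[2] - 0.85), 0.011)
  # brute-force check: each reported mode is the densest bin in its vicinity
  h <- hist(two$similarity, breaks = seq(0, 1, 0.01), plot = FALSE)
  for (mm in m2$mean) {
    near <- abs(h$mids - mm) <= 0.03
    # raw densest bin within a couple of bins of the smoothed mode
    expect_lt(abs(h$mids[near][which.max(h$counts[near])] - mm), 0.025)
  }

  expect_error(find_local_modes(runif(50)), class = "wgdfrac_error")
})

test_that("finer bins raise the spurious mode count on structureless data", {
  set.seed(99)
  counts <- vapply(1:20, function(i) {
    x <- runif(2000)
    fine <- nrow(find_local_modes(x, mode_config(bin_width = 0.004, window = 3,
                                                 min_prominence = 0.02)))
    coarse <- nrow(find_local_modes(x, mode_config(bin_width = 0.05, window = 3,
                                                   min_prominence = 0.02)))
    c(fine = fine, coarse = coarse)
  }, numeric(2))
  expect_gt(mean(counts["fine", ]), mean(counts["coarse", ]))
})

test_that("constrained EM reduces to closed-form ML for one component", {
  x <- generate_similarities(mixture_model(0.6, 0.05, 1), 2000, seed = 7)$similarity
  fit <- fit_constrained_mixture(x, means = 0.6)
  expect_equal(fit$components$weight, 1)
  # ML variance about the fixed mean
  expect_equal(fit$components$sd, sqrt(mean((x - 0.6)^2)), tolerance = 1e-6)
  expect_equal(fit$components$count, length(x))
})

test_that("constrained EM recovers known weights and sds", {
  mix <- mixture_model(c(0.45, 0.65, 0.85), c(0.05, 0.04, 0.03), c(0.3, 0.4, 0.3))
  x <- generate_similarities(mix, 20000, seed = 8)
  fit <- fit_constrained_mixture(x, means = mix$mean)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$components$weight - mix$weight)), 0.03)
  expect_lt(max(abs(fit$components$sd - mix$sd) / mix$sd), 0.15)
  expect_equal(sum(fit$components$weight), 1, tolerance = 1e-10)
})

test_that("EM log-likelihood is monotone and below the unconstrained optimum", {
  mix <- mixture_model(c(0.55, 0.8), c(0.05, 0.04), c(0.5, 0.5))
  x <- generate_similarities(mix, 5000, seed = 9)$similarity
  lls <- vapply(1:12, function(k)
    fit_constrained_mixture(x, means = c(0.55, 0.8), max_iter = k)$loglik,
    numeric(1))
  expect_true(all(diff(lls) >= -1e-10))

  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  fit <- fit_constrained_mixture(x, means = c(0.55, 0.8))
  un <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_lte(fit$loglik, un$loglik + 1e-6)
})

test_that("component collapse is floored and flagged", {
  x <- c(rep(0.5, 300), rnorm(300, 0.8, 0.05))
  x <- pmin(pmax(x, 1e-3), 1)
  fit <- fit_constrained_mixture(x, means = c(0.5, 0.8))
  expect_true(fit$collapsed[1])
  expect_gte(fit$components$sd[1], 1e-4)
})

test_that("tidy, glance and autoplot expose the fit", {
  x <- generate_similarities(mixture_model(c(0.5, 0.8), c(0.05, 0.04), c(0.5, 0.5)),
                             3000, seed = 10)
  fit <- fit_constrained_mixture(x, means = c(0.5, 0.8))
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_named(td, c("component", "mean", "sd", "weight", "count", "collapsed"))
  gl <- glance(fit)
  expect_equal(gl$n_components, 2)
  expect_true(gl$converged)
  p <- ggplot2::autoplot(fit, sample = x)
  expect_s3_class(p, "ggplot")
})

test_that("prominence rule finds the true component count in most replicates", {
  # three components separated by at least 2 sd: >= 90 % correct counts
  mix <- mixture_model(c(0.45, 0.65, 0.85), c(0.05, 0.04, 0.03), c(0.3, 0.4, 0.3))
  hits <- vapply(1:100, function(i) {
    x <- generate_similarities(mix, 5000, seed = 1000 + i)
    nrow(find_local_modes(x, mode_config())) == 3
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("modes align across comparisons by single linkage", {
  mks <- function(means, seed) generate_similarities(
    mixture_model(means, rep(0.03, length(means)), rep(1 / length(means), length(means))),
    8000, seed = seed)
  # identical samples: consensus equals the individual modes
  s <- mks(c(0.5, 0.8), 11)
  al <- shared_mode_alignment(list(s, s), mode_config())
  expect_true(all(al$matched))
  expect_equal(al$consensus, al$mode, tolerance = 1e-12)

  # one shared old event, two distinct recent events
  a <- mks(c(0.45, 0.72), 12)
  b <- mks(c(0.45, 0.9), 13)
  al2 <- shared_mode_alignment(list(a, b), mode_config(), threshold = 0.05)
  sizes <- table(al2$cluster)
  expect_equal(sort(as.vector(sizes)), c(1, 1, 2))

  # jitter below half the threshold leaves the clustering unchanged
  al3 <- shared_mode_alignment(list(a, mks(c(0.46, 0.9), 14)),
                               mode_config(), threshold = 0.05)
  sizes3 <- table(al3$cluster)
  expect_equal(sort(as.vector(sizes3)), c(1, 1, 2))

  expect_error(shared_mode_alignment(list(a)), class = "wgdfrac_error")
})
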