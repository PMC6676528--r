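# Recovering the mixture from an observed similarity sample: local modes
# anchor the component means (overlapping tails make plain averaging or
# unconstrained decomposition unreliable), then maximum likelihood fills in
# the standard deviation and amplitude of each component with means fixed.

#' Mode-search configuration
#'
#' @param bin_width Histogram bin width in similarity units, in
#'   `(0, 0.1]`.  Default 0.01: fine enough to separate events a few My
#'   apart, coarse enough to keep spurious modes rare at realistic
#'   sample sizes.
#' @param window Moving-average smoothing window in bins; must be odd.
#' @param min_prominence Minimum topographic prominence of a reported
#'   mode, as a fraction of the highest smoothed bin.
#' @param min_components,max_components Acceptable mode-count bounds;
#'   when more modes pass the prominence rule than `max_components`,
#'   the most prominent ones are kept.
#' @return An object of class `wgd_mode_config`.
#' @export
mode_config <- function(bin_width = 0.01, window = 5, min_prominence = 0.05,
                        min_components = 1, max_components = Inf) {
  if (!is.numeric(bin_width) || bin_width <= 0 || bin_width > 0.1)
    stop_wgdfrac("`bin_width` must lie in (0, 0.1]")
  if (!is.numeric(window) || window < 1 || window %% 2 != 1)
    stop_wgdfrac("`window` must be a positive odd number of bins")
  if (min_prominence < 0 || min_prominence > 1)
    stop_wgdfrac("`min_prominence` must be a fraction in [0, 1]")
  structure(list(bin_width = bin_width, window = as.integer(window),
                 min_prominence = min_prominence,
                 min_components = min_components, max_components = max_components),
            class = "wgd_mode_config")
}

similarity_vector <- function(sample) {
  if (is.data.frame(sample)) {
    if (!"similarity" %in% names(sample))
      stop_wgdfrac("data-frame samples need a `similarity` column")
    sample <- sample$similarity
  }
  if (!is.numeric(sample)) stop_wgdfrac("`sample` must be numeric similarities")
  sample <- sample[is.finite(sample)]
  if (any(sample < 0 | sample > 1))
    stop_wgdfrac("similarities must lie in [0, 1] (divide percent values by 100)")
  sample
}

#' Locate local modes of a similarity sample
#'
#' Bins the sample, smooths the bin counts with a centred moving
#' average, and reports local maxima by topographic prominence (the
#' drop needed before higher ground is reached, as a fraction of the
#' global peak).  Ties between equal-height adjacent bins resolve to
#' the leftmost (lowest-similarity) bin.
#'
#' @param sample Numeric similarities in `[0, 1]`, or a data frame with
#'   a `similarity` column.  At least 100 values.
#' @param config A [mode_config()].
#' @return A tibble `mean` (bin centre), `height` (smoothed count),
#'   `prominence` (fraction of global peak), ordered by `mean`.  Empty,
#'   with a `"diagnostic"` attribute, when no mode passes the
#'   prominence rule.
#' @examples
#' x <- generate_similarities(
#'   mixture_model(c(0.55, 0.85), c(0.05, 0.05), c(0.5, 0.5)), 5000, seed = 1)
#' find_local_modes(x, mode_config())
#' @export
find_local_modes <- function(sample, config = mode_config()) {
  if (!inherits(config, "wgd_mode_config")) stop_wgdfrac("`config` must be a mode_config()")
  x <- similarity_vector(sample)
  if (length(x) < 100)
    stop_wgdfrac("mode search needs at least 100 similarities")
  breaks <- seq(0, 1 + config$bin_width / 2, by = config$bin_width)
  counts <- tabulate(pmin(findInterval(x, breaks, left.open = TRUE) ,
                          length(breaks) - 1L) + (x == 0),
                     nbins = length(breaks) - 1L)
  centers <- breaks[-length(breaks)] + config$bin_width / 2
  # centred moving average; edges use the available partial window
  h <- config$window %/% 2L
  csum <- cumsum(c(0, counts))
  nb <- length(counts)
  lo <- pmax(seq_len(nb) - h, 1L); hi <- pmin(seq_len(nb) + h, nb)
  smooth <- (csum[hi + 1L] - csum[lo]) / (hi - lo + 1L)

  peak <- max(smooth)
  if (peak == 0) {
    out <- empty_modes("sample produced an empty histogram")
    return(out)
  }
  # local maxima, leftmost-wins ties: strictly above the previous bin,
  # at least as high as the next
  left <- c(-Inf, smooth[-nb]); right <- c(smooth[-1], -Inf)
  cand <- which(smooth > left & smooth >= right)
  prom <- vapply(cand, function(i) {
    p <- smooth[i]
    drop_side <- function(idx) {
      m <- p
      for (j in idx) {
        if (smooth[j] > p) return(m)
        m <- min(m, smooth[j])
      }
      # boundary reached without higher ground: full height counts
      min(m, 0)
    }
    lmin <- drop_side(rev(seq_len(i - 1L)))
    rmin <- drop_side(seq(i + 1L, length.out = nb - i))
    p - max(lmin, rmin)
  }, numeric(1)) / peak
  keep <- prom >= config$min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand))
    return(empty_modes("no local mode reached the configured prominence"))
  if (length(cand) > config$max_components) {
    ord <- order(prom, decreasing = TRUE)[seq_len(config$max_components)]
    cand <- cand[sort(ord)]; prom <- prom[sort(ord)]
  }
  out <- tibble::tibble(mean = centers[cand], height = smooth[cand],
                        prominence = prom)
  out <- out[order(out$mean), ]
  if (nrow(out) < config$min_components)
    attr(out, "diagnostic") <- sprintf("only %d mode(s) found, %d expected",
                                       nrow(out), config$min_components)
  out
}

empty_modes <- function(msg) {
  structure(tibble::tibble(mean = numeric(0), height = numeric(0),
                           prominence = numeric(0)),
            diagnostic = msg)
}

#' Constrained maximum-likelihood mixture fit
#'
#' EM for a normal mixture on `(0, 1]` with the component means held
#' fixed at the supplied anchors (typically local modes): only the
#' standard deviations and weights are estimated, the procedure that
#' keeps overlapping, noisy similarity data from dragging components to
#' spurious locations.  The log-likelihood is non-decreasing across
#' iterations; convergence is declared when the gain drops below `tol`.
#'
#' @param sample Similarities in `(0, 1]` (vector or data frame with a
#'   `similarity` column).
#' @param means Fixed component means, strictly increasing.
#' @param init_sds,init_weights Optional starting values (defaults:
#'   sd = half the smallest gap between means or 0.05, equal weights).
#' @param max_iter,tol Iteration cap (500) and log-likelihood gain
#'   tolerance (`1e-8`).
#' @param sd_floor Lower bound on component sd; components driven below
#'   it are floored and flagged (`collapsed`).
#' @param uniform_noise If `TRUE`, adds a uniform background component
#'   over `(0, 1]` whose weight is estimated — an optional absorber for
#'   unmodelled noise; off by default.
#' @param refine_means If `TRUE`, means may move at most one
#'   `refine_bin` from their anchors during EM; off by default.
#' @param refine_bin Bin width bounding the mean refinement.
#' @return An object of class `wgd_mixture_fit`: list with `components`
#'   (a [mixture_model()] tibble with `count = weight * n`), `noise_weight`,
#'   `loglik`, `n`, `iterations`, `converged`, `collapsed`.
#' @export
fit_constrained_mixture <- function(sample, means, init_sds = NULL,
                                    init_weights = NULL, max_iter = 500,
                                    tol = 1e-8, sd_floor = 1e-4,
                                    uniform_noise = FALSE,
                                    refine_means = FALSE, refine_bin = 0.01) {
  x <- similarity_vector(sample)
  x <- x[x > 0]
  n <- length(x)
  if (n < 2) stop_wgdfrac("need at least two similarities to fit")
  K <- length(means)
  if (K < 1) stop_wgdfrac("`means` must contain at least one component")
  if (is.unsorted(means, strictly = TRUE))
    stop_wgdfrac("`means` must be strictly increasing")
  anchors <- as.numeric(means)
  mu <- anchors
  default_sd <- if (K > 1) max(min(diff(anchors)) / 2, 1e-3) else max(stats::sd(x), 1e-3)
  sds <- if (is.null(init_sds)) rep(min(default_sd, 0.05), K) else rep_len(init_sds, K)
  nc <- K + as.integer(uniform_noise)
  w <- if (is.null(init_weights)) rep(1 / nc, nc) else {
    iw <- rep_len(init_weights, K)
    if (uniform_noise) c(iw * 0.95 / sum(iw), 0.05) else iw / sum(iw)
  }

  dens <- function(mu, sds, w) {
    d <- vapply(seq_len(K), function(k) w[k] * stats::dnorm(x, mu[k], sds[k]),
                numeric(n))
    if (uniform_noise) d <- cbind(d, w[K + 1L])     # dunif(x, 0, 1) = 1
    d
  }
  ll <- -Inf
  collapsed <- rep(FALSE, K)
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    d <- dens(mu, sds, w)
    rs <- rowSums(d)
    rs[rs < .Machine$double.xmin] <- .Machine$double.xmin
    new_ll <- sum(log(rs))
    gamma <- d / rs
    nk <- colSums(gamma)
    w <- nk / n
    for (k in seq_len(K)) {
      if (nk[k] <= 0) { collapsed[k] <- TRUE; sds[k] <- sd_floor; next }
      if (refine_means) {
        m_new <- sum(gamma[, k] * x) / nk[k]
        mu[k] <- min(max(m_new, anchors[k] - refine_bin), anchors[k] + refine_bin)
      }
      v <- sum(gamma[, k] * (x - mu[k])^2) / nk[k]
      s <- sqrt(v)
      if (s < sd_floor) { collapsed[k] <- TRUE; s <- sd_floor }
      sds[k] <- s
    }
    if (is.finite(ll) && new_ll - ll < tol) { ll <- new_ll; converged <- TRUE; break }
    ll <- new_ll
  }
  comp_w <- w[seq_len(K)]
  comps <- tibble::tibble(mean = mu, sd = sds, weight = comp_w,
                          count = comp_w * n)
  structure(list(components = comps,
                 noise_weight = if (uniform_noise) w[K + 1L] else 0,
                 anchors = anchors, loglik = ll, n = n, iterations = it,
                 converged = converged, collapsed = collapsed,
                 config = list(tol = tol, max_iter = max_iter,
                               sd_floor = sd_floor, uniform_noise = uniform_noise,
                               refine_means = refine_means, refine_bin = refine_bin)),
            class = "wgd_mixture_fit")
}

#' @export
print.wgd_mixture_fit <- function(x, ...) {
  cat(sprintf("<wgd_mixture_fit> %d component(s), n = %d, logLik = %.3f (%s, %d iterations)\n",
              nrow(x$components), x$n, x$loglik,
              if (x$converged) "converged" else "not converged", x$iterations))
  print(x$components)
  if (x$config$uniform_noise)
    cat(sprintf("uniform noise weight: %.4f\n", x$noise_weight))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a constrained mixture fit
#'
#' @param x A `wgd_mixture_fit`.
#' @param ... Unused.
#' @return One row per component: `component`, `mean`, `sd`, `weight`,
#'   `count`, `collapsed`.
#' @export
tidy.wgd_mixture_fit <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(component = seq_len(nrow(x$components))),
                   x$components,
                   tibble::tibble(collapsed = x$collapsed))
}

#' @rdname tidy.wgd_mixture_fit
#' @return For `glance()`: a one-row tibble `logLik`, `n`, `n_components`,
#'   `iterations`, `converged`, `noise_weight`.
#' @export
glance.wgd_mixture_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n = x$n, n_components = nrow(x$components),
                 iterations = x$iterations, converged = x$converged,
                 noise_weight = x$noise_weight)
}

#' Plot a mixture fit over the sample histogram
#'
#' @param object A `wgd_mixture_fit`.
#' @param sample The similarities the fit was computed from.
#' @param bin_width Histogram bin width.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wgd_mixture_fit <- function(object, sample, bin_width = 0.01, ...) {
  x <- similarity_vector(sample)
  comp <- tidy.wgd_mixture_fit(object)
  grid <- tidyr::expand_grid(component = comp$component,
                             similarity = seq(0.001, 1, by = 0.002))
  grid <- dplyr::left_join(grid, comp, by = "component")
  grid$density <- grid$weight * stats::dnorm(grid$similarity, grid$mean, grid$sd) *
    length(x) * bin_width
  ggplot2::ggplot() +
    ggplot2::geom_histogram(ggplot2::aes(x = .data$similarity),
                            data = tibble::tibble(similarity = x),
                            binwidth = bin_width, fill = "grey80", colour = NA) +
    ggplot2::geom_line(ggplot2::aes(x = .data$similarity, y = .data$density,
                                    colour = factor(.data$component)),
                       data = grid) +
    ggplot2::labs(x = "similarity", y = "gene pairs per bin", colour = "component") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Align local modes across several genome comparisons
#'
#' Events shared by several comparisons (the same WGD seen from
#' different species pairs) should surface as modes at nearby
#' similarities.  Modes pooled over samples are clustered by
#' single-linkage with a similarity-distance threshold; each cluster's
#' consensus is the median of its member modes.  When a cluster holds
#' two modes from the same sample, only the one nearest the consensus
#' stays assigned; the rest are reported unmatched rather than forced.
#'
#' @param samples A list of similarity samples (vectors or data frames).
#' @param config A [mode_config()] used for per-sample mode detection.
#' @param threshold Single-linkage merge threshold in similarity units.
#' @return A tibble `sample`, `mode`, `cluster`, `consensus`, `matched`;
#'   cluster consensus values are medians over matched member modes.
#' @export
shared_mode_alignment <- function(samples, config = mode_config(),
                                  threshold = 0.03) {
  if (!is.list(samples) || length(samples) < 2)
    stop_wgdfrac("`samples` must be a list of at least two samples")
  per <- purrr::imap_dfr(samples, function(s, i) {
    m <- find_local_modes(s, config)
    if (!nrow(m)) return(tibble::tibble(sample = integer(0), mode = numeric(0)))
    tibble::tibble(sample = as.integer(i), mode = m$mean)
  })
  if (!nrow(per)) stop_wgdfrac("no modes detected in any sample")
  if (nrow(per) == 1L) {
    per$cluster <- 1L; per$consensus <- per$mode; per$matched <- TRUE
    return(per)
  }
  hc <- stats::hclust(stats::dist(per$mode), method = "single")
  per$cluster <- stats::cutree(hc, h = threshold)
  per <- dplyr::group_by(per, .data$cluster)
  per <- dplyr::mutate(per, consensus = stats::median(.data$mode))
  per <- dplyr::group_by(per, .data$cluster, .data$sample)
  per <- dplyr::mutate(per,
                       matched = rank(abs(.data$mode - .data$consensus),
                                      ties.method = "first") == 1L)
  per <- dplyr::ungroup(per)
  # recompute consensus over matched members only
  per <- dplyr::group_by(per, .data$cluster)
  per <- dplyr::mutate(per, consensus = stats::median(.data$mode[.data$matched]))
  per <- dplyr::ungroup(per)
  per$cluster[!per$matched] <- NA_integer_
  per$consensus[!per$matched] <- NA_real_
  dplyr::arrange(per, .data$sample, .data$mode)
}
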