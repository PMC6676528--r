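# The mutational observation model: event ages map to expected sequence
# similarity through exponential decay, and each event's surviving pairs
# scatter around that mean as a truncated normal component.

#' Exponential similarity-decay model
#'
#' Expected similarity (proportion of identical nucleotides) of a gene
#' pair of age `t` My: `p(t) = C * exp(-lambda * t)`, clipped above at 1.
#' The default amplitude is `C = 1` (two identical sequences at age 0);
#' empirical fits on real comparisons can prefer amplitudes slightly
#' above 1, which is supported as a configuration choice.
#'
#' @param C Amplitude (unitless), `> 0`.
#' @param lambda Decay rate per My, `> 0`.
#' @return An object of class `wgd_decay`.
#' @examples
#' decay_model(1, 0.09)
#' @export
decay_model <- function(C = 1, lambda = 0.09) {
  if (length(C) != 1L || !is.numeric(C) || is.na(C) || C <= 0)
    stop_wgdfrac("`C` must be a single positive number")
  if (length(lambda) != 1L || !is.numeric(lambda) || is.na(lambda) || lambda <= 0)
    stop_wgdfrac("`lambda` must be a single positive rate per My")
  structure(list(C = C, lambda = lambda), class = "wgd_decay")
}

#' Expected similarity at a given age
#'
#' @param decay A [decay_model()].
#' @param t Age(s) in My before present.
#' @return `min(C * exp(-lambda * t), 1)`, vectorised over `t`.  No
#'   lower clip is applied: remote events may fall below any detectable
#'   similarity, which is informative in itself.
#' @export
mean_similarity <- function(decay, t) {
  if (!inherits(decay, "wgd_decay")) stop_wgdfrac("`decay` must be a decay_model()")
  pmin(decay$C * exp(-decay$lambda * t), 1)
}

#' Linear mean-to-standard-deviation model
#'
#' Component standard deviations scale linearly with the component mean
#' (older components, with lower mean similarity, are more diffuse).
#' Defaults give sd 0.025 at similarity 0.95 and 0.07 at 0.5, the
#' magnitudes typical of syntenic-pair similarity histograms.
#'
#' @param intercept,slope Coefficients of `sd = intercept + slope * mean`.
#'   Must yield `sd > 0` over `(0, 1]`.
#' @return An object of class `wgd_sd_model`.
#' @export
sd_model <- function(intercept = 0.12, slope = -0.1) {
  if (!is.numeric(intercept) || !is.numeric(slope) || anyNA(c(intercept, slope)))
    stop_wgdfrac("`intercept` and `slope` must be numeric")
  if (intercept + slope * 1 <= 0 || intercept + slope * 0 <= 0)
    stop_wgdfrac("sd must stay positive over the whole similarity range (0, 1]")
  structure(list(intercept = intercept, slope = slope), class = "wgd_sd_model")
}

#' @rdname sd_model
#' @param sdm A `wgd_sd_model`.
#' @param mean Component mean(s).
#' @export
component_sd <- function(sdm, mean) {
  if (!inherits(sdm, "wgd_sd_model")) stop_wgdfrac("`sdm` must be an sd_model()")
  sd <- sdm$intercept + sdm$slope * mean
  if (any(sd <= 0)) stop_wgdfrac("sd model yields non-positive sd at the requested mean(s)")
  sd
}

#' Component means implied by an event schedule
#'
#' One similarity-component mean per pair-generating event: WGDs for a
#' single-genome schedule; shared WGDs plus the speciation for a
#' scenario (post-speciation WGDs amplify ortholog counts but do not
#' originate ortholog pairs).  Means are strictly increasing in event
#' recency.
#'
#' @param x A [event_schedule()] or [speciation_scenario()].
#' @param decay A [decay_model()].
#' @return A tibble `origin_event`, `time_My`, `mean`, ordered by
#'   event age (oldest first, so means increasing).
#' @export
component_means <- function(x, decay) {
  if (inherits(x, "wgd_schedule")) {
    sel <- x$events$kind == "wgd"
    times <- x$events$time[sel]
  } else if (inherits(x, "wgd_scenario")) {
    times <- x$shared$time
  } else stop_wgdfrac("`x` must be a wgd_schedule or wgd_scenario")
  if (anyDuplicated(times))
    stop_wgdfrac("two pair-generating events share a time: their components are indistinguishable")
  tibble::tibble(origin_event = seq_along(times), time_My = times,
                 mean = mean_similarity(decay, times))
}

#' Mixture of similarity components
#'
#' @param mean Component means in `(0, 1)`, strictly increasing.
#' @param sd Component standard deviations, `> 0`.
#' @param weight Mixing weights, summing to 1 (renormalised within
#'   `1e-9`).
#' @param count Optional integer pair counts per component.
#' @return A tibble of class `wgd_mixture`.
#' @export
mixture_model <- function(mean, sd, weight, count = NA_integer_) {
  if (any(mean <= 0) || any(mean >= 1)) stop_wgdfrac("component means must lie in (0, 1)")
  if (is.unsorted(mean, strictly = TRUE)) stop_wgdfrac("component means must be strictly increasing")
  if (any(sd <= 0)) stop_wgdfrac("component sds must be positive")
  if (any(weight < 0)) stop_wgdfrac("weights must be non-negative")
  s <- sum(weight)
  if (abs(s - 1) > 1e-9) stop_wgdfrac("weights must sum to 1")
  if (!all(is.na(count)) && any(count < 0 | count != round(count), na.rm = TRUE))
    stop_wgdfrac("counts must be non-negative integers")
  tbl <- tibble::tibble(mean = as.numeric(mean), sd = as.numeric(sd),
                        weight = as.numeric(weight) / s,
                        count = as.integer(round(count)))
  structure(tbl, class = c("wgd_mixture", class(tbl)))
}

# inverse-CDF draws from N(mean, sd) truncated to (lo, hi]
rtrunc_norm <- function(n, mean, sd, lo = 0, hi = 1) {
  pa <- stats::pnorm(lo, mean, sd)
  pb <- stats::pnorm(hi, mean, sd)
  q <- stats::qnorm(pa + stats::runif(n) * (pb - pa), mean, sd)
  pmin(pmax(q, lo + .Machine$double.eps), hi)
}

#' Draw a synthetic similarity sample from a mixture
#'
#' Components are chosen by weight and values drawn from the component
#' normal truncated to `(0, 1]` (truncation, not clipping, so no mass
#' piles up at the bounds).
#'
#' @param mixture A [mixture_model()].
#' @param n_pairs Number of draws.
#' @param seed Integer random seed.
#' @return A tibble `similarity`, `component` (1-based index into the
#'   mixture).
#' @export
generate_similarities <- function(mixture, n_pairs, seed) {
  if (!inherits(mixture, "wgd_mixture")) stop_wgdfrac("`mixture` must be a mixture_model()")
  check_seed(seed)
  set.seed(seed)
  comp <- sample.int(nrow(mixture), n_pairs, replace = TRUE, prob = mixture$weight)
  sim <- rtrunc_norm(n_pairs, mixture$mean[comp], mixture$sd[comp])
  tibble::tibble(similarity = sim, component = comp)
}

#' Synthesize a full gene-pair similarity dataset with ground truth
#'
#' The end-to-end generator standing in for a syntenic-pair comparison:
#' simulates the branching process once, assigns every surviving pair
#' the component mean of its origin event (via the decay model) and the
#' matching standard deviation (via the sd model), and draws its
#' similarity from the truncated normal.  The returned ground truth
#' (component table with exact pair counts, the generating survival
#' probabilities, the unpaired-gene count) supports parameter-recovery
#' studies.
#'
#' @param x A [event_schedule()] (paralog sample) or
#'   [speciation_scenario()] (ortholog sample).  Its `M1` sets the
#'   scale of the sample.
#' @param decay A [decay_model()].
#' @param sdm A [sd_model()].
#' @param seed Integer random seed.
#' @return An object of class `wgd_synth`: a list with `sample` (tibble
#'   `gene_id_1`, `gene_id_2`, `similarity`, `origin_event`), `mixture`
#'   (ground-truth [mixture_model()] whose counts are exactly the
#'   simulated pair counts), `unpaired` (simulated unpaired-gene count;
#'   `NA` for scenarios), and `source` (the generating object).
#' @export
synthesize_dataset <- function(x, decay, sdm = sd_model(), seed) {
  check_seed(seed)
  tree <- if (inherits(x, "wgd_schedule")) simulate_schedule(x, seed)
          else if (inherits(x, "wgd_scenario")) simulate_scenario(x, seed)
          else stop_wgdfrac("`x` must be a wgd_schedule or wgd_scenario")
  cm <- component_means(x, decay)
  prs <- enumerate_pairs(tree)
  mu <- cm$mean[match(prs$origin_event, cm$origin_event)]
  sd <- component_sd(sdm, mu)
  sim <- rtrunc_norm(nrow(prs), mu, sd)
  gid <- function(node, genome) {
    ifelse(is.na(genome), sprintf("g%06d", node), sprintf("%s_g%06d", genome, node))
  }
  sample <- tibble::tibble(
    gene_id_1 = gid(prs$gene_1, prs$genome_1),
    gene_id_2 = gid(prs$gene_2, prs$genome_2),
    similarity = sim,
    origin_event = prs$origin_event
  )
  counts <- vapply(cm$origin_event, function(i) sum(prs$origin_event == i), integer(1))
  keep <- counts > 0
  # component means already increase with origin_event (older events are less similar)
  mix <- mixture_model(cm$mean[keep], component_sd(sdm, cm$mean[keep]),
                       counts[keep] / sum(counts), counts[keep])
  mix$origin_event <- cm$origin_event[keep]
  cp <- count_pairs(tree)
  structure(list(sample = sample, mixture = mix,
                 unpaired = unpaired_count(cp), total_genes = total_genes(cp),
                 source = x, decay = decay, sd_model = sdm, seed = seed),
            class = "wgd_synth")
}

#' @export
print.wgd_synth <- function(x, ...) {
  cat(sprintf("<wgd_synth> %d gene pairs, %d component(s); unpaired genes: %s\n",
              nrow(x$sample), nrow(x$mixture), format(x$unpaired)))
  print(x$mixture)
  invisible(x)
}
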