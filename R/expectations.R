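#' Expected observed gene count
#'
#' Expected number of genes at the observation generation.  By linearity
#' of expectation over generations this is `M1 * prod(mu_i)` where
#' `mu_i` is the mean survivor count of event `i`; it equals the full
#' enumeration of histories weighted by their multinomial probabilities.
#'
#' @param schedule A [event_schedule()].
#' @return Expected gene count (a single number).
#' @examples
#' expected_gene_count(event_schedule(1, wgd_event(10, c(0, 0.7, 0.3)),
#'                                    wgd_event(5, c(0, 0.7, 0.3))))  # 1.3^2
#' @export
expected_gene_count <- function(schedule) {
  check_schedule(schedule)
  schedule$M1 * prod(purrr::map_dbl(wgd_survivals(schedule), .surv_mean))
}

check_schedule <- function(schedule) {
  if (!inherits(schedule, "wgd_schedule"))
    stop_wgdfrac("expected a `wgd_schedule`; see event_schedule()")
}

check_scenario <- function(scenario) {
  if (!inherits(scenario, "wgd_scenario"))
    stop_wgdfrac("expected a `wgd_scenario`; see speciation_scenario()")
}

#' Probability of a full fractionation history
#'
#' A history records, for each WGD generation `i`, the vector
#' `a^(i) = (a_0, ..., a_{r_i})` counting the genes of which exactly
#' `j` of the `r_i` copies survive to the next generation.  Its
#' probability is the product over generations of the multinomial term
#' `choose(M_i; a_0, ..., a_r) * prod_j u_j^{a_j}`.  Summed over all
#' histories consistent with `M1` this yields 1.
#'
#' @param schedule A [event_schedule()].
#' @param a A list with one integer vector per WGD generation, the
#'   `j = 0, ..., r_i` survivor-count table; must satisfy the population
#'   recursion `M_{i+1} = sum(j * a^(i))`.
#' @return The probability of the history.
#' @examples
#' s <- event_schedule(1, wgd_event(10, c(0, 0.4, 0.6)))
#' history_probability(s, list(c(0, 0, 1)))  # 0.6
#' @export
history_probability <- function(schedule, a) {
  check_schedule(schedule)
  survs <- wgd_survivals(schedule)
  if (!is.list(a) || length(a) != length(survs))
    stop_wgdfrac("`a` must be a list with one survivor-count vector per WGD generation")
  M <- schedule$M1
  p <- 1
  for (i in seq_along(survs)) {
    d <- survs[[i]]
    ai <- a[[i]]
    if (length(ai) != d$r + 1L || any(ai < 0) || any(ai != round(ai)))
      stop_wgdfrac(sprintf("a[[%d]] must be %d non-negative integers", i, d$r + 1L))
    if (sum(ai) != M)
      stop_wgdfrac(sprintf("a[[%d]] is inconsistent: sums to %d but M_%d = %d",
                           i, sum(ai), i, M))
    # multinomial coefficient times the survival probabilities, u_0 term included
    p <- p * exp(lgamma(M + 1) - sum(lgamma(ai + 1))) * prod(d$u^ai)
    M <- sum(seq(0L, d$r) * ai)
  }
  p
}

new_pair_counts <- function(tbl, unpaired, total_genes, simulated = FALSE) {
  structure(tbl, class = c("wgd_pair_counts", class(tbl)),
            unpaired = unpaired, total_genes = total_genes, simulated = simulated)
}

#' @export
print.wgd_pair_counts <- function(x, ...) {
  cat(sprintf("<wgd_pair_counts>%s unpaired = %g, total genes = %g\n",
              if (attr(x, "simulated")) " (simulated)" else " (expected)",
              attr(x, "unpaired"), attr(x, "total_genes")))
  NextMethod()
}

#' Unpaired-gene and total-gene accessors
#'
#' @param x A pair-count summary from [expected_paralog_pairs()],
#'   [expected_ortholog_pairs()] or [count_pairs()].
#' @return A single count.
#' @export
unpaired_count <- function(x) attr(x, "unpaired")

#' @rdname unpaired_count
#' @export
total_genes <- function(x) attr(x, "total_genes")

#' Expected paralog pair counts by event of origin
#'
#' For each WGD generation `i`, the expected number of observed gene
#' pairs whose most recent common ancestor was replaced at that event
#' (the *i*-pairs):
#' `E(N_i) = M1 * prod_{j<i} mu_j * c_i * prod_{j>i} mu_j^2`, where
#' `c_i = sum_{k>=2} choose(k, 2) u_k^(i)` is the expected surviving
#' pairs created per gene and the squared factor reflects independent
#' descent of the two pair members.  With ploidy 2 throughout this
#' reduces to `prod_{j<i}(1+u_2^(j)) u_2^(i) prod_{j>i}(1+u_2^(j))^2`,
#' and with ploidy 3 to the analogous form in `(1 + u_2 + 2 u_3)` and
#' `(u_2 + 3 u_3)`.
#'
#' @param schedule A [event_schedule()] (WGD events only).
#' @return A `wgd_pair_counts` tibble with columns `origin_event`,
#'   `time_My`, `kind` (`"paralog"`), `expected_pairs`, plus the
#'   expected unpaired-gene count and total gene count as attributes
#'   (see [unpaired_count()], [total_genes()]).
#' @examples
#' expected_paralog_pairs(event_schedule(1,
#'   wgd_event(10, c(0, 0.6, 0.4)), wgd_event(5, c(0, 0.6, 0.4))))
#' @export
expected_paralog_pairs <- function(schedule) {
  check_schedule(schedule)
  survs <- wgd_survivals(schedule)
  K <- length(survs)
  mus <- purrr::map_dbl(survs, .surv_mean)
  cps <- purrr::map_dbl(survs, .surv_pairs)
  en <- vapply(seq_len(K), function(i) {
    before <- prod(mus[seq_len(i - 1L)])
    after  <- if (i < K) prod(mus[(i + 1L):K]) else 1
    schedule$M1 * before * cps[i] * after^2
  }, numeric(1))
  tbl <- tibble::tibble(
    origin_event = seq_len(K),
    time_My = schedule$events$time[schedule$events$kind == "wgd"],
    kind = "paralog",
    expected_pairs = en
  )
  new_pair_counts(tbl, unpaired = expected_unpaired(schedule),
                  total_genes = expected_gene_count(schedule))
}

#' Expected count of unpaired genes
#'
#' A gene is unpaired when it has no surviving WGD-generated partner,
#' i.e. its lineage kept exactly one survivor at every generation:
#' `E(M*) = M1 * prod_i u_1^(i)`.  Exact under the no-lineage-extinction
#' constraint `u_0 = 0`; with `u_0 > 0` side-branch extinctions can
#' leave additional singletons that this product does not count.
#'
#' @param schedule A [event_schedule()].
#' @return Expected unpaired-gene count.
#' @examples
#' expected_unpaired(event_schedule(1000,
#'   wgd_event(10, c(0, 0.7, 0.3)), wgd_event(5, c(0, 0.5, 0.5))))  # 350
#' @export
expected_unpaired <- function(schedule) {
  check_schedule(schedule)
  schedule$M1 * prod(purrr::map_dbl(wgd_survivals(schedule), function(d) d$u[2]))
}

#' Expected ortholog pair counts by event of origin
#'
#' Ortholog pairs are observed pairs with one member in each daughter
#' genome.  The speciation event contributes one copy per genome; its
#' survival vector `(u_0, u_1, u_2)` gives the per-genome marginal copy
#' expectation `m = u_1/2 + u_2` and the joint both-genome survival
#' `u_2`.  With shared pre-speciation WGDs `j = 1..s-1` (means `mu_j`,
#' pair constants `c_j`) and post-speciation WGD mean products `P_A`,
#' `P_B`:
#' \itemize{
#'   \item `E(O_i) = M1 prod_{j<i} mu_j c_i prod_{i<j<s} mu_j^2 * 2 m^2 P_A P_B`
#'     for `i < s` (each pre-speciation pair yields cross-genome pairs
#'     through either member in either genome, hence the factor 2);
#'   \item `E(O_s) = M1 prod_{j<s} mu_j * u_2 * P_A P_B` (an s-pair
#'     requires both speciation copies of the same gene to survive).
#' }
#' With full survival at speciation (`u_2 = 1`) the constants reduce to
#' the familiar 1/2 and 1/4 in front of `(1+u)^2`-style factors.
#'
#' @param scenario A [speciation_scenario()].
#' @return A `wgd_pair_counts` tibble (kind `"ortholog"`), origins
#'   `1..s` with `s` the speciation generation.
#' @export
expected_ortholog_pairs <- function(scenario) {
  check_scenario(scenario)
  survs <- scenario_shared_wgds(scenario)
  mus <- purrr::map_dbl(survs, .surv_mean)
  cps <- purrr::map_dbl(survs, .surv_pairs)
  K <- length(survs)                     # s - 1 shared WGDs; speciation is generation K + 1
  sp <- speciation_survival(scenario)
  m_marg  <- sp$u[2] / 2 + sp$u[3]
  u_joint <- sp$u[3]
  PA <- prod(purrr::map_dbl(scenario_branch_wgds(scenario$branch_a), .surv_mean))
  PB <- prod(purrr::map_dbl(scenario_branch_wgds(scenario$branch_b), .surv_mean))
  eo <- vapply(seq_len(K), function(i) {
    before  <- prod(mus[seq_len(i - 1L)])
    between <- if (i < K) prod(mus[(i + 1L):K]) else 1
    scenario$M1 * before * cps[i] * between^2 * 2 * m_marg^2 * PA * PB
  }, numeric(1))
  eo_s <- scenario$M1 * prod(mus) * u_joint * PA * PB
  tbl <- tibble::tibble(
    origin_event = seq_len(K + 1L),
    time_My = scenario$shared$time,
    kind = "ortholog",
    expected_pairs = c(eo, eo_s)
  )
  total <- scenario$M1 * prod(mus) * m_marg * (PA + PB)  # genes summed over both genomes
  new_pair_counts(tbl, unpaired = expected_ortholog_unpaired(scenario),
                  total_genes = total)
}

#' Expected count of ortholog-unpaired genes
#'
#' An observed gene of genome A is ortholog-unpaired when genome B
#' retains no observed descendant of its generation-1 root (and vice
#' versa), since any two cross-genome genes from the same root pair at
#' some shared generation.  Writing `G` for the probability generating
#' function of the gene count at the speciation generation (the
#' composition of the shared events' survival pgfs), `z_B` for the
#' probability that a single post-speciation B copy leaves no observed
#' descendant (composition of branch-B pgfs evaluated at 0), and per
#' speciation survival `(u_0, u_1, u_2)`:
#' \itemize{
#'   \item `beta_B = u_0 + u_1 (1 + z_B)/2 + u_2 z_B` — one
#'     generation-s gene leaves nothing observed in B;
#'   \item `alpha_A = (u_1/2) w_A + u_2 w_A z_B` — expected observed A
#'     descendants of one generation-s gene, jointly with no B
#'     survivor, `w_A` the branch-A mean-product;
#'   \item `E = M1 * (alpha_A * G'(beta_B) + alpha_B * G'(beta_A))`.
#' }
#' This is the scenario analogue of the unpaired-gene expectation and
#' provides the optional extra multinomial cell in
#' [estimate_survival()].
#'
#' @param scenario A [speciation_scenario()].
#' @return Expected count of observed genes (over both genomes) with no
#'   cross-genome partner.
#' @export
expected_ortholog_unpaired <- function(scenario) {
  check_scenario(scenario)
  survs <- scenario_shared_wgds(scenario)
  sp <- speciation_survival(scenario)
  pgf <- function(d, x) sum(d$u * x^(0:d$r))
  pgf_deriv <- function(d, x) sum(seq_len(d$r) * d$u[-1] * x^(seq_len(d$r) - 1L))
  # z: extinction-by-observation probability of one post-speciation copy
  z_branch <- function(branch_survs) {
    z <- 0
    for (d in rev(branch_survs)) z <- pgf(d, z)
    z
  }
  zA <- z_branch(scenario_branch_wgds(scenario$branch_a))
  zB <- z_branch(scenario_branch_wgds(scenario$branch_b))
  wA <- prod(purrr::map_dbl(scenario_branch_wgds(scenario$branch_a), .surv_mean))
  wB <- prod(purrr::map_dbl(scenario_branch_wgds(scenario$branch_b), .surv_mean))
  u0 <- sp$u[1]; u1 <- sp$u[2]; u2 <- sp$u[3]
  beta  <- function(z) u0 + u1 * (1 + z) / 2 + u2 * z
  alpha <- function(w_own, z_other) (u1 / 2) * w_own + u2 * w_own * z_other
  # G'(x) for the pgf of the speciation-generation gene count (M1 = 1 root),
  # by the chain rule through the shared events
  G_deriv <- function(x) {
    vals <- x
    if (length(survs)) {
      ys <- numeric(length(survs))   # ys[i] = argument seen by event i's pgf
      y <- x
      for (i in rev(seq_along(survs))) {
        ys[i] <- y
        y <- pgf(survs[[i]], y)
      }
      prod(vapply(seq_along(survs), function(i)
        pgf_deriv(survs[[i]], ys[i]), numeric(1)))
    } else 1
  }
  scenario$M1 * (alpha(wA, zB) * G_deriv(beta(zB)) +
                 alpha(wB, zA) * G_deriv(beta(zA)))
}

#' Write a pair-count report
#'
#' Serialises a pair-count summary to tab-separated text
#' (columns `origin_event`, `time_My`, `expected_pairs`, `kind`),
#' with the unpaired and total-gene counts in commented header lines.
#'
#' @param x A `wgd_pair_counts` object.
#' @param path Output file path.
#' @param header Named character vector of extra `# key: value` header
#'   lines (e.g. the run configuration).
#' @return `path`, invisibly.
#' @export
write_pair_report <- function(x, path, header = character()) {
  if (!inherits(x, "wgd_pair_counts"))
    stop_wgdfrac("`x` must be a wgd_pair_counts summary")
  hdr <- c(header,
           unpaired = format(attr(x, "unpaired")),
           total_genes = format(attr(x, "total_genes")))
  tbl <- tibble::as_tibble(x)[, c("origin_event", "time_My", "expected_pairs", "kind")]
  write_tsv_with_header(tbl, path, hdr)
  invisible(path)
}
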