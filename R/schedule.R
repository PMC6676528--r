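#' Per-event survival distribution
#'
#' After a whole-genome event of ploidy `r`, every gene is replaced by `r`
#' copies; `u[k+1]` is the probability that exactly `k` of them survive
#' until the next event (fractionation acting over the inter-event
#' interval).  This is the offspring distribution of the underlying
#' Galton-Watson process, reinterpreted as survival.
#'
#' @param r Integer ploidy of the event, `>= 2` (2 = doubling, 3 = tripling).
#' @param u Numeric vector of length `r + 1` giving `P(k survivors)` for
#'   `k = 0, ..., r`.  Must lie in `[0, 1]` and sum to 1 within `1e-9`
#'   (renormalised if within tolerance, rejected otherwise).
#' @param no_extinction If `TRUE`, enforce the "no lineage extinction"
#'   constraint `u[1] == 0` (at least one copy always survives).
#'
#' @return An object of class `wgd_survival`: a list with elements `r`
#'   and `u` (renormalised).
#' @examples
#' survival_dist(2, c(0, 0.3, 0.7))
#' survival_dist(3, c(0, 0.76, 0.2, 0.04), no_extinction = TRUE)
#' @export
survival_dist <- function(r, u, no_extinction = FALSE) {
  if (length(r) != 1L || !is.numeric(r) || is.na(r) || r != round(r) || r < 2)
    stop_wgdfrac("`r` must be a single integer ploidy >= 2")
  r <- as.integer(r)
  if (!is.numeric(u) || anyNA(u))
    stop_wgdfrac("`u` must be a numeric probability vector without NAs")
  if (length(u) != r + 1L)
    stop_wgdfrac(sprintf("`u` must have length r + 1 = %d, got %d", r + 1L, length(u)))
  if (any(u < 0) || any(u > 1))
    stop_wgdfrac("all survival probabilities must lie in [0, 1]")
  s <- sum(u)
  if (abs(s - 1) > 1e-9)
    stop_wgdfrac(sprintf("survival probabilities must sum to 1 (got %.12f)", s))
  u <- u / s
  if (no_extinction && u[1] != 0)
    stop_wgdfrac("no_extinction = TRUE requires u_0 = 0")
  structure(list(r = r, u = as.numeric(u)), class = "wgd_survival")
}

#' @export
print.wgd_survival <- function(x, ...) {
  cat(sprintf("<wgd_survival> ploidy r = %d, u = (%s)\n",
              x$r, paste(format(x$u, digits = 4), collapse = ", ")))
  invisible(x)
}

#' Mean and variance of the per-gene survivor count
#'
#' The first two moments of the survival distribution: the mean
#' `mu = sum(k * u_k)` is the expected number of surviving copies per gene
#' per event, the quantity that drives all expected-count formulas.
#'
#' @param d A [survival_dist()] object.
#' @return A one-row tibble with columns `mean` and `variance`.
#' @examples
#' derive_offspring_moments(survival_dist(2, c(0, 0.5, 0.5)))
#' @export
derive_offspring_moments <- function(d) {
  d <- as_survival(d)
  k <- 0:d$r
  mu <- sum(k * d$u)
  tibble::tibble(mean = mu, variance = sum((k - mu)^2 * d$u))
}

# internal scalar versions, used throughout the expectation formulas
.surv_mean <- function(d) sum(seq(0L, d$r) * d$u)
# expected number of surviving pairs created per gene at the event:
# sum over k >= 2 of choose(k, 2) u_k
.surv_pairs <- function(d) sum(choose(seq(0L, d$r), 2) * d$u)

as_survival <- function(d) {
  if (inherits(d, "wgd_survival")) return(d)
  stop_wgdfrac("expected a `wgd_survival` object; see survival_dist()")
}

#' Extinction probability of a gene lineage
#'
#' Probability that the descendant population of a single gene eventually
#' dies out when the same survival distribution applies at every
#' generation: the smallest root in `[0, 1]` of the generating-function
#' fixed point `f(s) = s`.  For ploidy 2 the quadratic has roots
#' `{1, (1 - u_1)/u_2 - 1}` so the closed form is used; higher ploidies
#' use a bracketed numeric solver (tolerance `1e-12`).  Extinction is
#' certain iff the mean survivor count is `<= 1`; for `r = 2` that is
#' exactly the condition `u_0 >= u_2`.
#'
#' @param d A [survival_dist()] object.
#' @return A single probability.
#' @examples
#' extinction_probability(survival_dist(2, c(0.25, 0.25, 0.5)))  # 0.5
#' @export
extinction_probability <- function(d) {
  d <- as_survival(d)
  u <- d$u
  if (u[1] == 0) return(0)                       # f(0) = 0: no extinction possible
  mu <- .surv_mean(d)
  if (mu <= 1) return(1)                         # (sub)critical process
  if (d$r == 2L) {
    if (u[3] == 0) return(1)                     # degenerate: mu <= 1 anyway
    return(min(1, (1 - u[2]) / u[3] - 1))        # = u0/u2, the quadratic's small root
  }
  f_gap <- function(s) sum(u * s^(0:d$r)) - s
  # supercritical: f(0) = u0 > 0 and f(s) < s just below 1, so a sign
  # change brackets the unique root in (0, 1)
  stats::uniroot(f_gap, lower = 0, upper = 1 - 1e-9, tol = 1e-12,
                 extendInt = "no")$root
}

#' Whole-genome duplication event
#'
#' @param time Event time in millions of years (My) before present, `>= 0`.
#' @param survival A [survival_dist()] object, or a bare numeric vector
#'   `u` (ploidy inferred from its length).
#' @return A list of class `wgd_event` used to build [event_schedule()].
#' @examples
#' wgd_event(71, survival_dist(3, c(0, 0.76, 0.2, 0.04)))
#' @export
wgd_event <- function(time, survival) {
  if (is.numeric(survival) && !inherits(survival, "wgd_survival"))
    survival <- survival_dist(length(survival) - 1L, survival)
  survival <- as_survival(survival)
  check_time(time)
  structure(list(kind = "wgd", time = as.numeric(time), survival = survival),
            class = "wgd_event")
}

#' Speciation event
#'
#' A speciation copies every gene once into each daughter genome, so its
#' ploidy is fixed at 2 (one copy per lineage).  Its survival vector
#' `(u_0, u_1, u_2)` governs joint survival of the two copies over the
#' interval following speciation: `u_2` both survive, `u_1` exactly one
#' (equally likely in either genome).
#'
#' @inheritParams wgd_event
#' @param survival A length-3 survival vector or `wgd_survival` with `r = 2`.
#' @export
speciation_event <- function(time, survival = c(0, 0, 1)) {
  if (is.numeric(survival) && !inherits(survival, "wgd_survival"))
    survival <- survival_dist(2L, survival)
  survival <- as_survival(survival)
  if (survival$r != 2L)
    stop_wgdfrac("speciation events have ploidy fixed at 2 (one copy per daughter genome)")
  check_time(time)
  structure(list(kind = "speciation", time = as.numeric(time), survival = survival),
            class = "wgd_event")
}

check_time <- function(time) {
  if (length(time) != 1L || !is.numeric(time) || is.na(time) || time < 0)
    stop_wgdfrac("`time` must be a single non-negative number (My before present)")
}

events_to_tbl <- function(events) {
  tibble::tibble(
    kind = purrr::map_chr(events, "kind"),
    time = purrr::map_dbl(events, "time"),
    r = purrr::map_int(events, function(e) if (is.null(e$survival)) NA_integer_ else e$survival$r),
    u = purrr::map(events, function(e) if (is.null(e$survival)) NULL else e$survival$u)
  )
}

#' Event schedule for a single genome
#'
#' An ordered series of whole-genome events acting on an initial
#' population of `M1` genes, ending at the present-day observation.
#' Events are ordered from oldest to most recent; times (My before
#' present) must strictly decrease.  Generation indices are derived:
#' the i-th WGD is generation `i`, the observation generation `n`.
#'
#' @param M1 Initial gene count at generation 1, `>= 1`.
#' @param ... [wgd_event()] objects, oldest first.
#' @param obs_time Observation time in My before present (default 0,
#'   the present).
#' @return An object of class `wgd_schedule`: a list with `M1` and an
#'   `events` tibble (`kind`, `time`, `r`, `u` list-column), observation
#'   last.
#' @examples
#' event_schedule(1000,
#'   wgd_event(100, c(0, 0.7, 0.3)),
#'   wgd_event(40, c(0, 0.5, 0.5)))
#' @export
event_schedule <- function(M1, ..., obs_time = 0) {
  events <- list(...)
  if (length(events) == 1L && is.list(events[[1]]) && !inherits(events[[1]], "wgd_event"))
    events <- events[[1]]
  if (!all(purrr::map_lgl(events, inherits, "wgd_event")))
    stop_wgdfrac("all events must be wgd_event()/speciation_event() objects")
  if (any(purrr::map_chr(events, "kind") == "speciation"))
    stop_wgdfrac("speciation events belong in speciation_scenario(), not event_schedule()")
  if (length(M1) != 1L || !is.numeric(M1) || is.na(M1) || M1 < 1 || M1 != round(M1))
    stop_wgdfrac("`M1` must be a single integer >= 1")
  check_time(obs_time)
  tbl <- dplyr::bind_rows(
    events_to_tbl(events),
    tibble::tibble(kind = "observation", time = as.numeric(obs_time),
                   r = NA_integer_, u = list(NULL))
  )
  if (any(diff(tbl$time) >= 0))
    stop_wgdfrac("event times must strictly decrease toward the present")
  structure(list(M1 = as.numeric(M1), events = tbl), class = "wgd_schedule")
}

#' @export
print.wgd_schedule <- function(x, ...) {
  cat(sprintf("<wgd_schedule> M1 = %g, %d event(s) + observation\n",
              x$M1, n_wgd(x)))
  print(x$events)
  invisible(x)
}

# number of WGD events (generations 1 .. n-1)
n_wgd <- function(schedule) sum(schedule$events$kind == "wgd")

# survival_dist objects of the WGD rows, in generation order
wgd_survivals <- function(schedule) {
  rows <- which(schedule$events$kind == "wgd")
  purrr::map(rows, function(i)
    survival_dist(schedule$events$r[i], schedule$events$u[[i]]))
}

#' Speciation scenario: shared history plus two diverging genomes
#'
#' A shared pre-speciation [event_schedule()]-like prefix ending in a
#' [speciation_event()], after which genomes A and B evolve
#' independently under their own WGD lists until each is observed at the
#' present.
#'
#' @param M1 Initial gene count in the ancestral genome.
#' @param shared List of [wgd_event()]s before speciation, oldest first
#'   (may be empty).
#' @param speciation A [speciation_event()].
#' @param branch_a,branch_b Lists of post-speciation [wgd_event()]s for
#'   each genome (possibly empty).
#' @param obs_time_a,obs_time_b Observation times (My before present)
#'   for the two genomes; default 0.
#' @return An object of class `wgd_scenario` with fields `M1`, `shared`
#'   (events tibble incl. the speciation row), `branch_a`, `branch_b`
#'   (events tibbles each ending in an observation row).
#' @examples
#' speciation_scenario(100,
#'   shared = list(wgd_event(100, c(0, 0.8, 0.2))),
#'   speciation = speciation_event(60, c(0, 0.3, 0.7)),
#'   branch_a = list(wgd_event(30, c(0, 0.25, 0.75))))
#' @export
speciation_scenario <- function(M1, shared = list(), speciation,
                                branch_a = list(), branch_b = list(),
                                obs_time_a = 0, obs_time_b = 0) {
  if (length(M1) != 1L || !is.numeric(M1) || is.na(M1) || M1 < 1 || M1 != round(M1))
    stop_wgdfrac("`M1` must be a single integer >= 1")
  if (!inherits(speciation, "wgd_event") || speciation$kind != "speciation")
    stop_wgdfrac("`speciation` must be a speciation_event()")
  ok_wgd <- function(evs) all(purrr::map_lgl(evs, function(e)
    inherits(e, "wgd_event") && e$kind == "wgd"))
  if (!ok_wgd(shared) || !ok_wgd(branch_a) || !ok_wgd(branch_b))
    stop_wgdfrac("`shared`, `branch_a`, `branch_b` must be lists of wgd_event()s")
  check_time(obs_time_a); check_time(obs_time_b)

  shared_tbl <- dplyr::bind_rows(events_to_tbl(shared), events_to_tbl(list(speciation)))
  if (any(diff(shared_tbl$time) >= 0))
    stop_wgdfrac("pre-speciation event times must strictly decrease toward the present")
  branch_tbl <- function(evs, obs_time) {
    tbl <- dplyr::bind_rows(
      events_to_tbl(evs),
      tibble::tibble(kind = "observation", time = as.numeric(obs_time),
                     r = NA_integer_, u = list(NULL)))
    if (any(tbl$time >= speciation$time))
      stop_wgdfrac("post-speciation events must be more recent than the speciation")
    if (any(diff(tbl$time) >= 0))
      stop_wgdfrac("post-speciation event times must strictly decrease toward the present")
    tbl
  }
  structure(list(M1 = as.numeric(M1),
                 shared = shared_tbl,
                 branch_a = branch_tbl(branch_a, obs_time_a),
                 branch_b = branch_tbl(branch_b, obs_time_b)),
            class = "wgd_scenario")
}

#' @export
print.wgd_scenario <- function(x, ...) {
  cat(sprintf("<wgd_scenario> M1 = %g; %d shared WGD(s), speciation at %g My; %d WGD(s) in A, %d in B\n",
              x$M1, sum(x$shared$kind == "wgd"),
              x$shared$time[x$shared$kind == "speciation"],
              sum(x$branch_a$kind == "wgd"), sum(x$branch_b$kind == "wgd")))
  invisible(x)
}

# survival dist of the speciation row
speciation_survival <- function(scenario) {
  i <- which(scenario$shared$kind == "speciation")
  survival_dist(2L, scenario$shared$u[[i]])
}

scenario_shared_wgds <- function(scenario) {
  rows <- which(scenario$shared$kind == "wgd")
  purrr::map(rows, function(i) survival_dist(scenario$shared$r[i], scenario$shared$u[[i]]))
}

scenario_branch_wgds <- function(branch_tbl) {
  rows <- which(branch_tbl$kind == "wgd")
  purrr::map(rows, function(i) survival_dist(branch_tbl$r[i], branch_tbl$u[[i]]))
}

stop_wgdfrac <- function(msg) {
  rlang::abort(msg, class = "wgdfrac_error")
}
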