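# Inverting the pair-count expectations: from observed (or fitted) counts of
# pairs per origin event, recover the per-interval survival probabilities u by
# multinomial maximum likelihood on a schedule/scenario skeleton, and convert
# them to fractionation rates rho via u = exp(-rho * dt).

#' Maximum-likelihood survival probabilities from pair counts
#'
#' Treats the per-origin pair counts (plus, optionally, the
#' unpaired-gene count) as one multinomial draw whose cell
#' probabilities are the normalised expected counts of the skeleton
#' evaluated at candidate survival values, and maximises the likelihood
#' over the free `u` parameters.  One `u_2` is estimated per WGD (and
#' per speciation); triplings use the constraint `u_3 = u_2^2` — the
#' joint survival of two extra copies approximated by the product of
#' their individual survivals — and `u_0 = 0` is imposed by default
#' (droppable via `u0_zero = FALSE`, which adds one free `u_0` per
#' event).
#'
#' @param observed_counts Numeric vector of pair counts by origin event
#'   (oldest first), or a `wgd_pair_counts` tibble.  Fractional counts
#'   (e.g. `weight * n` from a mixture fit) are accepted.
#' @param skeleton A [event_schedule()] or [speciation_scenario()]
#'   fixing ploidies, event order and times; its `u` values are ignored
#'   (placeholders).
#' @param unpaired Optional unpaired-gene count, added as an extra
#'   multinomial cell through the `M1 * prod(u_1)` expectation
#'   (schedules) or [expected_ortholog_unpaired()] (scenarios); often
#'   required for identifiability.
#' @param u0_zero Impose the no-lineage-extinction constraint (default
#'   `TRUE`).
#' @param n_restarts Random restarts of the bounded quasi-Newton search
#'   (the likelihood can be flat when components overlap).
#' @param seed Seed for the restart draws.
#' @return An object of class `wgd_survival_fit`: list with `estimates`
#'   (tibble `event`, `kind`, `time_My`, `r`, `u2`, `u3`, `u0`),
#'   `loglik`, `converged`, `skeleton`, `counts`.
#' @examples
#' sk <- event_schedule(1, wgd_event(100, c(0, 0.5, 0.5)),
#'                      wgd_event(40, c(0, 0.5, 0.5)))
#' truth <- event_schedule(1000, wgd_event(100, c(0, 0.7, 0.3)),
#'                         wgd_event(40, c(0, 0.4, 0.6)))
#' cp <- expected_paralog_pairs(truth)
#' fit <- estimate_survival(cp$expected_pairs, sk,
#'                          unpaired = unpaired_count(cp))
#' fit$estimates$u2  # recovers 0.3, 0.6
#' @export
estimate_survival <- function(observed_counts, skeleton, unpaired = NULL,
                              u0_zero = TRUE, n_restarts = 10, seed = 1) {
  counts <- if (inherits(observed_counts, "wgd_pair_counts"))
    observed_counts$expected_pairs else as.numeric(observed_counts)
  if (any(counts < 0) || anyNA(counts)) stop_wgdfrac("counts must be non-negative")
  is_scen <- inherits(skeleton, "wgd_scenario")
  if (!is_scen) check_schedule(skeleton)

  ev <- skeleton_events(skeleton)        # tibble: kind, time, r (origin events only)
  n_events <- nrow(ev)
  if (length(counts) != n_events)
    stop_wgdfrac(sprintf("expected %d origin-event counts for this skeleton, got %d",
                         n_events, length(counts)))
  # free parameters: one u2 per event (+ one u0 per event if u0 is free)
  n_par <- n_events * (1L + as.integer(!u0_zero))
  n_cells <- length(counts) + as.integer(!is.null(unpaired))
  if (n_par > n_cells - 1L)
    stop_wgdfrac(sprintf(paste(
      "%d free survival parameters but only %d independent proportions",
      "(%d cells): supply the unpaired count or fix more parameters"),
      n_par, n_cells - 1L, n_cells))

  probs_fun <- function(par) {
    # par on logit scale; map into valid simplex region per event
    obj <- rebuild_with_u(skeleton, ev, par, u0_zero)
    e <- if (is_scen) expected_ortholog_pairs(obj) else expected_paralog_pairs(obj)
    cells <- e$expected_pairs
    if (!is.null(unpaired))
      cells <- c(cells, if (is_scen) expected_ortholog_unpaired(obj)
                        else expected_unpaired(obj))
    cells / sum(cells)
  }
  obs <- c(counts, if (!is.null(unpaired)) unpaired)
  negll <- function(par) {
    p <- probs_fun(par)
    if (any(!is.finite(p)) || any(p <= 0)) return(1e10)
    -sum(obs * log(p))
  }
  set.seed(seed)
  starts <- c(list(rep(0, n_par)),
              purrr::map(seq_len(max(n_restarts - 1L, 0L)),
                         function(i) stats::rnorm(n_par, 0, 1.5)))
  best <- NULL
  for (st in starts) {
    o <- tryCatch(stats::optim(st, negll, method = "BFGS",
                               control = list(maxit = 500, reltol = 1e-12)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop_wgdfrac("survival optimisation failed from every start")
  est <- u_from_par(ev, best$par, u0_zero)
  structure(list(estimates = est, loglik = -best$value,
                 converged = best$convergence == 0,
                 u0_zero = u0_zero, skeleton = skeleton,
                 counts = obs, n_restarts = n_restarts),
            class = "wgd_survival_fit")
}

# origin events of a skeleton as a flat tibble (WGDs, plus speciation last
# for scenarios)
skeleton_events <- function(x) {
  if (inherits(x, "wgd_scenario")) {
    tibble::tibble(kind = x$shared$kind, time = x$shared$time, r = x$shared$r)
  } else {
    sel <- x$events$kind == "wgd"
    tibble::tibble(kind = "wgd", time = x$events$time[sel], r = x$events$r[sel])
  }
}

# map optimiser parameters (logit scale) to per-event survival vectors.
# For triplings the u3 = u2^2 constraint needs u2 + u2^2 <= 1, so u2 is
# scaled into (0, (sqrt(5)-1)/2); with u0 free, u0 takes a fraction of the
# probability mass left after u2 (+ u3), keeping u1 >= 0 by construction.
u_from_par <- function(ev, par, u0_zero) {
  n_events <- nrow(ev)
  cap <- ifelse(!is.na(ev$r) & ev$r == 3L, (sqrt(5) - 1) / 2, 1)
  u2 <- cap * stats::plogis(par[seq_len(n_events)])
  u3 <- ifelse(!is.na(ev$r) & ev$r == 3L, u2^2, NA_real_)
  rest <- 1 - u2 - dplyr::coalesce(u3, 0)
  u0 <- if (u0_zero) rep(0, n_events) else
    rest * stats::plogis(par[n_events + seq_len(n_events)])
  out <- ev
  out$event <- seq_len(n_events)
  out$u2 <- u2
  out$u3 <- u3
  out$u0 <- u0
  out[, c("event", "kind", "time", "r", "u0", "u2", "u3")]
}

# rebuild the schedule/scenario with candidate survival values
rebuild_with_u <- function(skeleton, ev, par, u0_zero) {
  est <- u_from_par(ev, par, u0_zero)
  mk_surv <- function(i) {
    r <- est$r[i]; u2 <- est$u2[i]; u0 <- est$u0[i]
    if (!is.na(r) && r == 3L) {
      u3 <- u2^2
      u1 <- 1 - u0 - u2 - u3
      if (u1 < 0) return(NULL)
      survival_dist(3L, c(u0, u1, u2, u3))
    } else {
      u1 <- 1 - u0 - u2
      if (u1 < 0) return(NULL)
      survival_dist(2L, c(u0, u1, u2))
    }
  }
  if (inherits(skeleton, "wgd_scenario")) {
    wgd_rows <- which(est$kind == "wgd")
    sp_row <- which(est$kind == "speciation")
    shared <- purrr::map(wgd_rows, function(i) {
      s <- mk_surv(i); if (is.null(s)) stop_wgdfrac("infeasible u")
      wgd_event(est$time[i], s)
    })
    sp_s <- mk_surv(sp_row)
    if (is.null(sp_s)) stop_wgdfrac("infeasible u")
    ba <- scenario_wgd_list(skeleton$branch_a)
    bb <- scenario_wgd_list(skeleton$branch_b)
    speciation_scenario(skeleton$M1, shared = shared,
                        speciation = speciation_event(est$time[sp_row], sp_s),
                        branch_a = ba, branch_b = bb,
                        obs_time_a = utils::tail(skeleton$branch_a$time, 1),
                        obs_time_b = utils::tail(skeleton$branch_b$time, 1))
  } else {
    evs <- purrr::map(seq_len(nrow(est)), function(i) {
      s <- mk_surv(i); if (is.null(s)) stop_wgdfrac("infeasible u")
      wgd_event(est$time[i], s)
    })
    event_schedule(skeleton$M1, evs,
                   obs_time = skeleton$events$time[skeleton$events$kind == "observation"])
  }
}

scenario_wgd_list <- function(branch_tbl) {
  rows <- which(branch_tbl$kind == "wgd")
  purrr::map(rows, function(i)
    wgd_event(branch_tbl$time[i], survival_dist(branch_tbl$r[i], branch_tbl$u[[i]])))
}

#' @export
print.wgd_survival_fit <- function(x, ...) {
  cat(sprintf("<wgd_survival_fit> logLik = %.3f (%s)\n", x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  print(x$estimates)
  invisible(x)
}

#' @rdname estimate_survival
#' @param x A `wgd_survival_fit`.
#' @param ... Unused.
#' @export
tidy.wgd_survival_fit <- function(x, ...) x$estimates

#' @rdname estimate_survival
#' @export
glance.wgd_survival_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, converged = x$converged,
                 n_events = nrow(x$estimates), u0_zero = x$u0_zero)
}

#' Fractionation rate over an inter-event interval
#'
#' Under continuous exponential loss `u(t) = exp(-rho * t)`, the rate
#' implied by survival `u` across the interval from `t_start` to
#' `t_end` My before present is `rho = -log(u) / (t_start - t_end)`.
#'
#' @param u Survival probabilities in `(0, 1]`.
#' @param t_start Interval start (older), My before present.
#' @param t_end Interval end (more recent), My before present.
#' @return Rates per My (vectorised).
#' @examples
#' fractionation_rate(exp(-1), 10, 0)  # 0.1
#' @export
fractionation_rate <- function(u, t_start, t_end) {
  if (any(u <= 0 | u > 1)) stop_wgdfrac("`u` must lie in (0, 1]")
  dt <- t_start - t_end
  if (any(dt <= 0)) stop_wgdfrac("interval must have positive length (t_start > t_end)")
  -log(u) / dt
}

#' Survival and rate table from a survival fit
#'
#' Converts fitted per-event survival probabilities into per-interval
#' fractionation rates.  The interval of event `i` runs from its time
#' to the next event's time (the next origin event, or for the last
#' shared event of a scenario the first post-speciation event — the
#' first interruption of that fractionation regime — or the
#' observation).
#'
#' @param fit A `wgd_survival_fit` from [estimate_survival()].
#' @return A `wgd_rate_estimates` tibble: `event`, `kind`,
#'   `interval_start_My`, `interval_end_My`, `u`, `rho_per_My`,
#'   `constraint`.
#' @export
rate_estimates <- function(fit) {
  if (!inherits(fit, "wgd_survival_fit")) stop_wgdfrac("`fit` must come from estimate_survival()")
  est <- fit$estimates
  sk <- fit$skeleton
  next_time <- if (inherits(sk, "wgd_scenario")) {
    first_a <- sk$branch_a$time[1]
    first_b <- sk$branch_b$time[1]
    c(est$time[-1], max(first_a, first_b))
  } else {
    c(est$time[-1], sk$events$time[sk$events$kind == "observation"])
  }
  out <- tibble::tibble(
    event = est$event, kind = est$kind,
    interval_start_My = est$time, interval_end_My = next_time,
    u = est$u2,
    rho_per_My = fractionation_rate(est$u2, est$time, next_time),
    constraint = ifelse(!is.na(est$r) & est$r == 3L, "u3=u2^2",
                        ifelse(est$u0 == 0, "u0=0", "none"))
  )
  structure(out, class = c("wgd_rate_estimates", class(out)))
}

#' Amplification factor from paired pair-counts
#'
#' A post-speciation WGD in species A multiplies every ortholog-pair
#' expectation in comparisons against A by `F_A = prod(1 + u^A)`.  With
#' pair counts for the same set of events measured against A and
#' against an outgroup free of post-speciation WGDs, `F_A` is the slope
#' of the least-squares regression through the origin of the counts
#' versus A on the counts versus the outgroup.
#'
#' @param pair_counts_vs_A Pair counts in comparisons with species A.
#' @param pair_counts_vs_outgroup Matching counts in comparisons with
#'   the outgroup.
#' @return A one-row tibble `F_hat`, `se`, `n`.
#' @examples
#' estimate_amplification(c(2, 4, 8), c(1, 2, 4))  # slope 2
#' @export
estimate_amplification <- function(pair_counts_vs_A, pair_counts_vs_outgroup) {
  y <- as.numeric(pair_counts_vs_A)
  x <- as.numeric(pair_counts_vs_outgroup)
  if (length(y) != length(x) || length(y) < 2)
    stop_wgdfrac("need paired counts across at least two comparisons")
  if (all(x == 0)) stop_wgdfrac("all outgroup counts are zero; slope undefined")
  # least squares through the origin; SE from the residual variance
  b <- sum(x * y) / sum(x^2)
  s2 <- sum((y - b * x)^2) / (length(y) - 1L)
  tibble::tibble(F_hat = b, se = sqrt(s2 / sum(x^2)), n = length(y))
}

#' Cross-comparison consistency of fractionation rates
#'
#' The model presumes a single fractionation rate per time interval
#' regardless of which descendant genome is examined
#' (`rho = rho_A = rho_B`).  Given rate estimates from several
#' comparisons sharing intervals, reports the spread per interval and
#' flags intervals whose coefficient of variation exceeds the
#' threshold.
#'
#' @param estimates A data frame with columns `comparison`, `interval`
#'   (a shared interval identifier), `rho`.
#' @param cv_threshold Flagging threshold on the coefficient of
#'   variation (sd/mean) of `rho` within an interval.
#' @return A tibble per interval: `interval`, `n`, `mean_rho`,
#'   `min_rho`, `max_rho`, `range`, `cv`, `flagged`.
#' @export
rate_consistency_report <- function(estimates, cv_threshold = 0.2) {
  need <- c("comparison", "interval", "rho")
  if (!is.data.frame(estimates) || !all(need %in% names(estimates)))
    stop_wgdfrac("`estimates` needs columns comparison, interval, rho")
  if (length(unique(estimates$comparison)) < 2)
    stop_wgdfrac("need rate estimates from at least two comparisons")
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(estimates), .data$interval),
    n = dplyr::n(),
    mean_rho = mean(.data$rho),
    min_rho = min(.data$rho),
    max_rho = max(.data$rho),
    range = max(.data$rho) - min(.data$rho),
    cv = ifelse(mean(.data$rho) > 0, stats::sd(.data$rho) / mean(.data$rho), 0),
    .groups = "drop")
  out$cv[is.na(out$cv)] <- 0
  out$flagged <- out$cv > cv_threshold
  out
}
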