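# Shared builders for test schedules and scenarios.

u2_dist <- function(u2, u0 = 0) survival_dist(2L, c(u0, 1 - u0 - u2, u2))
u3_dist <- function(u2, u3, u0 = 0) survival_dist(3L, c(u0, 1 - u0 - u2 - u3, u2, u3))

# doubling schedule from a vector of u2 values (times equally spaced)
doubling_schedule <- function(u2s, M1 = 1, t_first = 100) {
  times <- seq(t_first, t_first / (length(u2s) + 1), length.out = length(u2s))
  event_schedule(M1, purrr::map2(times, u2s, function(t, u) wgd_event(t, u2_dist(u))))
}

# binomial speciation survival: both copies survive independently with
# marginal probability m (the independent-genomes fractionation reading)
binom_speciation <- function(time, m) {
  speciation_event(time, c((1 - m)^2, 2 * m * (1 - m), m^2))
}
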