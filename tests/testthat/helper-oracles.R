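# Independent brute-force oracles: exhaustive enumeration of fractionation
# histories, weighted by multinomial probabilities computed with
# stats::dmultinom (not with the package's own history_probability).

# all length-`parts` non-negative integer vectors summing to m
compositions <- function(m, parts) {
  if (parts == 1L) return(matrix(m, 1L, 1L))
  do.call(rbind, lapply(0:m, function(k) cbind(k, compositions(m - k, parts - 1L))))
}

# E over all histories of `terminal(M_n)`, starting from M genes at event `i`
enum_expect <- function(M1, survs, terminal) {
  rec <- function(M, i) {
    if (i > length(survs)) return(terminal(M))
    d <- survs[[i]]
    comp <- compositions(M, d$r + 1L)
    total <- 0
    for (row in seq_len(nrow(comp))) {
      a <- comp[row, ]
      p <- stats::dmultinom(a, prob = d$u)
      if (p == 0) next
      total <- total + p * rec(sum((0:d$r) * a), i + 1L)
    }
    total
  }
  rec(M1, 1L)
}

enum_E_Mn <- function(M1, survs) enum_expect(M1, survs, identity)

# P(exactly one observed gene) -- the unpaired-gene probability under u0 = 0
enum_P_single <- function(survs) enum_expect(1L, survs, function(M) as.numeric(M == 1L))

# E(pairs created at event i and surviving one step), by enumeration up to i
enum_E_pairs_created <- function(M1, survs, i) {
  rec <- function(M, g) {
    d <- survs[[g]]
    comp <- compositions(M, d$r + 1L)
    total <- 0
    for (row in seq_len(nrow(comp))) {
      a <- comp[row, ]
      p <- stats::dmultinom(a, prob = d$u)
      if (p == 0) next
      contrib <- if (g == i) sum(choose(0:d$r, 2) * a)
                 else rec(sum((0:d$r) * a), g + 1L)
      total <- total + p * contrib
    }
    total
  }
  rec(M1, 1L)
}

# E(N_i): pairs created at i, each member amplified independently to the end
enum_E_Ni <- function(M1, survs, i) {
  amp <- if (i < length(survs)) enum_E_Mn(1L, survs[(i + 1L):length(survs)]) else 1
  enum_E_pairs_created(M1, survs, i) * amp^2
}

# mean and 3-standard-error half-width helpers for simulator comparisons
mc_mean_se <- function(x) c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
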