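# Shared fixtures, built once per test run.

hacat <- pathway_params("hacat_like")

# independent equilibrium oracle for the minimal model: bisection on
# f(x) = K1*L*(R1-x)*(R2-x) - x, which is strictly decreasing on
# [0, min(R1, R2)], so the admissible root is unique.
lrc_bisect <- function(p, iter = 200) {
  kl <- p$K1 * p$L
  lo <- 0
  hi <- min(p$R1tot, p$R2tot)
  if (kl == 0 || hi == 0) return(0)
  f <- function(x) kl * (p$R1tot - x) * (p$R2tot - x) - x
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (mid == lo || mid == hi) break
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

rand_minimal <- function() {
  minimal_params(L = 10^runif(1, -3, 1), K1 = 10^runif(1, -3, 4),
                 K2 = 10, R1tot = 10^runif(1, 0, 5),
                 R2tot = 10^runif(1, 0, 5))
}

# short default stimulation reused by several tests
tc_100pM <- simulate_pathway(hacat, dose_nM = 0.1,
                             t_grid = seq(0, 480, by = 2))
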