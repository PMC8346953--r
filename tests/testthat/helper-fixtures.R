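# shared fixtures: canonical distributions and a few reference agents

dist_low <- reward_distribution("low")
dist_high <- reward_distribution("high")
dist_full <- reward_distribution("full")
dist_alt <- reward_distribution("full_alt")

linear_curve <- utility_curve("power1", 1)
prelec_s <- utility_curve("prelec2", c(alpha = 2, beta = 1))

risk_neutral_agent <- function(lambda = 100, seed = 11) {
  agent_config(linear_curve, lambda = lambda, seed = seed)
}

s_shaped_agent <- function(lambda = 25, seed = 12) {
  agent_config(prelec_s, lambda = lambda, seed = seed)
}

# independent dense-grid second-difference oracle for inflection location
grid_inflection_oracle <- function(f, n = 1e5) {
  x <- seq(1 / n, 1 - 1 / n, length.out = n)
  u <- f(x)
  d2 <- diff(diff(u))
  s <- sign(d2)
  i <- which(s[-1] * s[-length(s)] < 0)
  if (!length(i)) return(NA_real_)
  x[i[1] + 1]
}
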