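# Independent oracles used to freeze expected values.

# Donor-only lifetime and Forster radius solved from two (lifetime, distance)
# anchors by a 1-D root find on the ratio of the Forster relation; this is
# independent of the package's fret_efficiency/distance_from_efficiency path.
forster_pair_oracle <- function(tau_a = 557.8, r_a = 35,
                                tau_b = 854.7, r_b = 40) {
  f <- function(td) (tau_a / (td - tau_a)) * ((td - tau_b) / tau_b) -
    (r_a / r_b)^6
  tau_d <- stats::uniroot(f, c(tau_b * 1.05, 20000), tol = 1e-12)$root
  e_b <- 1 - tau_b / tau_d
  r0 <- r_b / ((1 / e_b - 1)^(1 / 6))
  list(tau_d = tau_d, r0 = r0)
}

# Closed-form biexponential curve, written independently of generate_decay
biexp_curve <- function(t, tau, alpha, baseline = 0) {
  out <- rep(baseline, length(t))
  for (i in seq_along(tau)) out <- out + alpha[i] * exp(-t / tau[i])
  out
}

# Two-state chain stationary bound probability and its binomial-style SE for
# an empirical frequency over n effectively correlated frames; the SE uses
# the integrated autocorrelation time of a two-state chain,
# tau_int = (1 - on - off) adjusted factor (2 - on - off) / (on + off) - 1.
markov_se <- function(on, off, n) {
  p <- on / (on + off)
  rho <- 1 - on - off          # lag-1 autocorrelation of the chain
  neff <- n * (1 - rho) / (1 + rho)
  sqrt(p * (1 - p) / neff)
}
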