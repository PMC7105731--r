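# Shared oracle helpers for the test suite.

# Plain-R reference integration of the four-state cross-bridge chain, kept
# deliberately independent of the compiled implementation. Returns the
# tension trace plus the maximum drift of the occupancy sum away from 1
# (the chain's rate matrix is conservative, so the sum is an invariant).
reference_crossbridge <- function(ca, times, params = crossbridge_params()) {
  p <- unclass(params)
  rate_cap <- 0.5 / p$dt
  nt <- length(times)
  tension <- numeric(nt)
  TCa <- 0; N <- 1; P <- 0; pre <- 0; post <- 0
  max_drift <- 0
  for (f in seq_len(nt - 1)) {
    span <- times[f + 1] - times[f]
    nsub <- max(1, round(span / p$dt))
    dts <- span / nsub
    for (s in seq_len(nsub)) {
      cai <- ca[f] + (ca[f + 1] - ca[f]) * ((s - 0.5) / nsub)
      TCa <- TCa + dts * (p$kon * cai * (1 - TCa) - p$koff * TCa)
      TCa <- min(max(TCa, 0), 1)
      tca <- max(TCa, p$tca_floor)
      knp <- min(p$Knp * tca^p$coop, rate_cap)
      kpn <- min(p$Kpn * tca^-p$coop, rate_cap)
      dN <- kpn * P - knp * N
      dP <- knp * N + p$g_aapT * pre + p$g_xbT * post - (kpn + p$f_aapT) * P
      dpre <- p$f_aapT * P + p$h_bT * post - (p$g_aapT + p$h_fT) * pre
      dpost <- p$h_fT * pre - (p$h_bT + p$g_xbT) * post
      N <- N + dts * dN; P <- P + dts * dP
      pre <- pre + dts * dpre; post <- post + dts * dpost
      max_drift <- max(max_drift, abs(N + P + pre + post - 1))
    }
    tension[f + 1] <- p$Tmax * (pre + post)
  }
  list(tension = tension, max_drift = max_drift)
}

# Smooth periodic calcium transient (mM) on a uniform time grid.
test_ca_transient <- function(times, period = 400, base = 1e-4, amp = 5e-4) {
  ph <- (times %% period) / period
  base + amp * ifelse(ph < 0.5, sin(pi * ph / 0.5)^2, 0)
}

# Half-sinusoid ventricular activation waveform at a given rate (Hz).
test_activation <- function(times, f_hz, duty = 0.35) {
  cl <- 1000 / f_hz
  ph <- (times %% cl) / cl
  ifelse(ph < duty, sin(pi * ph / duty)^2, 0)
}

# Random regression table with named columns (no special structure).
random_table <- function(n, seed) {
  set.seed(seed)
  data.frame(apd = rnorm(n, 130, 50), df = rnorm(n, 5.6, 1.2),
             ps = rnorm(n, 50, 25), filament = rnorm(n, 12000, 8000),
             sv = rnorm(n, 0.4, 0.6), amptens = rnorm(n, 0.4, 0.4))
}
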