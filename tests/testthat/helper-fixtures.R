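# shared helpers for the test suite

# independent log-log interpolation reading a bundled table straight from
# the CSV file (oracle path, bypassing the package loader)
read_mu_csv <- function(symbol, energy, col = NULL) {
  fn <- system.file("extdata", "xs", paste0(symbol, ".csv"),
                    package = "ppeshield")
  d <- read.csv(fn, comment.char = "#")
  val <- if (is.null(col)) {
    d$photoelectric + d$incoherent + d$coherent + d$pair
  } else d[[col]]
  i <- findInterval(energy, d$energy_keV)
  if (d$energy_keV[i] == energy) return(val[i])
  w <- (log(energy) - log(d$energy_keV[i])) /
    (log(d$energy_keV[i + 1]) - log(d$energy_keV[i]))
  exp((1 - w) * log(val[i]) + w * log(val[i + 1]))
}

# flat-background spectrum with an optional Gaussian peak of known area
make_peak_spectrum <- function(n_ch = 1024, gain = 1, bkg = 50,
                               peak_energy = NULL, peak_area = 0,
                               fwhm = 10, live_time = 100, seed = 42) {
  set.seed(seed)
  counts <- rpois(n_ch, bkg)
  if (!is.null(peak_energy)) {
    e <- gain * (seq_len(n_ch) - 1)
    sdv <- fwhm / 2.35482
    p <- dnorm(e, peak_energy, sdv) * gain
    counts <- counts + rpois(n_ch, peak_area * p)
  }
  spectrum(counts, offset = 0, gain = gain, live_time = live_time,
           label = "test")
}

# Klein-Nishina CDF of the scattered-photon angle, by numeric integration
# (independent of the C++ sampler)
kn_theta_cdf <- function(energy, theta) {
  a <- energy / 510.99895
  f <- function(th) {
    mu <- cos(th)
    eps <- 1 / (1 + a * (1 - mu))
    eps^2 * (eps + 1 / eps - (1 - mu^2)) * sin(th)
  }
  Z <- integrate(f, 0, pi, rel.tol = 1e-10)$value
  vapply(theta, function(t) integrate(f, 0, t, rel.tol = 1e-10)$value / Z, 0)
}

fast_cfg <- function(n = 2e4, seed = 1, mode = "analog") {
  transport_config(n_histories = n, seed = seed, variance_mode = mode)
}
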