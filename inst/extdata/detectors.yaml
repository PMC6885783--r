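# Generic detector response models for the synthetic spectrum generator.
# fwhm(E) = a * sqrt(E) + b   [keV, E in keV]
# full-energy-peak efficiency: log-normal in energy,
#   eps(E) = eps_max * exp(-0.5 * (log(E / e_peak) / width)^2)
# geometry: calibrated solid-angle x collimator transmission constant
# continuum: fraction of detected line events routed to a flat continuum
labr:
  label: "Generic handheld scintillator (LaBr3 class, ~3% FWHM at 662 keV)"
  channels: 2048
  gain_keV_per_ch: 1.5
  offset_keV: 0.0
  fwhm_a: 0.75
  fwhm_b: 0.6
  eps_max: 0.35
  e_peak_keV: 120.0
  eps_width: 1.6
  geometry: 0.002
  continuum: 0.25
hpge:
  label: "Generic high-resolution semiconductor (HPGe class, ~0.2% FWHM at 662 keV)"
  channels: 8192
  gain_keV_per_ch: 0.4
  offset_keV: 0.0
  fwhm_a: 0.05
  fwhm_b: 0.05
  eps_max: 0.35
  e_peak_keV: 120.0
  eps_width: 1.6
  geometry: 0.002
  continuum: 0.15
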