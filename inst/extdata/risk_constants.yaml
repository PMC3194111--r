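# Physical and epidemiological constants of the lifetime-risk algorithm.
# wl_per_pci embodies a 40% radon-progeny equilibrium fraction
# (1 pCi/L radon gas at 40% equilibrium = 0.004 WL of progeny).
exposure:
  wl_per_pci: 0.004          # working levels of progeny per pCi/L radon gas
  wlm_per_wl_year: 51.6      # working level months per WL-year
  occupancy_fraction: 0.70   # fraction of time spent indoors at home
  equilibrium_fraction: 0.40 # documentation only; already embodied in wl_per_pci
  exposure_duration_years: 75
# Lifetime fatal lung-cancer risk per WLM, by sex and ever/never smoking.
# general_population is a calibration value only (EPA central estimate).
unit_risks:
  male_ever: 0.00106
  female_ever: 0.000851
  male_never: 0.000174
  female_never: 0.000161
  general_population: 0.00054
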