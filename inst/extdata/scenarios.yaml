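# Borehole scenario presets for the Utqiagvik cryopeg system.
#
# Units: cell densities in cells mL^-1; carbon pools in fg C mL^-1
# (equivalently fg C cm^-3 of frozen bulk for the surrounding-sediment
# pools); per-cell quantities in fg C cell^-1; rates in day^-1; times in
# years since brine enclosure.
#
# CB1 and CB4 are intra-sediment brines; CBIW is an intra-ice brine that
# is modeled as receiving a pulsed carbon addition when it migrated into
# the massive ice 11,000 years before present (29,000 years after
# enclosure of a 40,000-year-old system).
scenarios:
  CB1:
    N_f: 5.70e+06
    P_0: 1.64e+13
    D_0: 3.41e+10
    P_f: 1.49e+11
    D_f: 1.23e+12
    D_in: 0.0
    P_in: 0.0
    addition_time: .na
    alpha_D: 15.7
    mu_max: 0.06
  CB4:
    N_f: 1.14e+07
    P_0: 1.75e+13
    D_0: 6.17e+11
    P_f: 4.97e+10
    D_f: 1.02e+12
    D_in: 0.0
    P_in: 0.0
    addition_time: .na
    alpha_D: 54.04
    mu_max: 0.016
    # Raw sediment measurement behind P_0.  The published P_0 above
    # (1.75e13) is not exactly reproduced by this measurement chain,
    # which gives ~1.69e13; the derived value is the package default
    # because it reproduces the downstream EEA and timespan estimates.
    sediment_measurement:
      poc_mass_fraction: 0.0136
      porewater_doc: 1286.0
      volumetric_ice_content: 0.527
      dry_sediment_density: 2.625
      expansion_factor: 0.0905
  CBIW:
    N_f: 1.39e+08
    P_0: 1.64e+13
    D_0: 3.41e+10
    P_f: 2.38e+10
    D_f: 3.60e+11
    D_in: 3.88e+10
    P_in: 1.86e+10
    addition_time: 29000.0
    alpha_D: 15.7
    mu_max: 0.06

constants:
  N_max: 1.0e+09
  K_D: 8.82e+05
  N_0: 1.0e+05
  gamma_measured: 1.22e-02
  t_f: 40000.0
  alpha_I: 0.0
  I_xr: 0.0
  days_per_year: 365.25

# Parameter bounds for the global sensitivity analysis (per-parameter
# sampling box; scale notes which parameters are drawn log-uniformly).
sensitivity_bounds:
  growth_rate:     {lower: 1.0e-06, upper: 1.0e+02, scale: log}
  metabolic_rate:  {lower: 1.0e-05, upper: 5.0e+02, scale: log}
  cell_carbon:     {lower: 1.0e+02, upper: 5.0e+02, scale: linear}
  eea_rate:        {lower: 0.0,     upper: 1.0e+02, scale: linear}
  half_velocity:   {lower: 1.0e+03, upper: 1.0e+08, scale: linear}
  carrying_capacity: {lower: 1.0e+08, upper: 1.0e+09, scale: linear}
  starting_density:  {lower: 1.0,     upper: 1.0e+08, scale: linear}
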