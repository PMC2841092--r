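# Example pipeline configuration: synthetic survey emulating a large US
# consumption survey, upshifted to an adult per-capita level of 8.75 liters
# pure alcohol per year, with an illustrative log-linear dose-response.
# The relative risks below are placeholders for literature-supplied curves,
# not a reproduction of any published disease-specific AAF.
seed: 20260101
percapita_liters: 8.75
ethanol_density_g_per_l: 789.24
days_per_year: 365
target_fraction: 1.0
synthetic:
  underreport: 0.529
  n_total: 43000
rr:
  type: loglinear
  beta: 0.01
  rr_former: 1.3
categories:
  men:
    breaks: [40, 60]
    rr: [1.3, 4.0, 9.0]
  women:
    breaks: [20, 40]
    rr: [1.3, 4.0, 9.0]
cap: null
integration_step: 0.02
integration_upper: 300
bootstrap:
  enabled: false
  n_reps: 1000
outdir: upshift-output
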