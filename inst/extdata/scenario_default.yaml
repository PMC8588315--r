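# Default synthetic scenario: the factorial design the generator emulates.
# Effect-size presets (fungal suppression, urease stimulation, dose shifts
# of the mock community) live in the package presets; this file exposes the
# design-shape knobs.
preset: default
doses: [0, 0.1, 1, 10, 50]   # contaminant dose, mg kg-1 DM of soil
days: [15, 30, 45]           # sampling days
replicates: 3
otu:
  library_size: 10000
  concentration: 200         # Dirichlet precision (overdispersion)
residue:
  k: 0.21459656              # first-order decay, d-1: 96% removed by day 15
  cv: 0
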