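# Flexible 80-bead linear chain in the S_p = 12, d_p = 9.9 post array,
# desk-scale step counts. All keys omitted here fall back to defaults.
chain:
  topology: linear
  n_beads: 80
  b: 0
geometry:
  S_p: 12.0
  d_p: 9.9
simulation:
  thermostat: langevin
  n_equil: 200000
  n_prod: 300000
  sample_every: 500
  seed: 502
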