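# Example pppflux run configuration: simulate the default four-condition
# knockdown design and compare Ru5P m1/m2 dilution rates against control.
control: siCon
seed: 7
n_draws: 1000
p13C: 0.0107
correct: false
qc_threshold: 0.05
output_dir: pppflux-run
simulate:
  scenarios: default
  tracer_fraction: 0.5
  purity: 1.0
  times: [0, 10, 60, 120, 240, 480, 900]
  replicates: 3
  sd_fraction: 0.01
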