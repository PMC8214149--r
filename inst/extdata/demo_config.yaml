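# Demo run configuration: simulate SDASO-M cross-linked species from the
# bundled synthetic protein database, then search, assemble and summarize.
# The fasta path is resolved relative to the package extdata directory by
# the demo code (see ?run_pipeline); replace with absolute paths for real use.
linker: SDASO-M
seed: 11
enzyme: trypsin
ppm: 20
ms3_window: 0.6
fdr_threshold: 0.01
run_preference: true
simulate:
  n_interlink: 25
  n_deadend_nhs: 5
  n_deadend_diazirine: 5
  n_intralink: 5
  ppm_sigma: 5
  noise_peaks: 20
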