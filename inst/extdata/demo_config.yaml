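# Demo pipeline configuration: synthetic proteome with ground truth.
out_dir: "neuropep_demo"
sieve_low: 600
sieve_high: 4000
tol_ppm: 300
frag_tol: 0.6
score_threshold: 20
p_threshold: 1.0e-05
bootstrap_reps: 1000
bootstrap_cutoff: 50
synthetic: yes
seed: 1
scan:
  w_sites: 1
  w_repeats: 2
  w_motifs: 3
  w_signal: 1
  threshold: 4
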