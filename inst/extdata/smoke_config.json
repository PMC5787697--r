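{
  "out_dir": "clipbind_smoke",
  "seed": 5,
  "genome": {"n_genes": 12, "chromosome_length": 40000},
  "binding": {"n_sites": 60},
  "n_reads": 4000,
  "n_events": 60,
  "kmers": {"n_shuffles": 5},
  "boundaries": {"n_regions": 200},
  "splicemap": {"n_permutations": 25}
}
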