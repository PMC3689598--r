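# Demonstration run: a small two-chromosome genome with genes, CpG islands
# and a satellite array; both developmental stages and all three protocols.
seed: 1
genome:
  chromosome_lengths:
    chr1: 80000
    chr2: 50000
  background_gc: 0.42
  n_genes: 6
  n_cpg_islands: 5
  satellite_array_count: 2
  satellite_array_len: 30
  interspersed_repeat_classes:
    SINE: [300, 4]
    LINE: [800, 2]
mark_model:
  p_mC_cpg_island: 0.1
  p_mC_cpg: 0.7
  p_mC_chh: 0.02
  p_hmC_cpg: 0.05
  p_hmC_chh_ctag: 0.02
  stages:
    D7: {}
    D12:
      p_hmC_cpg: 0.1
stages: [D7, D12]
protocols: [ME_RDA, HME_RDA, HELP_COCKTAIL]
coverage: 2
error_rate: 0.0
use_adaptors: true
alpha: 0.05
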