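target,stage,pool,ct_digested,ct_undigested
SAT_locus1,D7,1,21.4,20.1
SAT_locus1,D7,2,21.6,20.3
SAT_locus1,D7,3,21.3,20.0
SAT_locus1,D12,1,23.9,20.2
SAT_locus1,D12,2,24.2,20.4
SAT_locus1,D12,3,24.0,20.1
SAT_locus2,D7,1,22.0,20.5
SAT_locus2,D7,2,21.8,20.2
SAT_locus2,D7,3,22.1,20.6
SAT_locus2,D12,1,22.1,20.4
SAT_locus2,D12,2,21.9,20.3
SAT_locus2,D12,3,22.2,20.6
SAT_locus2,D12,4,22.0,20.4
SAT_locus2,D7,4,21.9,20.3
SAT_locus2,D12,5,22.3,20.7
SAT_locus2,D7,5,22.2,20.6
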