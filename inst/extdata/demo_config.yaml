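# demo configuration: a small copper-stress style experiment
n_transcripts: 300
utr5_len: 150
cds_len: 1200
utr3_len: 300
frac_noncoding: 0.10
frac_methylated: 0.60
frac_stress_only: 0.13
frac_control_only: 0.15
ip_enrichment: 8
depth: 30
window_size: 25
dispersion: 0.02
motif: TGTA
motif_rate_in_peaks: 0.8
motif_rate_background: 0.05
lfc_shift_stress_enriched: 0.5
lfc_shift_control_enriched: -0.5
lfc_shift_lncRNA_stress: -0.5
occupancy_shift_stress_enriched: 0.5
seed: 42
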