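# Demonstration run: wild type against three chaperone-mutant presets.
# Scaled down (40 origins, 200 cells per library) so the full pipeline
# finishes in about a minute; raise n_origins / cells_per_sample /
# brdu_reads_per_bp toward the package defaults (200 / 1000 / 3) for
# smoother curves.
outdir: espan_demo
seed: 1
reference: WT
analysis:
  radius: 10000
  window: 100
  step: 10
  exclude: 300
  density_halfwidth: 2500
  density_bin: 100
  filter_halfwidth: 1000
  filter_threshold: 2
  normalization: none
simulation:
  n_origins: 40
  origin_spacing: 30000
  margin: 15000
  replicated_halfwidth: 5000
  nucleosome_spacing: 160
  fragment_length_mean: 150
  fragment_length_sd: 15
  reads_per_nucleosome: 0.3
  brdu_reads_per_bp: 1.5
  cells_per_sample: 200
  strand_recovery_w: 1.0
  genotypes: [WT, mcm2_2A, dpb4d, mcm2_2A_dpb3d]
  marks: [H3K4me3, H3K56ac]
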