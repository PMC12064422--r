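# Demo run: small synthetic panel with two planted saline-effect QTLs,
# one shared by three traits (a true colocation) and one by two.
seed: 42
n_lines: 120
n_chrom: 2
chrom_length_bp: 2.0e6
snp_density: 0.001
traits: [grain_yield, filled_grains, panicle_length, shoot_biomass]
anchor_trait: grain_yield
qtls:
  - chrom: chr1
    pos: 1000000
    traits: [grain_yield, filled_grains, panicle_length]
    control: 0
    saline: 1.5
  - chrom: chr2
    pos: 600000
    traits: [grain_yield, shoot_biomass]
    control: 0
    saline: 1.2
coloc_threshold: 3
coloc_window_kb: 100
min_traits: 2
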