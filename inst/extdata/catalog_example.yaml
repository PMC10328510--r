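# Example catalog entry: a small synthetic diploid used in examples and the
# command-line interface. Values are illustrative fixtures, not published
# estimates for any real species.
schema_version: 1
species:
- id: ExaSpe
  name: Examplea specifica (synthetic)
  ploidy: 2
  generation_time: 1.0
  default_Ne: 10000
  chromosomes:
  - id: chr1
    length: 1000000
    mutation_rate: 1.0e-8
    recombination_rate: 1.0e-8
    gene_conversion_fraction: 0.5
    gene_conversion_length: 100
  - id: chrM
    length: 20000
    mutation_rate: 1.0e-8
    recombination_rate: 0.0
  citations:
  - authors: Synthetic fixture (this repository)
    year: 2026
    reasons: [assembly, mutation_rate, recombination_rate, gene_conversion,
              population_size, generation_time]
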