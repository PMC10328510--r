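# Illustrative cattle-style demographic model (SYNTHETIC). Only two size
# anchors are published point values (ancestral Ne = 62,000 from about
# 33,000 generations ago; recent Ne = 90) plus the mutation-rate override
# of 9.4e-9 assumed during inference; the intermediate steps of the real
# 13-step model are NOT published in text form, so the values in between
# here are made-up placeholders exercising the schema.
schema_version: 1
id: cattle_synthetic
populations: [pop0]
initial_sizes:
  pop0: 90
mutation_rate_override: 9.4e-9
events:
- {time: 100, type: size_change, population: pop0, size: 500}
- {time: 1000, type: size_change, population: pop0, size: 5000}
- {time: 10000, type: size_change, population: pop0, size: 20000}
- {time: 33000, type: size_change, population: pop0, size: 62000}
citations:
- authors: Runs-of-homozygosity inference (published); intermediate sizes synthetic
  year: 2013
  reasons: [demographic_model, mutation_rate]
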