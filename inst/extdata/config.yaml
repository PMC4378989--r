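# Example analysis configuration for the synthetic metabolomics toy data
# shipped with the package (all values simulated).
phenotype:
  path: phenotype.tsv
  trait: aggregation
  covariates: [age]
modules:
  - data: module1.tsv
    network: module1_edges.tsv
    kernel: topology
  - data: module2.tsv
    network: module2_edges.tsv
    kernel: topology
tests: all
strategy: sequential
alpha: 0.05
seed: 1
outDir: netkm-results
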