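# Demo run: two simulated breeding populations (300 + 300 DH lines,
# 2000 SNPs over five chromosomes) with one shared QTL, analysed with
# the single-population, MP1 and MP2 GWAS models.
seed: 20240817
trait: trait
populations: [pop1, pop2]
modes: [single, mp1, mp2]
alpha: 0.05
spatial_mode: none
terms: [additive, line]
power: true
ld: false
lps: false
simulate:
  n_populations: 2
  n_founders: 12
  n_families: 25
  lines_per_family: 12
  n_chromosomes: 5
  snps_per_chrom: 400
  n_environments: 2
  n_reps: 1
  fst: 0.15
  var_additive: 1.5
  var_line: 0.15
  var_gxe: 0.0
  var_spatial: 0.0
  var_error: 0.8
  qtl:
    chrom: ["2H"]
    pos: [52312500]
    effect: [0.45]
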