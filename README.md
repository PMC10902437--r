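# ldrefine

Refining fragmented draft genome assemblies with population linkage
disequilibrium, and analysing the resulting genome's rearrangements
against chromosome-level relatives.

## The problem

Many non-model organisms have only a scaffold-level draft genome:
thousands of sequences whose order and orientation along chromosomes are
unknown, which blocks downstream work on structural variation and genome
evolution. Long reads or Hi-C would fix this, but for species where fresh
samples are hard or impossible to obtain, often the only additional data
available is short-read population resequencing.

`ldrefine` turns that resequencing into scaffolding information. Linkage
disequilibrium (LD) between SNPs decays with physical distance, so SNPs
near the ends of two scaffolds that were adjacent on the chromosome stay
correlated in the population, while random scaffold-end pairs do not. The
pipeline:

1. reads population genotypes (VCF), keeping biallelic SNPs with missing
   rate < 15% and minor allele count > 3, on scaffolds ≥ 20 kb with
   ≥ 100 SNPs;
2. takes up to *k* = 500 SNPs from each scaffold end and scores every
   pair of scaffold terminals by the mean composite genotype r²
   (squared dosage correlation — phase-free, so unphased calls are fine)
   over cross pairs of sites;
3. fits a Gaussian null to the score distribution (robust median/MAD
   fit) and takes the upper bound of its central 97% interval as the
   junction threshold — the published geometry is a null centred near
   0.12 with the cutoff at 0.15;
4. orders and orients scaffolds by maximizing total junction score over
   disjoint chains (exact dynamic programming on small components;
   greedy matching + local search with min-edge cycle linearization on
   large ones), and emits super-scaffolds as FASTA + AGP v2.1 with
   native N50/N90 statistics;
5. for comparative analysis, consumes whole-genome alignment coordinate
   tables, filters blocks (≥ 2 kb, ≥ 90% identity), intersects
   homologous regions across genomes (> 80% reciprocal-style overlap;
   three-way blocks > 10 kb), and calls inversions and translocations
   from signed block permutations, with a majority-rule reconstruction
   of ancestral adjacencies for a three-genome topology.

A first-class synthetic-data module (`simulate_truth()`,
`simulate_coords()`) generates chromosomes, founder-mosaic populations
with distance-decaying LD, and alignment tables with planted
rearrangements — all with explicit truth records — so the whole pipeline
is testable offline. See the methods vignette
(`vignettes/ld-scaffolding-methods.Rmd`) for models, conventions, design
decisions and known limitations.

## A worked example

```r
library(ldrefine)

sim <- simulate_truth(sim_config(chromosome_length = 3e5, n_scaffolds = 6,
                                 n_samples = 30, n_founders = 8,
                                 n_sites = 600, recomb_rate = 1e-5,
                                 seed = 3))
gms    <- lapply(genotype_matrices(sim), filter_sites)
mat    <- score_matrix(lapply(gms, extract_edge_blocks, k = 100))
null   <- fit_null(mat)
layout <- solve_layout(build_graph(mat, null))
compare_to_truth(layout, sim$truth$adjacencies)
```

which prints (exact output of this seed):

```
linkage_score_matrix: 6 scaffolds, 60 defined inter-scaffold scores (median 0.0496)
ld_null_model: mean 0.0496, sd 0.0252 -> threshold 0.1043 (60 scores, 97% CI)
scaffold_layout: 2 super-scaffolds, 1 singletons, 0 edges cut during linearization; total score 0.4218
ld_recovery: precision 1, recall 0.6, orientation 1 (3/5 correct)
```

Reading this: the 60 inter-scaffold terminal scores have a noise bulk
near 0.05; the fitted null puts the junction threshold at 0.104; solving
the thresholded graph joins the six scaffolds into two super-scaffolds
plus one singleton, recovering 3 of the 5 true junctions with no false
joins and all relative orientations correct. Emitting the
super-scaffolds raises the N50 from 64,432 to 104,143 bp:

```
assembly_stats: 6 sequences, total 3e+05 bp; N50 64,432 N90 28,774 ; 0.00 Ns per 100 kbp
assembly_stats: 3 sequences, total 300,300 bp; N50 104,143 N90 86,813 ; 99.90 Ns per 100 kbp
```

## Command line

A thin CLI is installed under `exec/`:

```sh
CLI=$(Rscript -e 'cat(system.file("exec", "ldrefine", package = "ldrefine"))')
Rscript $CLI simulate        --outdir demo --seed 7
Rscript $CLI build-scaffolds --vcf demo/variants.vcf --fasta demo/scaffolds.fasta \
                             --outdir out --threshold 0.15
Rscript $CLI stats           --fasta out/super_scaffolds.fasta
Rscript $CLI simulate-coords --out fx.coords --n-blocks 20 --inversions 1 \
                             --translocations 1 --seed 4
Rscript $CLI rearrange       --coords fx.coords --out calls.tsv
```

`--config` files are JSON (keys mirror `sim_config()` arguments);
thresholds are exposed as flags with the published defaults.

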