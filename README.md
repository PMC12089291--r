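# karyotracer

Karyotype evolution from shared chromosome fusion breakpoints.

`karyotracer` is for comparative genomicists who have chromosome-level gene
annotations and homology tables for a set of related genomes and want to
know how their karyotypes evolved: which protochromosomes make up the
ancestral karyotype, which chromosome fusions happened on which lineage,
whether two genomes share a fusion by descent or acquired similar fusions
independently, and which diploid lineages contributed the subgenomes of an
allopolyploid.

## The method

Chromosome numbers fall ("descending dysploidy") through three kinds of
interchromosomal rearrangement: reciprocal chromosome translocation (RCT;
two breakpoints, *n* unchanged), end-to-end joining (EEJ; one breakpoint,
*n* − 1) and nested chromosome fusion (NCF; two breakpoints, *n* − 1).
Every fusion leaves a breakpoint — a junction between ancestrally
non-adjacent regions — and such junctions are rare, effectively
irreversible characters. Working entirely in gene-rank coordinates, the
package:

- chains homologous gene pairs into collinear synteny blocks (an exact
  maximal-coverage monotone-run partition with a gap bound);
- paints genomes by the protochromosomes of a reference karyotype and
  identifies chromosome-like synteny blocks (CLSBs), protochromosomes
  conserved as whole chromosomes everywhere;
- detects junctions, classifies them as RCT / EEJ / NCF (residuals are
  reported as `complex`), and names events in the field's nomenclature
  (`AKI/7_8/RCT`, `tAKI/(4_6/EEJ)_5/RCT`);
- tests breakpoint sharing with 100-gene windows (50 genes per side): a
  breakpoint is present in another genome only when a single synteny block
  spans the junction, so same-chromosome fusions at different positions are
  told apart;
- roots event directionality with an outgroup, builds a genomes ×
  breakpoints copy-number matrix, and infers relationships under a Dollo
  (unique, irreversible fusion) assumption;
- phases allopolyploid chromosomes into subgenomes (complementarity,
  balance, and gene-retention homogeneity) and assigns each subgenome a
  parent by uniquely shared fusion events;
- ships a karyotype-evolution simulator (RCT/EEJ/NCF/inversions,
  fractionation, allopolyploid merging) that emits GFF3/BED gene tables,
  homology files and ground-truth logs, so every stage is validated against
  known histories.

## Worked example

Simulate a lineage that lost three chromosomes (three EEJs and two RCTs)
against an unrearranged reference, then recover the events:

```r
library(karyotracer)

res <- simulate_scenario(sim_preset("thaliana_like"), seed = 1)
res
#> sim_result: 2 genome(s) [REF, THA], 5 recorded event(s), seed 1

st <- detect_events(res$genomes$THA, res$genomes$REF)
st$events[, c("event_id", "type", "proto_a", "proto_b", "name", "delta_n")]
#>   event_id type proto_a proto_b        name delta_n
#> 1 THA.ev01  RCT       2       7 REF/2_7/RCT       0
#> 2 THA.ev02  RCT       7       8 REF/7_8/RCT       0
#> 3 THA.ev03  EEJ       1       2 REF/1_2/EEJ      -1
#> 4 THA.ev04  EEJ       3       4 REF/3_4/EEJ      -1
#> 5 THA.ev05  EEJ       5       6 REF/5_6/EEJ      -1
```

The two RCTs conserve chromosome number and carry two breakpoints each; the
three EEJs each fuse two protochromosome ends and account for the drop from
n = 8 to n = 5 (the `delta_n` column sums to −3). Rooting the first two
breakpoints against a genome with the ancestral arrangement marks them as
derived — collinearity support exists on each flank separately
(`n_left`/`n_right` anchors) but no single block spans the junction:

```r
sb <- genome_pair_blocks(res$genomes$THA, res$genomes$REF)
orient_with_outgroup(st$breakpoints[1:2, ], sb)
#>      bp_id verdict n_left n_right
#> 1 THA.bp01 derived     50       0
#> 2 THA.bp02 derived      0      49
```

Higher-level drivers chain these stages: `reconstruct_protochromosomes`
(CLSBs + outgroup rooting → ancestral karyotype),
`breakpoint_matrix_pipeline` (breakpoint matrix + Dollo tree) and
`phase_and_assign` (subgenome phasing + parentage). A command-line wrapper
with `simulate`, `synteny`, `paint`, `events`, `share`, `tree`, `phase` and
`cgb-overlap` subcommands lives in `inst/cli/karyotracer.R`.

See the vignette (`vignettes/karyotype-evolution.Rmd`) for the model,
parameter defaults and limitations.

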