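---
title: "Tracing karyotype evolution through shared fusion breakpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing karyotype evolution through shared fusion breakpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyotracer)
```

## The model

Descending dysploidy -- the stepwise reduction of chromosome number without
loss of genomic content -- proceeds through three kinds of interchromosomal
rearrangement. A reciprocal chromosome translocation (RCT) exchanges
terminal segments between two chromosomes and leaves the chromosome number
*n* unchanged; an end-to-end joining (EEJ) fuses two chromosomes at their
ends; a nested chromosome fusion (NCF) inserts one whole chromosome into an
internal position of another. EEJ and NCF each reduce *n* by one. Each
event leaves one (EEJ) or two (RCT, NCF) *fusion breakpoints*: junctions
between regions that were not adjacent in the ancestral karyotype.

The central idea this package implements is that a fusion breakpoint is a
rare, effectively irreversible genomic change. Two genomes that share a
breakpoint -- the same protochromosomes joined *at the same position* --
inherited it from a common ancestor, whereas independent fusions of the
same chromosomes occur at different positions and can be told apart. Shared
breakpoints therefore behave as Dollo characters whose presence sets define
clades, and, in allopolyploids, tie each subgenome to the parental lineage
it came from.

All positional logic runs in *gene-rank coordinates*: genes are ranked
0-based along each chromosome, intervals are half-open, and a junction sits
at the rank of its right-hand gene. Windows and thresholds are counted in
genes, not base pairs, because fractionation and annotation density make
physical distance incomparable across genomes; base-pair coordinates are
carried only as metadata.

## The pipeline

1. **Anchors and synteny blocks** (`build_anchors`,
   `chain_collinear_blocks`). Homologous gene pairs become dot-plot
   anchors; tandem arrays are collapsed to their lowest-rank member. Within
   each chromosome pair, the anchors (sorted by rank in genome A) are
   partitioned into strictly monotone runs -- increasing in both genomes
   (orientation `+`) or increasing in A and decreasing in B (`-`) -- with
   consecutive anchors at most `max_gap = 25` ranks apart on either side.
   Among all such partitions we take one that maximizes the number of
   anchors covered by runs of at least `min_anchors = 5`, breaking ties by
   fewest blocks. This is solved exactly by a linear-time dynamic program
   with a monotone deque; we chose an exact objective over one-pass greedy
   seeding because greedy run extension absorbs stray anchors at block
   boundaries (the three-block example in the test suite is mis-chained by
   greedy seeding but is the optimum of the stated objective, confirmed by
   a brute-force oracle). A final pass appends unused anchors adjacent to a
   block when monotonicity and the gap bound allow, so no emitted block can
   be extended.

2. **Painting** (`ak_from_genome`, `paint_genome`). A structurally
   conserved reference genome supplies the protochromosome gene lists; each
   target chromosome is segmented by its blocks and each segment labeled by
   the majority protochromosome of its block anchors (per block, not per
   gene, which is robust to isolated homolog misassignment). Painted
   segments shorter than `min_segment = 30` genes are merged into the
   flanking segment with more anchors; adjacent same-label segments are
   re-joined only when their ancestral intervals are contiguous within
   `contiguity_tol = 30` ranks in a consistent orientation, so inversions
   and genuine intra-protochromosome rearrangements stay visible.

3. **Junctions and events** (`detect_junctions`, `classify_events`). Every
   adjacent segment pair whose ancestral positions are not contiguous ends
   of one protochromosome is a breakpoint, with up to 50 gene ids recorded
   per side. Classification proceeds NCF first (two consecutive junctions
   on one chromosome flanking a complete donor), then RCT (junction pairs
   with the same two protochromosomes and complementary internal splits,
   within `split_tol = 30` ranks), then EEJ (a junction whose two facing
   ancestral coordinates are both within `end_tol = 15` ranks of a
   protochromosome terminus). Two generalizations matter for compound
   histories: the two junctions of an RCT may end up on *one* chromosome
   when a later fusion merged the translocation products, and an EEJ
   junction may carry the same label on both sides when earlier
   translocations swapped the tails being joined. Whatever fits no pattern
   is reported as `complex`, never dropped. Inversions (orientation flips
   with contiguous ancestral intervals) are logged separately and are not
   fusion events.

4. **Sharing and rooting** (`breakpoint_shared`, `orient_with_outgroup`).
   A breakpoint is present in another genome when a single synteny block
   spans its junction with at least `min_side_anchors = 25` anchors on each
   50-gene flank -- half the flank, a deliberately conservative default
   exposed as a parameter, since the underlying collinearity-support
   criterion has no published numeric threshold. For rooting, a junction
   spanned in the outgroup is ancestral; a junction *not* spanned while
   each flank individually has single-block support is derived (the absence
   of spanning is then evidence of a different arrangement rather than of
   missing data); anything else is unresolved. The operation takes one
   junction set at a time and is called once per candidate karyotype.

5. **CLSBs and karyotype assembly** (`identify_clsbs`,
   `assemble_ancestral_karyotype`, `reconstruct_protochromosomes`). A
   protochromosome is a chromosome-like synteny block (CLSB) when, in every
   genome, at least `purity = 0.95` of its painted content sits on one
   chromosome and that chromosome is at least 95% that label. The purity
   value operationalizes "chromosome-like"; no numeric criterion exists in
   the literature, and 0.95 tolerates the small mislabeled fringes that
   fractionation produces without admitting genuine fusions. Labels that
   fail the test must be rooted by an outgroup before assembly; assembly
   then extracts each protochromosome's genes from the reference painting.

6. **Breakpoint matrix and tree** (`build_breakpoint_matrix`,
   `infer_tree_dollo`). Breakpoints are clustered into identity classes by
   mutual sharing; evidence in either direction links a pair, because gene
   loss erodes windows while fusions do not revert. Cells count the
   chromosomes of a genome carrying an instance of the class, so fusions
   duplicated by polyploidy score 2. Binarized columns are Dollo
   characters: when their presence sets form a laminar family the nesting
   tree is returned (with polytomies where resolution is lacking);
   otherwise a maximal laminar subset is kept greedily by column support,
   ties to the more inclusive set, and the excluded columns are reported as
   conflicts. Conflicts are a diagnostic, not an expected path.

7. **Subgenome phasing and parentage** (`phase_subgenomes`,
   `assign_parentage`, `phase_and_assign`). Phasing minimizes a
   three-term score: each subgenome should cover each protochromosome close
   to once (complementarity), painted totals should balance, and retention
   (painted genes over ancestral span) should be homogeneous within a
   subgenome. The retention term is essential, not cosmetic: coverage alone
   cannot distinguish swapping whole homeologous chromosomes between
   subgenomes, while biased fractionation -- the empirically common state
   of allopolyploid subgenomes -- breaks that tie. The search is exhaustive
   when `k^C <= 2e5` assignments exist and seeded multi-start hill climbing
   (single moves plus swaps, deterministic given `seed`) otherwise; a
   literal exhaustive sweep is infeasible already at k = 3 subgenomes and
   C = 20 chromosomes. Parentage counts an event as shared with a
   candidate parent when *every* breakpoint of the event is
   collinearity-supported there, and assigns each subgenome by its
   *unique* shared events -- events shared with exactly one candidate --
   because an event shared by all candidates (e.g. a basal fusion predating
   their divergence) carries no parentage information. Ties are broken by
   conflicts (a candidate's own fusion that the subgenome lacks argues
   against that candidate) and then by total sharing. If two subgenomes
   claim one parent, phasing is re-run with a shifted search seed.

## The simulator

`simulate_scenario` evolves a defined ancestor (default 8 chromosomes of
400 genes -- desk scale; real crucifer chromosomes carry thousands, and the
size is configurable) through recorded events, applies fractionation as
uniform per-gene loss on emitted genomes (internal nodes are lossless; one
rate per leaf or per polyploid subgenome), and merges lineages into
allopolyploids with suffixed chromosomes. Junction positions are drawn at
least 60 genes from chromosome ends and 120 genes from existing junctions
so full 100-gene windows exist; both margins scale down proportionally on
short test-size chromosomes, then relax stepwise on crowded ones.
Base-pair coordinates are synthesized as rank-by-1000 spans because the
interchange formats require them; the analysis never reads them. Gene
identifiers carry ancestral-slot family labels, so homology tables, truth
paintings and truth event logs (with nested nomenclature names built from
per-chromosome tokens) are exact.

The presets replay the package's study conditions: a lineage undergoing
three EEJs and two RCTs against an unrearranged reference (n = 8 to 5); an
allotetraploid of those two lineages (n = 13) with subgenome fractionation
rates of 0.04 and 0.10; an allohexaploid of three lineages (n = 7, 6, 7;
rates 0.03/0.08/0.13) sharing one basal EEJ, with lineage-specific
translocations of the same chromosome pair at different positions; a
five-taxon clade with nested fusions on internal branches plus an
unrearranged reference and outgroup; and an ingroup pair differing by an
RCT with an ancestral-structured outgroup. Where the emulated scenarios
state no rate, the fractionation rates above were chosen once as realistic
for post-polyploid genomes and are not tuned.

What the simulator deliberately does not model: sequence evolution, gene
length and intergenic-distance variation, segmental duplications,
non-uniform (cluster-biased) gene loss, centromere position, and
whole-genome-duplication signatures such as Ks distributions. Passing
tests therefore demonstrate the method's correctness on clean gene-order
histories with uniform fractionation, not robustness to annotation errors
or assembly artifacts in real genomes.

## Numerical choices and degenerate inputs

- Ranks are assigned by sorting on `(start, end, gene_id)`, so ranks are
  deterministic under any input row order; duplicate gene ids are a hard
  error.
- Chaining ties prefer orientation `+`, then the leftmost (longest) run;
  anchors claimed by no block stay unassigned and are reported.
- The between-gene junction convention is the rank of the right-hand gene;
  windows truncated by a chromosome end are flagged rather than padded.
- An empty anchor set paints a genome all-`NA` with a warning rather than
  failing, and an empty breakpoint matrix yields a star tree.
- A `flank` of zero genes is refused (`"empty window"`), as is a
  fractionation rate of 1 (`"degenerate scenario"`), and overlapping
  painting or CGB intervals are refused at write/read time.
- Breakpoint-to-CGB linking uses the 50-gene rule inclusively (distance of
  exactly 50 links); exact coincidences are additionally counted, since
  published "complete overlap" counts may have used either reading.

## Problem sizes used in the checks

The test suite and the acceptance script run the presets at their default
size (8 x 400 genes) and the two 20-replicate studies -- Dollo tree
recovery on the five-taxon clade and event-recovery F1 under 10% loss with
five events per replicate -- at 8 x 200 genes, a size at which every stage
of the pipeline is still comfortably identifiable while the whole study
runs in minutes on one core.

## Known limitations

- The painting cannot resolve fragments shorter than `min_segment` genes;
  an event whose cut leaves a sub-30-gene fragment on a short (test-size)
  chromosome surfaces as a `complex` junction rather than its true type.
  This accounts for the few misses in the F1 study.
- Two independent fusions of the same protochromosomes closer than
  `max_gap` genes apart would be indistinguishable from a shared fusion;
  the discrimination power is set by the gap bound.
- Two independent EEJs joining the same two chromosome ends have no
  positional signature at all and are inherently indistinguishable from a
  shared event by gene order alone.
- Robertsonian versus telomeric EEJ mechanisms cannot be told apart from
  gene order, and centromeres are not modeled.
- `reconstruct_protochromosomes` assumes the designated reference genome
  is structurally ancestral for the labels it resolves; a reference
  carrying its own undetected fusion would propagate that fusion into the
  assembled karyotype. Outgroup verdicts guard against this only for
  junctions visible in the panel.
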