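---
title: "Codon usage bias and gene-family expansion with codonfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias and gene-family expansion with codonfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonfam)
```

codonfam packages the computations behind a typical gene-family
molecular-evolution study — here modelled on the NIN-like protein (NLP)
transcription-factor family of foxtail millet and related cereals — as
tested, reusable functions: CDS screening, CodonW-style codon-usage bias
statistics and the ENC-plot, optimal-codon determination from a ΔRSCU
contrast, parsimony duplication–loss reconciliation for family-expansion
analysis, and GFF3 promoter/gene-structure extraction. A synthetic-data
module generates inputs with known structure so every stage is testable
without genome downloads.

## CDS screening

Codon statistics are only meaningful on complete, clean coding sequences.
`screen_cds()` keeps a record iff it is at least 300 bp long (configurable),
a whole number of codons, starts with ATG, ends with TAA/TAG/TGA, and
contains only A, C, G, T. The frame predicate is not part of the classic
screening recipe but is required for everything downstream, so it is checked
and reported as its own failure reason. U→T and case normalization happen at
read time, so mRNA-style FASTA works unchanged. Internal stop codons are
*not* screened by default — only the terminal codon is inspected — but
`internal_stops = TRUE` adds that predicate for users who want it.

## Codon-usage bias statistics

All statistics follow the conventions of CodonW, the program that
popularized this parameter set, so that outputs are comparable with the
large body of published tables.

**RSCU.** For codon $j$ of an amino acid with degeneracy $k$ and total count
$N$: $\mathrm{RSCU}_j = n_j / (N/k)$, the observed count over the count
expected under uniform synonymous usage. Values sum to $k$ within each
observed amino acid. An amino acid absent from a gene yields `NA` — a
deliberate distinction from 0, which means "observed amino acid, unused
codon".

**ENC.** Wright's effective number of codons estimates, per amino acid with
$n \ge 2$ observations, the codon homozygosity
$\hat F = (n\sum \hat p_i^2 - 1)/(n - 1)$, averages $\hat F$ within each
degeneracy class, and reports

$$\mathrm{ENC} = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3} +
\frac{5}{\bar F_4} + \frac{3}{\bar F_6},$$

capped at 61. The single three-fold class (Ile) is frequently unobservable
in short genes; its class mean is then imputed as $(\bar F_2 + \bar F_4)/2$,
as CodonW does. If any other class mean is undefined or non-positive the
statistic is flagged not computable — never silently zero. The theoretical
range is 20 (one codon per amino acid) to 61 (uniform usage); sampling noise
can push the raw estimator far above 61 (61 codons each observed twice give
a raw value of 102), which is why the cap exists.

**CAI.** The geometric mean of per-codon relative adaptiveness $w$, where
$w = \mathrm{RSCU}/\mathrm{RSCU}_{\max}$ within each amino acid of a
reference set of highly expressed genes. The shipped default is the classic
*E. coli* table of Sharp & Li (1987); `reference_weights()` derives weights
from any user-chosen reference gene set and a two-column TSV is accepted
(`read_weights_tsv()`). Reference weights of 0 are floored at 0.01 so the
geometric mean stays finite. Because published CAI/CBI/Fop values depend on
which reference their authors had active, reproducing someone else's table
requires knowing that choice; the functions surface the weights rather than
hiding them.

**CBI and Fop.** Over amino acids possessing at least one "optimal" codon,
with $N_{opt}$ optimal codons used, $N_{tot}$ total and $N_{ran}$ the count
expected under uniform synonymous usage:
$\mathrm{CBI} = (N_{opt}-N_{ran})/(N_{tot}-N_{ran})$ and
$\mathrm{Fop} = N_{opt}/N_{tot}$. The default optimal set is the codons
carrying $w = 1$ in the active CAI reference — a deterministic convention of
this package — and is meant to be replaced by the species-specific set from
`determine_optimal()` once one exists.

**Base composition.** GC3s is the G/C fraction at synonymous third
positions (stop codons, Met and Trp excluded). T3s/C3s/A3s/G3s follow
CodonW's "silent base" convention: the frequency of base X at synonymous
third positions *among codons whose amino acid can accept X at position 3*.
Several inconsistent X3s definitions circulate; this one is stated precisely
because the denominators differ per base. GC is computed over the whole
sequence.

`usage_table()` assembles the classic per-gene table (columns `gene, T3s,
C3s, A3s, G3s, CAI, CBI, Fop, ENC, GC3s, GC`) with per-set `range` and
`average` summaries; averages are arithmetic means over genes, with
not-computable cells excluded.

## The ENC-plot

Under mutation pressure alone, the expected ENC at a given GC3s value $s$ is

$$\mathrm{ENC}_{exp} = 2 + s + \frac{29}{s^2 + (1-s)^2},$$

evaluating to 31 at $s=0$, 60.5 at $s=0.5$ and 32 at $s=1$. (The curve's
true maximum sits marginally above $s = 0.5$ — the linear $+s$ term shifts
it to $s \approx 0.5017$ — a detail that matters only to tests asserting
curve geometry.) `enc_deviation()` reports each gene's observed minus
expected ENC and classifies genes as `near`, `below` or `above` the curve.
The "near" band is an explicit parameter (default 2 ENC units): published
ENC-plot interpretations rarely define "close to the curve", so the
threshold is exposed rather than implied. Genes well below the curve use
fewer codons than their base composition predicts — the standard signature
of selection on codon usage beyond mutational bias.

## Optimal codons from an ENC partition

`partition_by_enc()` sorts genes by ENC and takes a fraction (default 10%,
round-half-up, minimum one gene) from each end. The **low-ENC tail is
treated as the putative high-expression set**: lower ENC means stronger
codon bias, the standard proxy when expression data are not part of the
analysis. Ties in ENC break lexicographically by gene id, so the partition
is invariant to input order. ΔRSCU is computed on **pooled codon counts** of
each tail (not per-gene RSCU means), the usual construction; codons with
ΔRSCU strictly greater than 0.08 are high-expression superior. Per amino
acid, the codon maximizing RSCU in the pooled full set is the high-frequency
superior codon, kept only when that RSCU strictly exceeds 1 (ties break
lexicographically and are flagged — six-fold families are treated as one
amino acid, not split 2+4). The optimal set is the intersection, reported
with A/U- vs G/C-ending tallies and, across species, shared/unique
membership tables (`compare_species()`). Both thresholds are arguments.

## Duplication–loss reconciliation

`reconcile()` embeds a rooted binary gene tree into a rooted binary species
tree by LCA mapping with unit costs — the assumption-light core of tools
like Notung, without bootstrap-guided rearrangement (which requires support
values this analysis does not consume). Every gene node maps to the species
LCA of its children's images; a node is a duplication iff it maps to the
same species node as one of its children; each gene edge implies one loss
per skipped species edge (plus one under a duplication parent). Duplications
are charged to the species branch ending at the mapped node, losses to the
branch of the species lineage in which the gene lineage disappeared, and a
single ancestral gene is assumed at the species root, so a family confined
to a subtree is explained by losses along the path from the root. From the
per-branch duplication/loss tallies the ancestral family size at every node
follows by conservation: count(child) = count(parent) + duplications −
losses. `expansion_report()` renders the per-branch "d:l" pairs, flags
expanding/contracting branches and writes an annotated Newick
(`label_d<dup>_l<loss>_n<count>`). Whole-genome duplication labels can be
carried as species-tree node labels; they annotate, but do not change, the
unit-cost model.

**What parsimony can and cannot recover.** Reconciled event counts never
exceed the true (realized) counts of a simulated history. They equal them
when events are isolated — at most one event per branch *and* no two
event-bearing branches sharing a species-tree node. Without that second
condition exact recovery is not merely hard but impossible for any method:
two sibling species each losing their only copy produce data identical to a
single loss on the parent branch, and a duplication whose two copies are
lost complementarily in the two child branches leaves no trace. The test
suite asserts exact recovery under the isolation condition and documents a
concrete sibling-loss counterexample under the weaker "one event per
branch" condition.

## Promoters and gene structure from GFF3

Coordinates are GFF3-native (1-based, inclusive) throughout. For a
plus-strand gene starting at $p$, `extract_promoters()` returns bases
$[\max(1, p-2000), p-1]$; for a minus-strand gene ending at $q$, the reverse
complement of $[q+1, \min(L, q+2000)]$ — in both cases the window abuts the
gene's 5′ end exactly. Windows clipped at contig boundaries are flagged
truncated and never padded. The window anchors on the *gene* feature by
default; `feature_type = "mRNA"` switches to transcript 5′ ends for
annotations where the two differ. `structure_summary()` reports, per
transcript, the gene-span length, CDS segment count, intron count (gaps
between consecutive exons, or between CDS segments when the annotation has
no exon features) and UTR segment count; when UTR features are absent, UTRs
are derived as exon∖CDS interval segments and marked `derived`. One
transcript per gene (the first mRNA) is summarized by default.

## Synthetic data: what it emulates and what it does not

`make_profile()` builds per-amino-acid codon distributions: the preferred
codon gets $\beta + (1-\beta)/k$, the rest $(1-\beta)/k$, so $\beta$ sweeps
uniform usage (ENC → 61 in long genes) to one-codon-per-amino-acid usage
(ENC = 20). A target GC3s is imposed by tilting all probabilities with a
common third-position G/C factor solved by `uniroot()` to $10^{-6}$;
infeasible targets (e.g. under $\beta = 1$, which pins every amino acid to
one codon) raise an error stating the attainable range. `generate_cds_set()`
draws gene lengths uniformly (default 100–400 codons, i.e. 300–1200 bp, so
every gene clears the screening floor), amino acids i.i.d. from a frequency
vector (default: uniform over the 18 multi-codon amino acids with Met/Trp at
a tenth weight), and codons i.i.d. from the profile, framing each gene as
ATG + body + stop. Codon sampling is deliberately context-free — no
dinucleotide or neighbour effects — because every statistic in scope is
context-free; passing tests therefore say nothing about context-dependent
features of real genomes (CpG avoidance, splice-site constraints,
amino-acid autocorrelation), nor about real length or expression
distributions.

`generate_family_history()` evolves a family down a species tree from one
root lineage with per-branch Poisson duplication and loss events (defaults
0.2 and 0.1 expected events per branch — an expansion regime, duplications
outnumbering losses, matching the behaviour of families like NLP). Losses
remove, and duplications copy, a uniformly chosen surviving lineage, the
simplest process whose event ledger a parsimony reconciliation can be
audited against. Events drawn on branches with no surviving lineage have no
effect and are not recorded. Histories leaving fewer than two genes are
rejected and resampled (with the count reported): a one-gene family has no
gene tree to reconcile, so this slightly extends the stated
reject-on-extinction rule.

## Numerical and design choices

* Round-half-up (`floor(x + 0.5)`) for the ENC-tail size, floored at one
  gene, so seven genes give one gene per tail.
* Strict inequalities at both optimal-codon thresholds (ΔRSCU > 0.08,
  RSCU > 1); boundary values are excluded.
* All deterministic tie-breaks are lexicographic (gene ids in the ENC sort,
  codons in per-amino-acid maxima) and ties are flagged in the output.
* CAI floor 0.01 for zero reference weights; geometric means are computed in
  log space.
* The GC3s tilt is solved on a log scale over $[-60, 60]$, covering the
  attainable range to beyond double precision.
* Internal codons are DNA-spelled; outputs intended for presentation (RSCU
  TSV, optimal-codon lists) use RNA spelling, matching the field's habit.
* Problem sizes in the test suite (up to 3,000-codon genes, 50-gene sets,
  hundreds of simulated histories on 6–7 species trees) were chosen as the
  smallest sizes at which the law-of-large-numbers assertions have
  comfortable margins.

## Known limitations

* Standard genetic code only; no mitochondrial or plastid codes.
* CAI/CBI/Fop values are only comparable across studies when the same
  reference weights and optimal sets are used; the built-in defaults are a
  documented convention, not a claim about any particular genome.
* Reconciliation assumes rooted, binary, error-free input trees; gene-tree
  estimation error masquerades as duplication/loss events, and no
  rearrangement, transfer events or dating are modelled.
* Promoter extraction is purely coordinate-based; it does not attempt to
  locate transcription start sites.
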