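---
title: "Diploid scaffolding with heterozygous bubbles: model, algorithm, and design"
author: "dipscaffold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diploid scaffolding with heterozygous bubbles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A stringently assembled diploid contig set contains two kinds of contigs:
*homotigs*, assembled from sequence that is homozygous between the two
haplotypes (their read pileup mixes both haplotypes and so shows diploid
depth), and *heterotigs*, assembled from sequence unique to one haplotype
(haploid depth). Under three assumptions — no large-scale rearrangements
between haplotypes, exactly one homologous partner heterotig per heterotig,
and heterotig pairs embedded in *bubbles* (flanked by a common homotig on
each side) — the genome reconstruction problem becomes: find the bubbles in
the scaffold graph, decide which candidate heterotig pairs are truly
homologous, chain the bubbles, assign each heterotig to a haplotype, and
print two linear haploid sequences per chain.

`dipscaffold` implements that pipeline, a synthetic diploid benchmark
generator with per-read truth labels, and four truth-based quality metrics.

## The scaffold graph

Each contig has a 5' and a 3' end. A read pair whose two ends map uniquely
to different contigs nominates one end of each: a forward-strand hit
nominates the 3' end of its contig, a reverse-strand hit the 5' end (the
standard innie geometry — the unsequenced fragment interior extends toward
the nominated end). The implied gap is

    gap = mean_insert − tail_1 − tail_2

where a *tail* is the distance from the alignment's outer read edge to the
nominated contig end (the read length is part of the tail). Identical
(end, end) links aggregate into one bidirected edge whose weight is the
number of supporting pairs and whose gap estimate is the arithmetic mean of
the per-pair gaps; negative estimates (overlapping contigs) are retained and
only floored at FASTA emission. Edges below a minimum support (default 2)
are marked excluded but are kept for dashed rendering in DOT output. Pairs
with a multiply-mapped end are suppressed by default
(`allow_multimapped = FALSE`); every input pair is accounted for in a
PairStatus metafile.

Repeat-like contigs are flagged by abnormal vertex degree (>
`degree_factor` × the median degree of linked contigs ≥ 100 bp, default 5×)
or abnormal depth (> `depth_factor` × the modal depth, default 3×). The
depth default deserves a note: in a diploid contig set heterotigs usually
outnumber homotigs, so the modal depth is the *haploid* mode and ordinary
homotigs sit at exactly twice it. A 2× threshold would flag half of all
homotigs; 3× (1.5× the diploid depth) separates genuine collapsed repeats
from homotigs. Flagged contigs are excluded from bubbles, chains, and
output.

## Bubbles and classification

A *perfect bubble* is a pair of contigs (a, b), each with exactly one
scaffolding per direction, leading to common flanks c1 and c2 that attach at
one consistent end of each flank carrying no other edges. Perfect bubbles
are so constrained that their heterotig pairs are assumed to be true
homologs; they form the training set. Candidate *imperfect bubbles* — with
missing or conflicting edges — are seeded from every contig pair sharing a
flank end and completed with each viable far flank. Every construction is
scored with a `(missing_edges, conflict_count, total_support)` lexicographic
perfectness key. A flank-less construction (both near-flank edges present,
far flank absent) is always offered as a conservative fallback: short
heterotig pairs flanked by short homotigs can be geometrically impossible to
link to their far flank with a fixed-insert library, yet remain genuine
bubbles.

Each candidate pair is described by six features: length ratio
min/max, depth ratio min/max, percent identity of the best local alignment,
alignment length as a percentage of the shorter contig, and each contig's
depth relative to the modal depth of all contigs (for a true pair at
haploid depth, both ≈ 1). Without a depth table the three depth features
are dropped (reduced-feature mode) and classification power falls but the
pipeline still runs.

Sequence identity uses BLASTn-tabular semantics (identical columns /
alignment columns, best local alignment, match +2 / mismatch −3 / gap
open 5 / gap extend 2 per column). Two engines sit behind one interface:
an exact affine-gap Smith–Waterman (row-vectorised DP with documented
tie-breaks: first score maximum in column-major order; diagonal over
vertical over horizontal; gaps end as early as possible; arguments
canonicalised by lexicographic order so the symmetric-quantity contract
holds) used up to 4×10⁶ DP cells, and a `blastn` subprocess for longer
pairs — the engine the similarity measure is defined against in the first
place.

The learner is pluggable: logistic regression (`stats::glm`, the
deterministic default), a single-hidden-layer perceptron (`nnet`), or a
linear SVM (`e1071`). Negative training examples are seeded random contig
pairs sharing no graph edge and not partnered in any perfect bubble, at a
configurable 1:1 ratio — the simplest unbiased null, since real negatives
are unlabeled. A pair is called homologous when P ≥ 0.5 (ties classify
positive). Training requires at least `min_training = 10` perfect bubbles;
below that the pipeline warns and emits bubble-only scaffolds.

## Acceptance, chaining, phasing, emission

Perfect bubbles are included first. Classified imperfect candidates are
considered in decreasing perfectness; a bubble is accepted only if none of
its constituent edges conflicts with or duplicates an already-included
edge. Occupancy is per contig end — a contig may be scaffolded once in each
direction per iteration — with one deliberate reading: a bubble's two
parallel edges on a flank end count as a *single* scaffolding of that end,
because the bubble is both candidate reconstructions of one locus. Since a
pair can be offered under several constructions, occupancy also guarantees
at most one construction per pair is ever included, and a pair whose best
construction conflicts still gets a chance with its next one.

Remaining edges of the current library rank are linked greedily in
decreasing weight (lexicographic tie-break), skipping occupied ends,
repeat-flagged contigs, and the ends of accepted-bubble heterotigs — the
last exclusion keeps every chain a clean alternation of homotigs and
heterotig pairs, which is what the two-haplotype emission consumes; the
open flank of a partial bubble simply terminates its chain. Iterations
beyond the first (larger-insert ranks) only link existing chains
end-to-end and contribute phasing evidence; occupancy persists across
iterations, so later ranks can only join chain terminals. Phasing is
re-evaluated after all ranks.

Phasing two-colours the heterotigs of each chain: read pairs joining
heterotigs of different bubbles vote for same-colour assignment, and
colours are assigned greedily along the chain by majority vote against the
currently open group pair. No evidence — or an exact tie, which is logged
as a conflict — closes the current complementary group pair and starts a
new one, so unphased bubbles still emit as opposite haplotypes with a
deterministic assignment (the group holding the lexicographically smallest
member becomes haplotype 1). Emission applies orientations by reverse
complement and renders gaps as N-runs of length `max(round(gap), 10)`
(rounding half away from zero); within a bubble boundary the haplotype's own
edge gap is used when available. Singletons are emitted identically in both
haplotype files. Rare cycles in the included-edge structure are broken
deterministically before the lexicographically smallest member contig.

## The synthetic benchmark

The generator builds the full truth-labeled universe: a diploid genome, a
stringent-assembly contig set, error-free paired reads, and their exact
placements.

**Variant landscape.** `generate_diploid()` places variant sites either
uniformly at `het_rate` per base, or — the benchmark's condition — in a
clustered landscape (`placement = "blocks"`): alternating homozygous runs
(exponential, mean 400 bp) and heterozygous blocks with a within-block rate
of 0.1 per base, block lengths chosen so the overall rate is still
`het_rate` (0.04 by default). Real diploid heterozygosity is clustered, and
only a clustered landscape produces the interleaved homotig/heterotig
geometry — homozygous runs long enough to assemble and to anchor a 400-bp
insert — that diploid scaffolding presupposes; under uniform placement at
0.04/bp a run exceeding 150 bp occurs once per ~370 variants and the
contig set degenerates to near-pure heterotigs. The 400-bp run mean and
0.1 within-block rate were calibrated once against the observed scale of a
stringent ~5-Mb diploid assembly (~21k contigs). Each site becomes a 1–5-bp
indel with probability `indel_fraction = 0.1` (insertions and deletions
equally likely, deletions truncated so variant footprints never collide),
otherwise a SNP.

**Stringent assembly surrogate.** The assembler is simulated, not
implemented: each variant is padded by `pad = 74` bases (read length − 1,
the furthest a haplotype-specific contig can extend into shared sequence),
padded blocks separated by homozygous runs shorter than
`min_homozygous_run = 150` merge, merged blocks become heterotig pairs, and
each remaining homozygous run becomes a homotig spanning the full run — so
homotig and heterotig share up to `pad` bases of flanking sequence, exactly
as stringent assembly of both haplotypes duplicates shared flanks. Runs at
the genome edge shorter than the threshold stay unassembled.

**Reads and placements.** Fragments are drawn uniformly per haplotype to a
per-haplotype coverage (default 40× per library; 75-bp ends, innie, insert
sizes rounded-normal and clamped to [2·read_len, 2·mean]). Placement
mirrors a stringent unique-placement aligner on the truth geometry: a read
containing a variant places in its haplotype's heterotig; a variant-free
read fully inside a homozygous run places in the homotig (both haplotypes
collapse); a variant-free read inside a heterozygous block matches both
heterotigs and is suppressed; boundary-spanning reads are unmapped.
Placements are emitted in any of the three alignment dialects, with real
read sequences on request (the SAM round-trip is exact in the error-free
regime).

What the generator does *not* emulate: sequencing error, quality strings,
repeat families, chimeric fragments, misassembled contigs, or
rearrangements between haplotypes. Passing the benchmark therefore
demonstrates the scaffolding and phasing logic under the method's own
assumptions, not robustness to violations of them.

## Quality metrics

With per-read haplotype truth (A or B), four metrics summarise a run, all
restricted to contigs > 100 bp:

* **Contig sequencing depth** — summed member-read length over contig
  length. Homotigs peak at diploid depth, heterotigs at haploid depth.
* **Contig homogeneity** — the fraction of a contig's reads deriving from
  haplotype A. Heterotigs should sit at 0 or 1, homotigs at 0.5.
* **Phase-group homogeneity** — the read-weighted A-fraction over a
  phase group's contigs; accurate groups cluster at 0 and 1.
* **Heterogeneity between complementary groups** — the difference of the
  two groups' A-fractions, reported as an absolute value. The signed form
  presumes an orientation of the pair; the absolute value is
  label-invariant and clusters at 1 for accurate phasing.

A depth-threshold summary reports the fraction of heterotig-classified
contigs below a cutoff (precision-like) and the fraction of below-cutoff
contigs classified (recall-like); the cutoff defaults to 1.5× the modal
depth, the scale-free generalisation of a fixed haploid-depth cutoff.
Densities are exported as histogram tables for headless use; `plot()` draws
the depth-by-class figure.

## Problem sizes and determinism

The package's validation runs on a seeded 500-kb benchmark (≈ 515 heterotig
pairs, ≈ 1.1 M reads across both libraries), where ≥ 95 % of true pairs are
recovered as perfect or classified bubbles, phase groups are essentially
pure, and the heterotig/homotig modal-depth ratio sits near 0.5. Unit tests
use 60–120-kb universes. All randomness flows from explicit seeds (genome,
per-library reads, negative sampling, learner initialisation); two runs
with identical seeds produce byte-identical FASTA/TSV/DOT outputs.

## Known limitations

* Bubbles with more than two parallel paths (polyploidy) and superbubble
  generalisations are out of scope.
* Rearrangements or inversions between haplotypes violate the model's
  first assumption and are not handled.
* Gap estimation is a plain mean of insert-implied distances; no
  maximum-likelihood refinement.
* Heterotig pairs whose both flanking homotigs are too short to anchor any
  library insert are structurally invisible to the method and stay
  unrecovered (observed at ~1–3 % on the benchmark).
* The greedy chain linker does not extend chains through the open flank of
  a partial bubble.
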