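---
title: "Methods: synteny-aware one-to-one ortholog inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synteny-aware one-to-one ortholog inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(syntolog)
```

## The model

`syntolog` infers strict one-to-one orthologs between two annotated
genomes. The unit of comparison is the protein-coding gene locus; isoforms
enter only to pick the best-scoring representative pair. Three metrics are
computed for every candidate homolog pair (X, Y):

- **Protein modified Jaccard** `J_p = S_xy / (S_xx + S_yy − S_xy)`, where
  `S_xy` is the local alignment score of the best isoform pair and `S_xx`,
  `S_yy` are the self-alignment scores under identical scoring parameters.
  Raw alignment scores scale with protein length; dividing by the remaining
  "potential similarity" makes scores comparable across pairs of very
  different lengths. `J_p = 1` exactly when the cross-alignment matches the
  self-alignments.
- **Nucleotide modified Jaccard** `J_n = L / (len_x + len_y − L)` over the
  *flanked exonic sequences*: all exons of the chosen isoform (UTRs
  included) concatenated in transcript order, extended on both ends by up
  to 2 kb of exonic sequence collected from adjacent genes walking outward
  in gene-rank order. `L` is the total number of aligned bases over
  non-overlapping local alignments. Flanks let conserved neighboring exons
  vote for the pair even when the focal exons are short, without ever
  including intergenic or intronic sequence. The lengths in the denominator
  are those of the flanked sequences actually compared.
- **Microsynteny** `N`: homologous gene pairs between the two 20-locus
  neighborhoods (at most 10 adjacent loci per side; windows never span
  scaffolds). "Homologous" means membership in the candidate table, not a
  finalized ortholog call — using calls would be circular. Neighbors are
  matched one-to-one so a duplicated neighbor cannot inflate `N`.

Candidate pairs are those whose `J_p` is within 20% of the best score for
either gene (`≥ 0.8 ×` the per-gene maximum). The filter is applied on the
normalized score, which is the quantity the rest of the method compares;
every gene's best pair always survives.

### The decision

Each candidate pair is evaluated against its *competitors* — all candidate
pairs sharing either of its genes. With `N ≥ 1`, acceptance requires any of:

- **S1**: no competitor has microsynteny support, and `J_p` is ≥ every
  competitor's.
- **S2**: `N ≥ 2` while no competitor has microsynteny support (no protein
  clause: two conserved neighbors outweigh a marginally better paralog
  score).
- **S3**: `N` exceeds every competitor's, `J_n` is ≥ every competitor's,
  and `J_p` beats every competitor by at least 5% and is the top score for
  either gene.
- **S4**: `N` exceeds every competitor's by at least 2 and `J_n` is ≥
  every competitor's.

With `N = 0`, all of the following must hold: no competitor has synteny
support; the protein alignment covers more than 50% of the longer and more
than 90% of the shorter protein; both `J_p` and `J_n` beat every competitor
by at least 5%; and `J_p` is the top score for either gene.

Afterwards, any gene appearing in more than one accepted pair has all its
accepted pairs demoted. The final call set is therefore a partial matching;
ambiguous situations (e.g. identical recent duplicates) produce no call for
any involved gene, by design trading recall for precision.

Interpretation choices where the written rules leave latitude:

- "at least 5%" margins are multiplicative (`≥ 1.05 ×`): the compared
  quantities are ratios and margins are stated in percent.
- "greater than or equal" is `≥`, "exceeded" is `>`, coverage "more than"
  is `>` — the wording taken literally.
- S1 applies only when *no* competitor has synteny support; allowing it
  alongside syntenic competitors would contradict the stricter demands S3
  and S4 place on exactly that situation.
- Comparisons over an empty competitor set hold vacuously — a lone
  syntenic pair is accepted via S1 — but the coverage thresholds of the
  zero-synteny path always apply.
- "top score for either gene" allows ties (`≥` all competitors on that
  gene); the 5% margin clause in the same rules makes the distinction moot
  in practice.

### Transitive anchors, sets, and nomenclature

Ortholog sets are keyed by the gene identifiers of an anchor genome. For
clades distant from the primary anchor, orthologs are computed against a
clade-internal transitive anchor B and composed: (c, a) is emitted iff
(c, b) and (b, a) are both accepted one-to-one pairs. Query genes whose B
ortholog has no A ortholog stay in B's sets. Symbols propagate from the
anchor gene to all set members unless the anchor symbol is a placeholder
(`LOC<digits>`, `CG<digits>` by default, configurable) or the member is
blocklisted; propagation is idempotent. `verify_transitive_agreement()`
diffs transitively inferred against directly computed pairs for
curation-style review.

## Tunable parameters

| key | default | meaning |
|---|---|---|
| `candidate_ratio` | 0.8 | keep pairs within 20% of either gene's best `J_p` |
| `score_margin` | 1.05 | the "at least 5%" multiplicative margin |
| `min_coverage_longer` / `min_coverage_shorter` | 0.5 / 0.9 | coverage thresholds of the zero-synteny path |
| `synteny_window` | 10 | loci per side of the microsynteny window |
| `synteny_delta` | 2 | `N` margin of rule S4 |
| `flank_len` | 2000 | exonic flank per side, bases |
| `protein_matrix`, `protein_gap_open/ext` | BLOSUM62, 11/1 | bundled protein aligner |
| `protein_score_floor` | 60 | raw-score floor standing in for an E-value cutoff |
| `nt_match/nt_mismatch` | +2/−3 | nucleotide scoring |
| `nt_kmer`, `nt_xdrop`, `nt_score_floor` | 11, 30, 50 | seed length, extension drop-off, HSP floor |

The floors are set so that unrelated random sequences (50-residue proteins,
500-base nucleotide stretches) produce no record, while genuinely homologous
sequences at the divergences the method targets sit far above them.

## Numerical and implementation choices

- Coordinates are 0-based half-open internally; GFF3 I/O converts to/from
  1-based inclusive. Gene order (rank) is ascending span start with ties
  broken by span end, then gene id; overlapping or nested genes keep their
  own ranks so ranks are always a total order.
- The bundled protein backend is Smith–Waterman local alignment
  (Biostrings) under BLOSUM62 with affine gaps. Self scores are the sum of
  diagonal substitution scores, which equals the local self-alignment score
  because every diagonal entry is positive (verified against the aligner in
  the tests).
- The bundled nucleotide backend is a compiled seed-and-extend HSP finder:
  exact 11-mer seeds, gap-free x-drop extension, both strands, then greedy
  selection of non-overlapping HSPs by descending score (ties by position).
  `aligned_length` is the summed width of the selected HSPs. Full dynamic
  programming over two ~5 kb flanked sequences costs seconds per pair;
  seed-and-extend is the standard approach for this job and is exact on
  the clean-identity cases, which the tests verify against full
  Smith–Waterman.
- Isoform-pair ties on `J_p` break to the lexicographically smallest
  (query isoform, subject isoform). All stage outputs have deterministic
  order; identical inputs give identical bytes.
- Flanks take each neighbor's representative (longest-protein) isoform,
  concatenated in genomic order and clipped to keep the bases nearest the
  focal gene; 5′/3′ are in the focal gene's transcript orientation
  (minus-strand constructs are reverse-complemented wholesale). Exonic
  bases shared by overlapping neighbors are taken per neighbor in rank
  order, without deduplication.
- Microsynteny matches neighbors greedily in rank order (each query
  neighbor takes its lowest-rank unmatched partner). Greedy maximal
  matching is not in general symmetric under swapping the genomes, but is
  on one-to-one candidate structures; the seeded property tests cover both.

## The simulator

`simulate_genome_pair()` evolves an ancestral gene set into two descendants:
codon sequences split into exons with intron and intergenic spacers,
per-site substitutions applied at the codon level (stop codons re-drawn) so
protein and nucleotide divergence stay consistent, gene losses, segmental
inversions (order reversed, strands flipped), duplications before the split
(diverged copies, resolvable through synteny and part of the truth) and
after the split (identical tandem copies, ambiguous by construction and
excluded from the truth). Translations use the standard genetic code; CDS
spans all exons unless `add_utr` adds an untranslated 5′ exon to exercise
the UTR-inclusion path.

Defaults are the standard validation scenario: 200 genes on 2 scaffolds,
5% pairwise divergence, 10 losses, 5 pre-speciation duplications, 2
inversions. Two scaffolds of ~100 genes mimic per-chromosome gene density
at desk scale; spacer and intron lengths are kept short (tens to hundreds
of bases) since only exonic sequence enters any metric. What the simulator
deliberately does not model: indels, rate heterogeneity across sites and
lineages, mobile elements and repeats, alternative splicing beyond a single
isoform, and annotation errors. Passing the planted-truth tests therefore
demonstrates the logic of the method — normalization, windowing, the
decision rules, one-to-one enforcement — not robustness to the full
messiness of real annotations.

Problem sizes used by the test-suite validation runs: the planted-truth
scenario above (~200 genes per genome), one hundred 10-gene simulations
with an identical tandem duplication each for the one-to-one and
ambiguity checks, and a clean 60-gene trio for transitive-anchor
agreement.

## Known limitations

- A 20-locus window over a 200-gene scaffold pair has non-trivial chance
  collocation: randomly permuting one genome's gene order leaves an
  expected `N ≈ w(w+1)/L` (~3.6 observed with w = 10 per side and L ≈ 100
  genes per scaffold). The shuffle control in the tests demonstrates the
  ~80% drop in mean `N` with byte-identical protein scores; mean `N` only
  approaches zero as scaffolds grow toward realistic gene counts.
- The greedy HSP selection is a heuristic for the maximal non-overlapping
  alignment set; adversarial repeat structures could select a suboptimal
  subset (exhaustive selection verifies it on the tested fixtures).
- One-to-many and many-to-many orthology, paralog classification and gene
  trees are out of scope; genes without an unambiguous one-to-one partner
  are simply reported uncalled in the full results table.
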