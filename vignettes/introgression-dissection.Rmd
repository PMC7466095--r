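---
title: "Dissecting an introgression sub-line with dual-reference variant calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting an introgression sub-line with dual-reference variant calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introdissect)
```

## The model

An introgression sub-line is, genomically, a piecewise genome: the
cultivated background everywhere except one homozygous segment that is the
wild donor's homologous sequence, with a crossover point at each edge. The
package treats dissection of such a line as five coupled inferences.

**Per-gene ancestry from two references.** Expressed reads from the line
are variant-called against both parental genomes. For a gene with
background ancestry, the line's sequence matches the background reference
(few or no variants) and diverges from the donor reference (many variants);
for an introgressed gene the pattern reverses. `classify_ancestry()` calls
a gene `donor` iff `n_vs_background > n_vs_donor` and the winning count
reaches `min_informative`, `background` in the mirrored case, and `unknown`
otherwise. The rule's assumptions: variants are homozygous (the line is a
fixed homozygous introgression; heterozygous calls are filtered as noise),
and divergence between the parents is high enough that an expressed gene of
either ancestry yields several diagnostic variants. At the divergence the
generator emulates (~1% per bp), a 1.7 kb gene carries ~17 diagnostic
variants, so `min_informative = 2` costs essentially no sensitivity while
guaranteeing that one stray variant — the sub-percent noise regime a
genome-wide purity scan shows — can never flip a call. Ties go to `unknown`
rather than either parent because the downstream marker stage, not the
variant counter, is the instrument for ambiguous genes.

**Breakpoints as uncertainty intervals.** Between the last gene with
background evidence and the first donor-diagnostic variant there is no
information about where the crossover lies, so `infer_breakpoints()`
reports each block edge as an open interval rather than a point: lower edge
`(last background-called gene end, first donor-diagnostic variant in the
block)`, mirrored above. Unknown-ancestry genes inside a donor run bridge
the run (unexpressed genes must not split a block), up to `max_bridge = 3`
consecutive unknowns; a background call always breaks the block. Strict
mode errors on more than one block because the target line carries a single
introgression; multi-block mode exists for other material.

**Reconstruction and lift-over.** `merge_genomes()` builds
`background[1..cut] + donor[span] + background[cut'..]`. The cut inside
each uncertainty interval defaults to the midpoint — the least-committal
choice given only bounding evidence — and can be anchored at either bound
(`last_donor`, `first_background`) when a conservative donor-maximal or
donor-minimal reconstruction is wanted. The donor source span is taken from
the donor-side gene models of the block's donor calls. The
`reconstruction_map` is a strict object: target segments tile each target
chromosome from 1, every segment conserves length, and the map inverts
exactly, which makes lift-over (`liftover()`) a pure offset shift and lets
a round-trip test assert coordinate identity. Genes spanning a junction are
returned as `chimeric_candidates`, never silently lifted.

**Chimera localization.** For a border gene the crossover can fall inside
the gene. Given a three-row alignment (line, donor allele, background
allele), every column where the parents differ is a diagnostic site
(`call_diagnostic_sites()`; adjacent gap columns collapse to one site,
left-anchored, so one indel is one site). Under a single-crossover model
the line matches the donor before the crossover and the background after
it; `locate_recombination()` chooses the split over the ordered informative
sites maximizing concordance — equivalent to minimal misclassified sites —
rather than the first discordant site, because Sanger reads carry errors.
`min_run = 3` concordant sites are required on each side so a single
sequencing error cannot fabricate a crossover. Sites matching neither
parent are excluded from the objective but reported. The result is the open
interval between the last donor-matching and first background-matching
site, annotated by `annotate_interval()` to the gene feature(s) containing
it.

**Orthology typing.** Relationships between the replaced and introgressed
gene sets are typed from a similarity hit table (the standard 12-column
tabular dialect, or desk-scale local alignments via `align_proteins()` —
Smith–Waterman with affine gaps and a Karlin–Altschul e-value proxy).
`classify_relationships()` applies, in order: one-to-many (duplicated)
groups, BBH, species-specific, then best-match homology for the remainder.
Duplicated-group detection requires the group's members to score within
`duplicate_score_ratio = 0.9` of the best member: recently duplicated genes
are near-equally similar to their shared partner, and without this window a
strong ortholog plus a weak interloper would masquerade as a duplication.
Full inparalog clustering with bootstrap confidence is deliberately not
re-implemented; BBH + one-to-many typing expresses every distinction the
regional accounting uses. The collinearity check
(`segment_order_check()`) computes the longest subsequence of ortholog
pairs strictly increasing in both parents' gene ranks and reports each
maximal excluded run as a translocated block; on the packaged region table
it reports exactly one block, the signature of the second donor segment
being embedded in the first.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_mean_depth` | 5 | reads | depth filter on variant calls, threshold inclusive |
| `require_homozygous` | TRUE | — | the line is a fixed homozygous introgression |
| `min_informative` | 2 | variants | winning count needed for an ancestry call |
| `max_bridge` | 3 | genes | unknowns bridged inside a donor block |
| `fdr_threshold` | 0.05 | — | strict DEG significance cutoff |
| `evalue_threshold` | 1e-10 | — | maximum e-value for an informative hit |
| `duplicate_score_ratio` | 0.9 | — | score window defining a duplication group |
| `min_run` | 3 | sites | concordant sites per side of a chimera split |
| `cut` | midpoint | — | cut placement inside an uncertainty interval |
| CAPS `tolerance` | 0 | relative | fragment-length match window (0.05 mimics gel resolution) |

## What the generator emulates — and what it does not

`sim_config()` defaults define the simulated study conditions: 2
chromosomes of 75 kb; 25 gene slots per chromosome of which 20 hold shared
(orthologous) genes, with species-specific and duplicated extra genes on
the last chromosome; every gene 1.7 kb on the plus strand with a fixed
5'UTR (200 bp) – CDS (1200 bp) – 3'UTR (300 bp) layout; parental divergence
`snp_rate = 0.008` and `indel_rate = 0.002` per bp (an 80:20 SNP:INDEL
mixture, ~17 variants per gene); indel lengths geometric (p = 0.5, capped
at 50 bp) and never spanning a feature boundary, so coordinate arithmetic
stays exact; a donor block covering genes 8–14 of chromosome 1 whose upper
crossover falls strictly inside the last block gene's 3'UTR;
`expression_dropout = 0.2` (an unexpressed gene emits no variants against
either reference); and `variant_error_rate = 1e-5`, planting isolated
spurious singletons (~1% of calls) that never form a two-gene block.
Because the sequenced border gene of the motivating study shows locally
elevated divergence around its crossover, the generator tops the chimeric
gene's 3'UTR up to ~8 diagnostic substitutions before placing the
crossover, and places it where at least three diagnostic differences flank
it on each side within the gene — otherwise a single-split localizer has,
correctly, nothing to find. Each generator operation reseeds a private
stream derived from `seed`, so outputs are byte-identical across runs and
independent of call order.

The generator does **not** emulate: read-level sequencing (no FASTQ, no
quality model), heterozygous genotypes beyond the error fraction,
overlapping or minus-strand gene models, recombination hotspots, or
realistic repeat content. Passing the end-to-end tests therefore shows the
inference machinery is correct under the stated statistical structure, not
that the pipeline is robust to alignment artifacts or structural variation
in real data — those enter upstream of this package, in the external
mapping and calling steps whose outputs it consumes.

In simulation, marker resolution genotypes CAPS assays on gene spans
extracted through the coordinate maps rather than via in-silico PCR;
`find_amplicon()` is exercised separately so that marker informativeness is
not confounded with primer-site divergence.

## Numerical and degenerate-input choices

* All coordinates are 1-based inclusive end to end (`interval_span(a, a) = 1`);
  no half-open representation is exposed.
* Depth and FDR thresholds: depth is kept at `>= 5` (inclusive); DEG
  significance is strict (`fdr < 0.05`), and a significant record with
  `logFC = 0` is flagged and excluded rather than assigned a direction.
* Best-hit ties break by score, then lexicographic subject id, and the
  tie-break is recorded in the output.
* The chimera split takes the first maximizer when several splits tie.
* A donor block at a chromosome edge degenerates to bounds 0 / `Inf`; a
  donor span of zero length reproduces the background identically with a
  one-segment map.
* Empty variant sets give zero counts and zero (not `NaN`) fractions in the
  purity report; report percentages are rounded to one decimal for
  presentation while the underlying fractions keep full precision.
* Restriction digestion counts overlapping site occurrences; cuts at
  position 0 or at the sequence end are no-ops, and fragment lengths always
  sum to the input length.

## Fixture-specific decisions

The packaged region table preserves two quirks of its printed source. Rows
whose donor coordinates are printed end-before-start encode minus-strand
genes and are normalized on read (`start <= end`, strand `-`). One row
(Sopen07g024590) is printed as a BBH with an empty background-partner cell;
the fixture keeps the cell empty and flags the row, while the derived hit
structure (`implied_hits()`) supplies the reciprocal partner under the id
its sort position implies (Solyc07g049260) so the row types as the printed
BBH — that id appears only in the derived hits, never in the fixture. The
common-DEG fixture carries two coordinate sets: the positions as printed
(an older assembly) and harmonized coordinates matching the assembly of the
region table, which are the ones used for region intersection; without the
harmonization the printed in-region genes do not numerically overlap the
region, an artifact of mixing assembly versions. The border-gene feature
model (`border_gene_model()`) is synthetic in its 3'UTR boundary (the
printed material gives the gene span and the fact that the crossover lies
in the 3'UTR, not the boundary itself).

One genuinely open question is left open: whether the two donor segments
reflect a donor-assembly mis-assembly or a double recombination cannot be
decided from the data the package consumes; `segment_order_check()` reports
the translocation and `infer_breakpoints(strict = FALSE)` supports
multi-block material, but nothing in the package commits to either
hypothesis.

## Problem sizes

The test suite and the acceptance script run the generator at the default
2 × 75 kb scale: 10 error-free and 50–100 noisy replicates for the recovery
and containment properties, 1,000 random maps for lift-over round-trips,
1,000 random sequences for digestion conservation, and brute-force oracle
comparisons at ≤ 10 genes / ≤ 50 sites. These sizes were chosen so each
property is measured on thousands of cases while a full run stays in the
low minutes on one core.

## Limitations

* Variant calling, read alignment, multiple sequence alignment and
  differential-expression fitting are consumed, not computed; garbage in,
  garbage out.
* The chimera model allows exactly one crossover per gene; a double
  crossover inside one gene would be reported as the best single split with
  misclassified sites.
* Orthology typing is regional and operational (best hits), not
  phylogenetic; it will not distinguish ancient paralogy from orthology.
* The CAPS genotyper compares fragment-length multisets; co-migrating
  fragments of different sequence are indistinguishable, as on a gel.
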