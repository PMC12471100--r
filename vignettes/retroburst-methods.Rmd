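---
title: "Models and methods behind retroburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retroburst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

retroburst analyses the copy dynamics of LTR retrotransposon families:
delimiting full-unit elements on genomic contigs, building family
consensus elements, and quantifying how copy sets evolve after a
transposition burst. This vignette explains the models, the defaults and
the numerical choices, and what the synthetic data generator does and does
not establish. It states no empirical result that the test suite does not
itself compute.

## The biological model

An autonomous LTR retrotransposon is a `5'LTR - internal - 3'LTR` unit.
The two LTRs are identical at the moment of insertion, because reverse
transcription regenerates both from a single template; they subsequently
diverge under host mutation, which makes LTR-pair identity a molecular
clock for insertion age. Integration duplicates a short host motif -- here
the canonical 4 bp -- on both flanks (the target site duplication, TSD),
and the LTRs of the families modelled here begin `TGT` and end `ACA`.
First-strand cDNA synthesis is primed by a host tRNA annealing to the
primer binding site (PBS) just inside the 5'-LTR, so the PBS is the exact
reverse complement of a tRNA 3' terminus.

Copy sets expand under a master-lineage model: a few replication-competent
masters spawn progeny; most progeny are dead on arrival and decay
neutrally, while master-competent lineages remain under purifying
selection on the Gag-Pol ORF. A recent burst leaves a star-like genealogy
whose signature is an excess of rare variants -- negative Tajima's D and
Fu & Li's D/F -- without requiring classical population-genetic selection.

## The simulator (`make_template`, `simulate_expansion`)

The generator encodes exactly this model. Its defaults are the stated
world of the analyses and are not tuned to test outcomes:

* element geometry: LTRs of 251--521 bp (default 300), full unit within
  4740--5190 bp (default 4900), a single ATG-initiated, stop-free ORF
  (default 3900 bp including the terminal stop) with an in-frame upstream
  stop planted so ORF prediction is exact, and a 1311-bp codon-anchored RT
  core used for dN/dS work;
* `mu_r = 2e-4` errors/site/replication and `mu_h = 1e-3`
  substitutions/site/time-unit with a default age of 10 units: that puts
  intra-family pairwise divergence near 2% and LTR-pair identities near
  98--99%, the "recently expanded" regime of the empirical families. Time
  units are arbitrary; only the products `mu_h * age` matter;
* a transition/transversion rate ratio of 2, uniform base frequencies, no
  rate heterogeneity -- the simplest process that produces the familiar
  transition-saturation curves;
* selection as acceptance sampling: on master-competent lineages a
  proposed nonsynonymous ORF change is accepted with probability `omega`
  (default 0.1) and stop gains are rejected; dead copies accept
  everything. Replication resets the daughter's LTR pair to identity;
* insertion chooses a host position outside existing elements (nested
  insertions are out of scope), duplicates the 4-mer at the target site,
  and picks a strand at random; host background is i.i.d. uniform DNA so
  the annotator is tested without repeat confounders;
* indels (default off) follow a geometric length distribution and avoid
  the RT core, so codon alignments of the RT region stay frame-clean, the
  same convention as removing copy-specific indels before codon analyses.

Copies are stored as a "ragged template" (one slot per founding-element
position), which makes the true multiple alignment available by
construction, along with a full truth table and the genealogy in Newick.

What a green test on simulated data establishes: that the implementations
recover what this model planted -- boundaries, TSDs, selection strength,
frequency-spectrum signatures. What it does not establish: performance on
real assemblies with nested insertions, solo LTRs, segmental duplications
or low-complexity repeats. A low-complexity decoy is deliberately absent
from the default world; the annotator's k-mer seeding would need
repeat-masking there.

## Element delimitation

`find_ltr_pairs` seeds the window against itself with exact 12-mers,
groups seeds into diagonal bands (+/- 50 bp) and chains them at gaps up to
2 kb; extension is gapless along the modal diagonal of a chain with a
4-mismatch run cutoff. Because extension overshoots into flank by a few
bases, terminus placement re-scans +/- 30 bp for positions where both
copies carry `TGT` (starts) and `ACA` (ends); every valid combination is
emitted as a candidate, nested variants that do not beat their encloser's
identity are dropped, and the rest are ranked by identity, then length,
then position. `confirm_element` then reads the 4-bp flanks; elements are
returned regardless, flagged `tsd_confirmed` only when the flanks match
exactly ("if possible" semantics). `annotate_genome` prefers the first
TSD-confirmed candidate containing the anchor: the TSD is the one signal
that pins the true boundary when several terminus placements tie on
identity. Contigs under 10 kb are skipped as potential assembly chimeras,
elements with > 50% reciprocal overlap are deduplicated, and strand is
called from ORF orientation of the internal region (direct-repeat
detection itself is strand-symmetric because `TGT...ACA` is its own
terminus pattern under reverse complement). A `termini_mismatch` allowance
(default 1 of the 12 terminal bases) admits mildly decayed copies.

## Statistics

**Deletion conventions.** Neutrality tests use complete deletion of
gapped/ambiguous columns (the DnaSP convention); distances use pairwise
deletion plus, for group p-distances, a 90% site-coverage column filter
and 1000 column-bootstrap replicates for standard errors (the MEGA
convention). Groups with one member report `NC`. The p-distance here is
the literal proportion of differing sites; a source that pairs
"p-distance" with a composite-likelihood model is internally contradictory
and the literal reading is the default.

**F84 distance.** Closed form from the transition proportion `P`,
transversion proportion `Q` and the pooled pair frequencies; it reduces to
Kimura's two-parameter distance at uniform frequencies and is checked
against a numerical ML fit of the F84 rate matrix. Non-positive log
arguments are reported as saturated (`NA`) rather than clamped; degenerate
frequency classes fall back to the p-distance with a warning. Tree
building substitutes a fixed large distance (5) for saturated pairs.

**Substitution saturation.** `iss` is mean per-site entropy over the
expected entropy of a fully saturated column (exact enumeration of
multinomial compositions for n <= 12, seeded Monte Carlo above).
`iss_critical` regenerates critical values by fresh simulation rather than
a lookup table: Jukes-Cantor alignments are evolved on balanced and on
extremely asymmetrical (ultrametric caterpillar) topologies across a
branch-length grid, and Iss.c is the interpolated Iss where
neighbor-joining recovery of the generating topology drops below 95%. The
caterpillar is ultrametric -- early-diverging tips carry long terminal
branches -- which is what makes the asymmetric case harder and puts
Iss.c(asym) below Iss.c(sym); small numeric deviations from other
implementations of the same idea are expected and documented.

**Neutrality tests.** Tajima's D uses the standard constants; Fu & Li's
statistics default to the no-outgroup starred variants (no outgroup is
assumed for within-family copy sets) with the Simonsen-corrected
constants, and the polarized variants are available when an outgroup
sequence is supplied. P-values come from Tajima's beta approximation
and/or seeded coalescent simulation conditional on S; both routes are
provided because the original tools' significance tiers are not traceable
to one of them. All statistics are checked against independent formula
oracles to 1e-12 and calibrated on neutral coalescent simulations.

**Counting dN/dS.** Codon changes are tallied directly: one-step changes
by the code table; multi-hit codons as the equal-weight average over all
minimal mutational pathways that avoid stop codons (all pathways if every
one passes through a stop) -- the Nei-Gojobori pathway convention, chosen
as the most defensible reading of a "simplified counting" approach; a
strict skip-multi-hit mode is available behind `skip_multi_hit`. Gap-,
N- or stop-containing codons are removed pairwise. Counts are deliberately
left uncorrected (no multiple-hit correction, no site normalization), so
the ratio is `nd/sd`; pairs with `sd = 0` are undefined and excluded from
medians and tests but reported as counts. Per family, all intra-group
pairwise ratios are pooled (the box-plot reading of distributions "among
copies"); group differences use a two-sided Mann-Whitney U test, exact via
the null U distribution when both n <= 10 without ties, else the normal
approximation with tie correction.

**Sliding-window divergence.** Mean pairwise p-distance per window
(default 300/50, a repository choice -- the source does not state its
window). The peak baseline deviates deliberately from "mean + 3 SD": a
genuine recombinant tract inflates the naive moments enough to hide
itself unless it occupies under ~10% of windows, so the default baseline
is the profile median with a 1.4826 x MAD scale plus a 1.5-fold
effect-size gate; `robust = FALSE` restores the naive rule.

## Trees and monophyly

`neighbor_joining` is a deterministic NJ (ties broken by row-major order;
negative branch lengths clamped to zero with the deficit moved to the
sibling edge). Bootstrap support is column resampling with bipartition
matching. ML tree inference is deliberately external: alignments can be
exported and external Newick trees fed into `check_monophyly`.

Monophyly is defined on the unrooted topology: a group is monophyletic iff
one edge separates exactly that group. "Paraphyletic" has no standard
unrooted formalization; here a group is paraphyletic when adding one
nested foreign clade makes it a bipartition side (`Y = group + X` with `X`
itself a clade disjoint from the group) -- the pattern left by a derived
sublineage arising inside a parental family. Everything else is
polyphyletic. Note one consequence: a derived sub-family is only detected
as "nested" if it branches from within the parental radiation; a
sub-family that attaches at the parental root is indistinguishable, on an
unrooted tree, from a sister family.

## Known limitations

* The annotator assumes seed-guided search (no de-novo genome-wide
  discovery), no nested insertions and no solo-LTR calling.
* The gapless repeat extension tolerates substitutions but not indels
  inside LTRs; indel-riddled copies surface as unresolved seeds.
* `iss_critical` is a Monte-Carlo reconstruction of the published
  construction, not a reimplementation of any specific tool's tables.
* The simulator's host background is memoryless uniform DNA; results on
  repeat-dense real genomes will be less clean than the green tests
  suggest.
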