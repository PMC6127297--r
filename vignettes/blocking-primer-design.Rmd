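---
title: "Designing blocking primers for host-depleted 18S metabarcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing blocking primers for host-depleted 18S metabarcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockprimr)
```

## The problem

In amplicon surveys of the eukaryotes living inside a host — protists in
coral tissue being the motivating case — almost all template DNA comes
from the host itself, so universal 18S primers return mostly host reads
and the community of interest is barely sampled. A *blocking primer*
counteracts this: an oligonucleotide that overlaps the reverse PCR
primer's binding site on host templates and extends into host-specific
sequence immediately 3' of the amplicon, capped at its 3' end (Spacer C3)
so that it anneals but cannot be extended. Host templates are bound and
not amplified; everything else amplifies normally.

`blockprimr` implements the design and evaluation of such blockers from a
taxonomy-annotated reference database, and the small set of community
statistics typically used downstream of host-depleted data.

## The design procedure

1. **Partition** (`partition_host_offtarget()`): the reference database is
   split into a *host* set (records carrying the host taxon label, e.g.
   Scleractinia, at any rank) and an *off-target* set (records carrying
   the exclusion label, e.g. Metazoa, at **no** rank). Matching is exact
   whole-label: substring matches such as "Metazoan-like" never count.
   Records with empty taxonomy go conservatively to the off-target set —
   the removal rule speaks of *annotated* members of the excluded taxon,
   so unannotated records are retained and counted in a message.
2. **In silico PCR** (`extract_amplicon()`): degenerate, IUPAC-aware
   scanning for the forward primer site and, downstream, the reverse
   complement of the reverse primer. Two symbols match iff their
   expansion sets intersect, so an `N` in a reference matches anything —
   references contain Ns, and treating them as mismatches would discard
   usable sequences (hits whose primer windows exceed 20% N are flagged).
   The first forward and the last reverse site are used: deterministic,
   and it favors the full-length amplicon. Matching has no positional
   weighting — the test is sequence-level, not kinetic.
3. **Tail stack** (`extract_tail_stack()`): the final 40 nt of every host
   amplicon (the amplicon 3' region plus the reverse-primer site),
   right-anchored on the primer site. Because every row is anchored on
   the same site and rRNA tails at this scale are essentially indel-free,
   gapless stacking equals a multiple alignment of the tails while
   removing the external-aligner dependence; an externally aligned tail
   FASTA can be supplied through `tail_stack_from_rows()` when exact
   replication of an aligner-based workflow is wanted.
4. **Entropy profile** (`column_entropy()`): per-column Shannon entropy in
   bits over the unambiguous bases A/C/G/T only, so the profile is
   bounded by 2 bits and a monomorphic column scores exactly 0. Columns
   where the host is conserved (low entropy) but the off-target set is
   variable are where a blocker discriminates.
5. **Candidate enumeration** (`enumerate_candidates()`): for each length
   L in 20–29 nt the candidate window covers the first 10 bases of the
   reverse-primer site plus the L − 10 bases immediately 5' of it; its
   per-column host consensus is reverse complemented so the candidate is
   written in reverse-primer orientation with a 10-base 5' overlap onto
   the reverse primer's 3' end. The bound "shorter than 30 nt" is read
   strictly (maximum 29); published blockers of 25 and 26 nt sit well
   inside it.
6. **Ranking** (`rank_candidates()`): candidates are scored against both
   databases and ordered lexicographically — maximal host blocked
   fraction, then minimal off-target blocked fraction, then shorter
   length, stable under ties.

`design_blocking_primers()` wires steps 2–6 together and returns a classed
object with `print`, `summary` and `plot` (entropy profile) methods.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `tail_len` | 40 nt | stacked amplicon 3'-tail length |
| `min_len`, `max_len` | 20, 29 nt | candidate length range (strict sub-30 bound) |
| `overlap_len` | 10 nt | candidate 5' overlap onto the reverse primer 3' end |
| `tm_tolerance` | 5 °C | allowed deviation from the mean primer Tm |
| `consensus_min_freq` | 0.9 | majority frequency keeping a consensus column unambiguous |
| `minor_freq` | 0.1 | frequency admitting a base into a degenerate code |
| `max_mismatch` | 0 | mismatch budget for amplifiability and blocking |

Melting temperatures use the Wallace rule `2(A+T) + 4(G+C)` up to 13 nt
and `64.9 + 41(GC − 16.4)/N` from 14 nt, with degenerate symbols
contributing their expansion's mean GC weight. These are standard,
parameter-free formulas; no specific Tm model is canonical for blocker
design, so the choice is deliberately simple and the function is a
single, replaceable unit. The 5 °C tolerance operationalizes "similar
Tm"; it is exposed rather than hard-coded. Likewise the 0.9/0.1 consensus
thresholds trade low degeneracy (synthesizability) against coverage of
common host variants; both are exposed. The default mismatch budget of 0
is the strictest reading of a sequence "matching" a primer, with the
budget available as a parameter.

"Blocked" means: the forward-strand window whose reverse complement the
blocker equals — positioned by the amplicon's reverse-primer site and the
overlap — matches the record within the mismatch budget. Records the
primer set cannot amplify are excluded from every denominator, since the
in silico universe is pre-filtered to primer-matched sequences.

## Clade annotation

Environmental symbiont OTUs are annotated against a reference panel
(e.g. *Symbiodinium* clades A, B, C, D, G) by clustering at the lowest
similarity threshold where the references fall into exactly one cluster
per clade (`find_separation_threshold()`, scanning 0.90–0.99), then
co-clustering queries with references at that threshold
(`annotate_by_cocluster()`): a query inherits a clade iff its cluster
contains references of exactly one clade. Identities are computed on a
caller-supplied alignment with overhangs trimmed, both-gap columns
skipped and one-sided gaps counted as mismatches; the package does not
align. Linkage defaults to complete — the published procedure names only
its clustering tool, not the method, and complete linkage is the
conservative choice that guarantees every within-cluster pair meets the
threshold (average linkage is available; this is the main replication
uncertainty of the procedure). When several thresholds qualify, the
lowest is returned by default (`pick = "highest"` for the other reading).

## Community statistics

* `filter_coverage()`: drop OTUs with annotation coverage below 90%
  (inclusive at the boundary: removal is of coverage *under* the
  threshold).
* `presence_filter()`: an OTU is present in a sample iff it has at least 3
  reads there.
* `aggregate_genus()` and `pielou_evenness()`: genus-level abundances and
  `J = H'/ln S`.
* `fisher_association()`: per-taxon 2×2 presence-by-region tables, two-sided
  Fisher exact p (via `stats::fisher.test`, the
  sum-of-at-most-as-probable-tables convention of the standard tool
  chain), Bonferroni over all taxa tested in one call — genera and
  symbiont clades supplied together form one family, which is recorded on
  the result. The presence/absence construction of the 2×2 table is the
  natural reading of region-association testing on presence-filtered
  data, and is documented here as an interpretation.
* `patristic_matrix()` and `mantel_test()`: path-length distances from trees
  with branch lengths, and a seeded one-sided (greater) Mantel
  permutation test, `p = (1 + #{r_perm ≥ r_obs}) / (n_perm + 1)`,
  matching the convention of the standard implementation.
* `prune_long_branches()`: the removal of long-branch OTUs before tree
  statistics is published without a threshold; here it is an optional
  Tukey-style fence (pendant length > Q3 + 3·IQR), explicitly an
  interpretation.

## What the synthetic generators emulate

All tests run on seeded generators with planted truth:

* `synth_host_family()`: a host family as forward primer + insert (10%
  divergence from a shared root) + a conserved 40-nt tail (2% divergence)
  + the reverse-primer site, with GC fraction 0.4 (18S variable loops are
  AT-rich). Degenerate primer positions are resolved deterministically so
  every record amplifies at zero mismatches. The conserved tail is drawn
  subject to admitting at least one Tm-compatible blocker, so the planted
  truth is designable by construction — mirroring the fact that real host
  tails that support no Tm-matched blocker would not be studied this way.
  The planted blockers per candidate length (prefixes of one 29-mer) are
  returned as ground truth.
* `synth_offtarget_db()`: labeled off-target groups with independent tail
  roots, optionally planting a known fraction of carriers of the host
  tail, giving exact expected blocked fractions.
* `synth_reference_panel()`: clade panels with controlled identities —
  each clade owns a disjoint block of signature positions, members
  re-mutate only inside their own block, so between-clade identity is
  exact by construction and realized identities sit within 1% of the
  request. With within-identity 0.99 and between-identity 0.90 the
  separation scan provably returns 0.91. A request with between-identity
  above within-identity is unsatisfiable by real clades and generates an
  inseparable cloud instead.
* `synth_otu_table()`: two regions, planted presence probabilities for
  associated taxa, nulls at 0.5; counts where present are at least the
  presence threshold, so the presence rule recovers the planted pattern
  exactly.
* `synth_tree()`: random topologies with uniform branch lengths for
  patristic/Mantel tests.

What passing on these fixtures does **not** show: performance on a real
reference snapshot (real taxonomies are noisier, tails contain indels and
Ns, and group compositions differ), nor empirical blocking efficiency in
PCR — in silico specificity is a sequence-level statement, and observed
host depletion in sequencing runs is known to fall short of it. No
kinetic model is attempted.

## Numerical and degenerate-input choices

* Entropy: log base 2, `0·log 0 := 0`; all-ambiguous columns are NA, not
  0, so they can be distinguished from genuinely conserved columns.
* Consensus: a column with every base below `minor_freq` would be empty;
  it falls back to the majority base. Candidates that are more than half
  N are rejected outright (a fully polymorphic stack yields no
  candidate rather than an all-N oligo).
* Clustering: merges at exactly the cutoff are inclusive (a 1e-9 epsilon
  guards against floating-point representation of `1 − threshold`); label
  order is fixed lexicographically before clustering so tie handling is
  deterministic.
* Fisher: region labels are sorted; exactly two are required, each with
  at least one sample.
* Mantel: permutations are seeded and the caller's RNG state is restored;
  `p ≥ 1/(n_permutations + 1)` by construction.
* Sequence validation fails fast with the record id and position of the
  first non-IUPAC character; duplicate ids are rejected by name.

## Problem sizes used in the test suite

The suite exercises the designer at the scale the method is meant for
(50-sequence host families, 20 seeds for the recovery experiment;
160-record off-target databases; 1000 null taxa for the Fisher
calibration; exhaustive enumeration of all 2×2 tables with margins up to
10; exact Mantel enumeration at 4–5 labels), chosen so the whole suite
runs in about a minute on one CPU while every statistical check retains
enough replication to be meaningful.

## Known limitations

* Anchored stacking assumes indel-free tails; supply an external tail
  alignment otherwise.
* The designer only produces reverse-side blockers (the published
  strategy); forward-side blocking is out of scope.
* In silico specificity does not predict empirical depletion rates.
* The Fisher exact test is discrete and conservative: at small sample
  sizes its attainable size at α = 0.05 is well below 0.05. The test
  suite therefore calibrates the empirical rejection rate against the
  exact attainable size under the generator's null rather than against
  the nominal level.
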