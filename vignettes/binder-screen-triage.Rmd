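---
title: "Triaging one-against-many structure-prediction interaction screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triaging one-against-many structure-prediction interaction screens}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binderclust)
```

## The problem

An *in silico* pull-down models one bait protein against every protein of a
proteome with AlphaFold-Multimer. Even after restricting to models with high
interface confidence (ipTM), hundreds of candidates remain, and no single
confidence score reliably separates true binders from false positives at
this scale. The observation this package builds on is behavioral rather
than score-based: a bait that truly binds a protein family tends to bind
its homologs in the same way. True positives therefore show up as *large
groups of similar targets bound with a consistent topology*, while false
positives scatter. `binderclust` finds those groups by clustering the
confidently-interacting parts of the targets jointly by sequence and by
fold, and ranks the clusters for manual inspection.

## The procedure

Stage one (`run_cluster_stage()`):

1. **ipTM gate.** Only complexes with `ipTM >= iptm_threshold` enter the
   analysis. The boundary is inclusive; the default is 0.75, a conventional
   high-confidence interface cutoff. If nothing passes, the run aborts with
   a suggestion to lower the threshold.
2. **PAE trimming.** The predicted aligned error (PAE) matrix gives, for
   each residue pair `(i, j)`, the expected positional error of residue `i`
   when the model is aligned on residue `j`. The inter-chain block measures
   how confidently each residue of one chain is placed relative to the
   other chain. For target residue `j` we define its interface confidence
   as `min_i min(PAE[i, j], PAE[j, i])` over all bait residues `i` — the
   symmetrized minimum, because PAE is asymmetric and either orientation
   being confident is evidence of reliable relative placement. Residues
   with confidence `<= pae_cutoff` seed segments; seed runs separated by at
   most `max_gap` unconfident residues are bridged (loops inside an
   interacting domain are rarely themselves low-PAE); runs shorter than
   `min_segment` are dropped as spurious; survivors get `pad` flanking
   residues. Both chains are trimmed by the same rule. A complex whose bait
   or target retains nothing is discarded and recorded with its reason in
   `discarded.csv`.
3. **Sequence clustering.** Greedy incremental clustering of the trimmed
   target sequences: visiting sequences by decreasing length, each joins
   the first founded cluster whose representative it matches at identity
   `>= min_id` (matches over all alignment columns, gaps included) with
   coverage `>= seq_min_cov` on both sequences, else founds a new cluster.
   The identity computation uses the package's global aligner (BLOSUM62,
   linear gap −6, deterministic traceback).
4. **Structure clustering.** The same greedy scheme on the trimmed target
   structures, the membership test being a TM-score (normalized by the
   shorter chain) `>= min_tm` with coverage `>= struct_min_cov` against the
   founding representative.
5. **Merging.** Sequence clusters and structure clusters sharing at least
   one member are joined; merged clusters are the connected components of
   that bipartite graph. This is what buys sensitivity to remote homologs:
   a fold cluster can bridge two sequence clusters that no pairwise
   sequence identity would join, and vice versa.
6. **Representatives.** Within each merged cluster, an all-vs-all
   structural alignment of the target chains; each member's median RMSD and
   median TM-score against all other members are recorded, and the member
   with the lowest median RMSD becomes the cluster representative (ties:
   higher median TM, then smaller id).

Stage two (`run_rank_stage()`) orders the clusters — size descending, then
representative median RMSD ascending, median TM descending, representative
coverage descending, label — writes `ranking.csv`, emits one directory per
top cluster with the members' trimmed models and a PyMOL command script
that stacks every member on the representative, and can optionally
re-cluster the top clusters by fold at a stricter TM threshold
(`subcluster_min_tm`) to separate distinct binding topologies within one
target family.

## The structural aligner

Cluster members reach the all-vs-all step only after sequence/fold
clustering, so they are homologous by construction. The aligner therefore
seeds the residue correspondence with a global sequence alignment
(Needleman–Wunsch, BLOSUM62, linear gap penalty −6, deterministic
diagonal > up > left traceback) instead of a sequence-independent fold
search — a deliberate scope decision: a 3Di-style sequence-independent
aligner is not needed for intra-cluster comparisons, and cross-family pairs
(where the correspondence is uninformative) correctly score near zero.

Superposition uses the Kabsch SVD solution with reflection correction, then
TM-align-style refinement: superpose on the current pair subset, keep the
pairs closer than `max(4.5, d0)` Å, repeat to a fixed point (at most 20
rounds, never below the 3 closest pairs; ties break by residue index). The
TM-score is computed over *all* aligned pairs under the final superposition,

$$\mathrm{TM}_i = \frac{1}{L_i} \sum_k \frac{1}{1 + (d_k / d_0(L_i))^2},
\qquad d_0(L) = 1.24\,(L-15)^{1/3} - 1.8 \;(\text{clamped at } 0.5),$$

normalized by each chain's length; the RMSD is reported over the final kept
subset. Degenerate alignments (fewer than 3 pairs) carry missing RMSD/TM,
which downstream medians exclude rather than zero-fill.

For the per-member medians, the TM-score is normalized by the length of the
member whose median is being computed; "representative coverage" in the
ranking is the representative's median pairwise coverage within its
cluster. Both conventions are stated here because other normalizations are
defensible.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `iptm_threshold` | 0.75 | – | inclusive interface-confidence gate |
| `pae_cutoff` | 12 | Å | interface-confidence seed threshold |
| `pad` | 2 | residues | flank kept around each segment |
| `max_gap` | 5 | residues | largest bridged unconfident gap |
| `min_segment` | 10 | residues | shortest kept segment (pre-padding) |
| `min_id` | 0.30 | fraction | sequence-cluster identity threshold |
| `seq_min_cov` | 0.8 | fraction | bidirectional sequence coverage |
| `min_tm` | 0.5 | – | structure-cluster TM threshold (shorter-normalized) |
| `struct_min_cov` | 0.8 | fraction | structural coverage |
| `min_cluster_size` | 4 | members | smallest ranked cluster |
| `top_n` | 5 | clusters | viewer directories emitted |
| `subcluster_min_tm` | 0.7 | – | stricter TM for subclustering |
| `cpus` | 1 | workers | all-vs-all parallelism (result-invariant) |

The PAE cutoff of 12 Å sits between the confident inter-chain blocks of
good models (typically < 10 Å) and the 25–30 Å plateau of unrelated
placements; `min_segment = 10` keeps compact interacting domains while
dropping isolated spurious residues; `min_id = 0.30` and `min_tm = 0.5` are
the conventional homology and same-fold thresholds; `min_cluster_size = 4`
reflects that a binder family needs a handful of homologs in the screened
proteome before cluster size is meaningful, and `top_n = 5` matches the
expectation that a successful screen resolves into a small number of
plausible clusters. All are exposed on the command line.

## The synthetic screen generator

`generate_screen()` emulates the *input contract* of a real screen, not its
physics. Binder families share a parametric fold — an ideal α-helix, a
β-hairpin, or helix–turn–helix variants with family-specific hinge angles,
all with protein-like 3.7–3.9 Å CA spacing — perturbed by Gaussian
coordinate noise (default σ = 0.5 Å) and a consensus sequence mutated at
rate 0.1 per residue; their PAE carries a 2–6 Å inter-chain block over the
planted interface span against a 25–30 Å background, and ipTM is 0.85 ±
0.02. Decoys are random-walk coils with uniform high PAE and ipTM 0.40.
The default spec is 3 families × 12 members + 50 decoys on a 50-residue
bait and 60-residue target with interface span [10, 50).

What it does *not* emulate: realistic PAE textures (the pipeline only
thresholds PAE, so only the block structure matters), side chains,
energetics, partially-confident interfaces, or the long disordered tails of
real proteomes. Passing the end-to-end tests therefore demonstrates that
the machinery recovers planted structure under controlled noise — it does
not certify performance on real AlphaFold output, where score calibration
and fold diversity are far richer.

Every complex draws from its own RNG stream seeded by (seed, complex
index), so regenerating any subset of a screen is stable and two runs from
one seed are byte-identical.

## Numerical and determinism choices

- All structural math is CA-based; trimming and clustering operate at
  residue resolution, and coordinate files are reduced to CA traces on
  read (residues without CA are dropped with a warning).
- Internal residue indices are 0-based and contiguous per chain; retained
  intervals are half-open; original author numbering survives in REMARK
  lines of the trimmed PDB output.
- Greedy clustering visits members by (length descending, id ascending), so
  the longest member of a family founds its cluster; representative
  selection and merging break all ties lexicographically. Every output
  table is sorted and numerically formatted before writing, which makes
  repeat runs — and runs with different `cpus` — byte-identical.
- Trimming is idempotent and monotone in the cutoff; both properties are
  enforced by tests.
- Validation problem sizes: the reference end-to-end check runs the full
  default generator spec (86 complexes); unit fixtures use 30–50-residue
  chains and 3×4-member screens, which exercise every code path at a
  fraction of the cost.

## Limitations

- The aligner is sequence-seeded; it will under-score structurally similar
  but sequence-scrambled pairs. Within clusters (its only consumer) this is
  by construction not a concern.
- Greedy clustering is order-dependent by design (deterministic, but not a
  global optimum); very diverse families can fragment, which the merging
  step partially repairs.
- A true binder with fewer than `min_cluster_size` homologs in the screened
  set will not be ranked, which is inherent to the cluster-size rationale —
  lowering the threshold or pooling related proteomes are the remedies.
- Homodimeric baits are handled positionally (first chain is the bait);
  shared identifiers get no special treatment.
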