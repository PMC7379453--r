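---
title: "Curating and analysing prolamin sequence databases with prolamap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and analysing prolamin sequence databases with prolamap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Quantifying gluten in food by mass spectrometry requires a curated database
of cereal seed storage prolamins — gliadins and glutenins in wheat, hordeins
in barley, secalins in rye, avenins in oats. Public repositories are highly
redundant (the same protein deposited many times under different accessions),
contain partial and ambiguous translations, and use inconsistent naming.
prolamap implements the full curation-and-analysis chain as deterministic,
testable code: FASTA curation, prolamin group classification, average-distance
phylogeny, exact mapping of coeliac-toxic-motif panels, and in-silico
chymotryptic digestion for marker-peptide discovery. A synthetic prolamin
generator with exact ground truth makes every stage verifiable offline.

## Curation model

Curation applies three rule families in a fixed order, each producing an
auditable removal record:

1. **Deduplication.** Exact duplicate sequences collapse to one
   representative chosen by source preference (Swiss-Prot > TrEMBL > NCBI >
   other), ties broken by input order; repeated accessions collapse to the
   first occurrence. Duplicate checks run before content checks so the
   retained representative — not a discarded copy — is what gets
   content-screened.
2. **Ambiguity screen.** Any record containing `X`, `B`, `Z` or `J` is
   removed. The reader deliberately *tolerates* these letters (while
   rejecting `U`, `O` and stop codons outright) precisely so the curation
   stage can see and remove them; a reader that refused ambiguous records
   would make this screen untestable.
3. **Partial-sequence heuristic.** Manual curation of fragments has no
   published rule, so prolamap operationalises "partial" as three explicit,
   configurable signals: length below `min_length` (default 50 residues, far
   below any mature prolamin — purely a fragment guard), a missing initiator
   methionine when no signal peptide is recorded, or a `partial`/`fragment`
   keyword in the header.

Proline+glutamine content below `pq_threshold_percent` (default 30%) is
**reported as a warning, never a removal**: genuine prolamins — notably
avenin-like proteins — run from the low twenties upward in P+Q, so a
composition cut-off would discard true positives. The threshold instead
confirms candidate master sequences.

Counts are conserved (`n_input = n_kept + removals`) and curation is
idempotent; both properties are enforced by tests across randomized
corrupted inputs.

## Classification model

Each record is classified by global (Needleman–Wunsch) alignment to a set of
per-group *master sequences*, with composition, cysteine skeleton and
repeat-motif evidence reported alongside:

* **Alignment**: BLOSUM62 with gap open 10 and gap extend 0.5. BLOSUM62 is
  the standard matrix for this protein family; the gap costs are the common
  global-alignment defaults and are configurable via `align_params()`.
* **Identity convention**: identical aligned pairs divided by *total*
  alignment columns, gap columns included in the denominator. This is one of
  several conventions in circulation, so published within-group similarity
  figures should be treated as approximate comparisons, not exact targets.
* **Assignment**: the group of the best-identity master wins if identity
  reaches `identity_floor` (default 30%, mirroring the homology floor used
  when recovering related sequences by BLAST); ties break on repeat-hit
  counts for the tied group, then template order. Below the floor the record
  is `unclassified`.
* **Evidence**: P+Q percentage; cysteine count (omega-type prolamins have
  none, B-/C-type avenins eight, A-type nine); and occurrences of the
  group's repeat grammar — a literal prefix optionally followed by a bounded
  glutamine run (e.g. `PFM` + Q(1–5)). Q-runs are matched greedily and
  capped at the upper bound, and overlapping occurrences are all reported,
  since no occurrence semantics is standardised for these repeats.

## Average-distance tree

Distances are `100 − identity`. The tree is classic UPGMA: merge the closest
pair at height `d/2`, update distances by size-weighted arithmetic means.
Tie-breaking is by smallest (row, column) index pair in the current label
order — repetitive prolamin sequences make exact ties common, and an
undocumented tie-break would make runs irreproducible. Average linkage is
monotone, so the output is ultrametric; tests verify exact reconstruction of
matrices induced from random ultrametric trees and the three-point condition
to 1e-9. Branch lengths are identity-distance units, *not* substitutions per
site: we claim topology-level agreement with alignment-viewer trees, not
branch-length agreement, because the internal score transform of such
viewers is undocumented.

## Coeliac-toxic-motif statistics

Motifs are matched as exact, case-sensitive substrings — deliberately: the
reference tool for this analysis is an exact-peptide-match function, and
deamidation-aware (Q→E) matching is out of scope. Three statistics per
sequence:

* `m` — number of *distinct* panel motifs present at least once. Repeat
  occurrences of the same motif do not recount it; motifs that are
  fragments of longer panel motifs count separately.
* `density = m / L` motifs per residue (a per-100-residue column is also
  emitted for readability).
* `coverage` — percentage of residues covered by the union of all hit
  intervals, reported to two decimals.

Duplicate motifs in an input panel are collapsed with a warning so `m` is
well defined. Coordinates are 1-based inclusive throughout. Coverage is
computed by interval union; an independent per-residue boolean-marking
oracle (`oracle_metrics()`) is kept deliberately naive and separate, and
tests require exact agreement on thousands of randomized cases. Whether
published motif statistics were computed on immature (signal-peptide) or
mature sequences is unstated in the literature; prolamap analyses the
sequence as given, with `signal_len` available to work on mature forms.

## Chymotryptic marker discovery

Digestion cleaves after `Y`, `W`, `F` or `L` unless the next residue is
proline, with up to two missed cleavages by default. Marker candidates are
peptides unique to one database protein, at least 5 residues long, with
neutral monoisotopic mass ≥ 750 Da. Two documented approximations:

* The 750 Da floor is applied to the *neutral peptide mass*. The original
  filter acts on precursor ions; charge-state handling is out of this
  MS-free scope.
* I/L equivalence for uniqueness is off by default (no published statement
  either way) but available via `ileq = TRUE`, since mass spectrometry
  cannot distinguish the isobaric pair.

Masses use the standard monoisotopic residue table plus water (18.010565
Da); the only supported modification is fixed carbamidomethyl-C
(+57.021464 Da), the one fixed modification in the workflow this mirrors.
Variable modifications (deamidation, oxidation, hydroxyproline, pyro-Glu)
are out of scope. The protein C-terminus always ends a peptide, and
N-terminal Met receives no special processing.

## The synthetic generator

`generate_synthetic()` emits families with *exact* ground truth. Each group
has a fixed architecture: 20-residue signal peptide (no Cys, no cleavage
letters), 30-residue N-terminal domain, a repetitive domain built from the
group's repeat grammar (8–16 units), and a 60-residue C-terminal domain
carrying the group's cysteine skeleton (0, 6, 8 or 9 Cys at fixed
positions). The background composition is 35% Q / 15% P — the
glutamine/proline-rich regime that defines prolamins. The default fixture
("toy-glupro") has six groups × five sequences, a 25-motif panel with 20%
nested fragments, seed 1, and 2+2+2 injected duplicate / ambiguous /
partial records.

Design choices that keep the truth exact:

* Panel motifs are embedded by splicing into the repetitive domain at
  recorded, non-overlapping coordinates. Motifs are cysteine-free (like the
  P/Q-rich epitope cores they emulate), so embedding never disturbs the
  skeleton.
* Point mutations never touch position 1 (the initiator Met), embedded
  motif spans, or cysteines, and never *introduce* a cysteine.
* Expected motif metrics are computed *after* assembly by the independent
  per-residue oracle — a repetitive background will create incidental
  motif matches, and the statistics legitimately count them, so the truth
  must too.

What the generator does **not** emulate: realistic evolutionary divergence
(mutations are i.i.d., not BLOSUM-distributed), allelic series, alternative
splicing, or genuine signal-peptide sequence biology. Passing recovery
tests on synthetic data therefore demonstrates algorithmic correctness on
known ground truth, not fidelity of any particular published database.

## Problem sizes and determinism

The shipped test suite and the acceptance script use the toy fixture
(36 records), 1,000 randomized motif oracle cases, 500 digestion cases and
100 random ultrametric trees — sizes chosen so the whole verification runs
in minutes on one core while still exercising every code path at
property-test depth. All randomness flows through explicit seeds;
generation is a pure function of its spec, and pipeline reruns are
byte-identical.

## Known limitations

* Classification reproduces a *rule-based operationalisation* of what was
  historically a partly manual, literature-informed assignment; agreement
  with hand-curated group labels on real data is expected but not
  guaranteed.
* Identity-based distances make the tree's branch lengths incomparable to
  substitution-model trees; only the clustering structure is meaningful.
* Homology-based removal of non-prolamins (the BLAST screening stage of
  database construction) and signal-peptide prediction are out of scope;
  records are screened by composition and structure only.
* Exact motif matching ignores deamidation, so motif loads on heavily
  deamidated mature proteins are conservative lower bounds.
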