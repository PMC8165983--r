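---
title: "Methods: PUL mining, glycan mass annotation, and esterase kinetics"
author: "pulminer authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PUL mining, glycan mass annotation, and esterase kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulminer)
```

# Scope and model

Bacteroidetes organize their glycan-degradation machinery into
polysaccharide utilization loci (PULs): physically linked gene clusters
around a *susC*/*susD* transporter/binding tandem, co-encoding CAZymes
(GH, CE, PL, CBM families) and, frequently, proteins of unknown function
(PUFs). Because PUFs inside a PUL inherit a strong functional hypothesis
from their neighbours, PUL mining is a practical route to novel enzyme
discovery: find loci whose CAZyme content pins down a substrate, then
shortlist the PUFs they carry.

`pulminer` implements that route for annotated (meta)genomic contigs, plus
the two downstream analyses used to characterize a discovered esterase:
composition annotation of MALDI-TOF spectra of substituted
xylooligosaccharides, and substrate-inhibition Michaelis–Menten kinetics.
Everything upstream of the annotated inputs — assembly, gene calling, HMM
scanning, signal-peptide prediction, alignment, tree inference — is
consumed as files, never re-implemented.

# Gene labelling

`load_features()` reads GFF3 gene models (1-based inclusive) and converts
them to the internal 0-based half-open convention; `load_domain_hits()`
filters a condensed domain-hit table at e-value ≤ 1e-5 and model coverage
≥ 0.35 by default. These cutoffs are the community convention for CAZy HMM
scans (dbCAN-style); both are arguments, not constants.

`assign_labels()` routes hits to labels:

* SusC-like transporter models → `SUSC`; SusD-like binding-protein models →
  `SUSD`;
* CAZy family models (`GH\d+`, `CE\d+`, `PL\d+`, `CBM\d+`) → their family
  token; several families on one protein all stick (multi-domain CAZymes
  such as GH43+CBM6 are real);
* Pfam accessions (`PFxxxxx`) are recorded as domain *evidence* but never
  produce a label. A protein whose only hits are Pfam folds stays a PUF —
  deliberately so: PUFs of interest often carry a fold-level domain (an
  α/β-hydrolase, say) without an assignable function, and stripping their
  PUF status would hide exactly the candidates the pipeline exists to find;
* any other *named* model (e.g. `RpoB`, `OmpA`) marks a known,
  non-PUL-related function: label `OTHER`;
* no surviving hit at all → `PUF`.

The `OTHER` class is the one extension to the minimal label vocabulary, and
it is load-bearing: cluster extension (below) must be stopped by genes of
known unrelated function, while unknowns are absorbed. Without a
distinguishable non-member class, every intergenic stretch of hypothetical
proteins would chain adjacent loci together.

# PUL detection

`detect_puls()` uses the relaxed anchoring rule suited to fragmentary
assemblies: a locus is seeded at every `SUSD` gene — *susC* is not required
(`require_susc = FALSE` by default) because truncated contigs frequently
break the tandem. From each seed, extension walks left and right absorbing
extendable genes (`SUSC`, `SUSD`, GH/CE/PL/CBM families, `PUF`), tolerating
at most `max_gap` consecutive non-member genes (default 1 intervening
gene). A locus starts and ends on member genes.

Greedy bidirectional extension provably yields the *maximal* valid window
containing each seed (windows from seeds in the same cluster coincide, so
merging is automatic); the test suite nevertheless checks equivalence
against a brute-force enumerator of maximal valid windows on thousands of
random contigs, and that growing `max_gap` only ever merges or extends
loci, never splits them.

Completeness flags encode assembly-margin caution: `complete_left` (resp.
`right`) is `FALSE` when fewer than `max_gap + 1` genes separate the locus
from the contig end — in that case one cannot rule out that the locus
continues past the break, so the flag marks it open rather than guessing.

## Substrate inference and candidate triage

`infer_substrate()` assigns a substrate when at least `min_families`
distinct families of a signature set are present. Defaults:

* **xylan** — `GH10, GH11, GH43, GH51, GH115, CE1`, ≥ 2 distinct families
  (endoxylanases, β-xylosidases/arabinofuranosidases, glucuronidases, and
  the acetyl-xylan esterase family);
* **alginate** — `PL6, PL7, PL15, PL17`, ≥ 2 distinct families. The
  canonical alginate-lyase families are used because alginate-targeting
  loci appear as a context class downstream.

Ties go to the substrate with more distinct families present, then to the
configured priority order; overlapping signature sets without a priority
are rejected as a configuration error.

`filter_candidates()` applies the discovery filter — at least 5 predicted
proteins and at least 2 signature CAZymes by default — and reports each
passing locus's PUFs with the triage evidence used to rank them: predicted
signal peptide (secretion capability), Pfam fold domains, and protein
length. A missing signal peptide demotes a PUF in the shortlist ordering
but never excludes it. The shortlist length filter defaults to 250 with a
configurable unit; the unit setting exists because "length > 250" for a
protein is ambiguous between residues and coding nucleotides in common
usage — the default interprets it as residues (aa), and `length_unit =
"bp"` divides by three instead. Set `min_length = NULL` to keep fragments.

## Deduplication

Enriched metagenomes repeat successful loci across samples.
`deduplicate_puls()` groups loci whose ordered member-protein sequences are
identical, and additionally matches a shorter locus to a longer one when it
equals a contiguous prefix (or suffix) of it *and* is incomplete at the
corresponding margin — the signature of an incompletely assembled copy.
Groups are transitive closures; each reports its longest member as
representative. Matching is exact on sequence: near-identical paralogs are
deliberately kept apart.

# Homolog genomic context and monophyly

`load_and_classify()` parses 12-column BLAST tabular output, applies the
retention threshold (default e ≤ 1e-10), keeps the top 200 hits by bit
score, and joins each subject to a curated context table; subjects inside a
PUL are classed by its predicted substrate (`xylan-PUL`, `alginate-PUL`,
`other-PUL`), everything else — including unmapped subjects — `no-PUL`.
Self-hits are ordinary records.

`partition_groups()` splits records into score groups. How such groups are
delimited in practice is rarely stated, so three modes coexist: the default
*largest-gap* heuristic (split at the biggest adjacent drop in sorted bit
scores, but only when it exceeds `k = 3` times the median adjacent drop —
otherwise one group), an explicit score *threshold*, and a *preset*
pass-through for externally curated group labels. The gap heuristic's
factor-of-median guard keeps uniform score ladders in a single group; its
behaviour is simulation-tested on two-cluster score draws.

`clade_consistency()` answers the concordance question — do all homologs of
one context class form a clade? The target class is monophyletic iff the
smallest clade containing all its leaves contains no other leaves; the
report returns that clade with inside/outside counts either way, which
quantifies *how far* from monophyly a class is. Trees are used as rooted at
their parsed root (an `outgroup` argument re-roots first); the test oracle
is an exhaustive scan over every clade of random trees, walking the edge
matrix independently of the implementation.

# Glycan composition masses

Substituted xylooligosaccharides are annotated over residue symbols
`P` (pentose, 132.0423 Da), `H` (hexose, 162.0528), `Ac` (acetyl, 42.0106),
`Fa` (feruloyl, 176.0473), `U` ((4-O-methyl)glucuronyl, 190.0477): a
neutral mass is the residue-mass sum plus water (18.0106), and reported m/z
adds the adduct (Na⁺, 22.9892, the MALDI convention for neutral sugars and
the default). Monoisotopic constants are carried to 4 decimals and the
electron mass is ignored — both far below the 0.1 Da at which such peaks
are read. Only Na⁺ is assumed by default; potassium adducts are not
enumerated.

`decompose_peak()` enumerates the full bounded composition lattice within a
tolerance (default 0.3 Da) and ranks matches by |Δm/z|, then fewer
substituents, then lexicographic order. Chemical feasibility rules — ester
groups cannot outnumber available sugar hydroxyls (`Ac + Fa ≤ 2(P+H)`) and
each feruloyl needs a pentose carrier (`Fa ≤ P`, feruloyl riding
arabinofuranosyl) — are on by default and prune compositions that are
arithmetically but not chemically possible. `predict_products()` encodes
ester hydrolysis (the product sugar loses exactly the acyl residue mass),
and `compare_spectra()` infers released moieties from before/after peak
lists by searching shifted masses, preferring the most parsimonious
explanation per peak (unshifted = "no change"). Intensities are carried,
never interpreted; isotope patterns and positional isomers are out of
scope.

# Substrate-inhibition kinetics

The canonical uncompetitive substrate-inhibition law is used:

$$v \;=\; \frac{V_{max}\, S}{K_m + S\,(1 + S/K_i)},$$

with a single interior optimum at $S^\* = \sqrt{K_m K_i}$ and plain
Michaelis–Menten recovered as $K_i \to \infty$. This is the standard form
fitted by common curve-fitting software when an initial-rate curve bends
down at high substrate.

`fit_si()` fits by Levenberg–Marquardt least squares with **relative
weighting** ($1/v^2$) by default: initial rates derived from absorbance
traces have errors roughly proportional to the rate, which is also the
noise model of the simulator; under that model relative weighting is the
correctly specified choice and measurably tightens Km recovery. Set
`weighting = "none"` for homoscedastic data. Start values come from a
deterministic heuristic ($V_{max,0} = 1.5\,\max v$; $K_{m,0}$ = the $S$
nearest half of that; $K_{i,0} = 10\,\max S$), $K_i$ is bounded above by a
$10^6$ mM sentinel, and fits reaching it are flagged `effectively_mm`.
Constant-rate inputs are refused with a degenerate flag rather than
returning a meaningless perfect fit (the law can reproduce a flat line with
$K_m \to 0$). $k_{cat} = V_{max}/E_{total}$ with a *user-supplied* molar
enzyme amount — molecular mass is an input, never computed from sequence,
since tags and truncations make that ambiguous.

A note on identifiability: on a 0.25–10 mM grid with $K_i$ near 14 mM, the
data barely enter the inhibition regime, so $K_i$ is weakly identified — at
3% multiplicative noise its median relative recovery error is several times
that of $K_m$ and $k_{cat}$ (the property suite asserts ≤ 35% vs ≤ 5%).
That asymmetry is a feature of the experimental design being emulated, not
of the optimizer.

`compare_models()` fits both laws and prefers by small-sample AICc (error
variance counted as a parameter). Residual sums are floored at a tiny
data-scaled value so that noise-free nested fits — both numerically zero —
are decided by the parameter-count penalty in favour of the reduced model.

# The synthetic-data module

The generators exist so that every stage is testable desk-scale, offline,
deterministically: identical seed and configuration give identical files.

`generate_metagenome()` plants label-template PULs (default template:
`SUSC, SUSD, GH10, GH43, GH51, CE1, PUF, PUF`, mirroring xylan-PUL anatomy)
into contigs of background genes carrying housekeeping-model hits
(→ `OTHER`). Defaults encode the linked-cluster biology: mean 0 intervening
genes inside a locus (geometric when positive), ≥ 3 background genes
between loci and 2 padding each margin — both exceeding the default gap
tolerance so planted and detected loci coincide exactly. With
`margin_trunc_prob`, a locus is placed at the right contig edge with its
tail cut (the SUSD anchor always survives; only the last locus of a contig
can be the truncated one, since a truncated locus is by definition at the
edge). The first PUF of each planted locus is the planted candidate: it
gets an α/β-hydrolase Pfam domain (PF12695), a signal peptide, and ≥ 260
residues. Protein sequences are uniform-random over the 20-letter alphabet
with per-gene seeds; domain hits are written directly to the hit table —
no HMM emission is simulated, because the annotation module consumes hit
tables, not HMMs.

What the fixtures do **not** emulate — and hence what green tests do not
show about real data: sequencing/assembly error, chimeric contigs, biased
gene calling, HMM score noise near thresholds, paralog interference, or
realistic protein composition. The fixtures validate the *logic* of
detection, triage and deduplication under the stated assumptions, not the
upstream annotation quality.

`generate_spectrum_pair()` emits before/after peak lists at theoretical
adduct masses with optional uniform jitter (which must stay below the
downstream matching tolerance); `generate_kinetics()` returns exact
rate-law values at zero noise and multiplicative Gaussian noise otherwise,
clamped at zero.

# Numerical and testing choices

Problem sizes in the default test run were chosen to exercise each
property exhaustively at desk scale: locus detection is compared to the
brute-force enumerator on 1000 random contigs of ≤ 15 genes; peak
decomposition to independent lattice enumeration at every 0.1 Da step of
the 300–1800 Da instrument window; monophyly to an exhaustive clade scan on
500 random trees of ≤ 12 leaves; kinetics recovery and model preference on
100 simulated datasets each. Mass arithmetic is asserted additive and
conservative to 1e-9 Da; fitted parameters scale-equivariant to 1e-6
relative.

# Known limitations

* Substrate inference sees only family presence; it cannot separate
  substrates whose signatures share all observed families, and loci seeded
  by mis-labelled SusD-like proteins will be false positives.
* Deduplication is exact-sequence; assembly base errors break groups.
* The score-gap group heuristic assumes one dominant gap; genuinely
  multi-modal score distributions need the threshold or preset modes.
* Peak decomposition reports compositions, not structures: positional
  isomers are indistinguishable by mass alone.
* The kinetics module fits initial rates only; progress curves, pH or
  temperature dependence, and mechanisms beyond the single-site
  substrate-inhibition law are out of scope.
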