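---
title: "Models and methods behind pufselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pufselect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pufselect)
```

`pufselect` analyses the sequence specificity of PUF-family RNA-binding
proteins: which RNA elements a protein (or a protein–partner complex)
selects from a random library, how tightly it binds individual elements,
and whether element architecture stratifies its mRNA targets into
distinct functional classes. This vignette explains the models, the
parameters that matter, and the design choices where more than one
reasonable option existed.

## Element definitions and coordinates

PUF binding elements are anchored at a UGU trinucleotide. We use the
standard coordinate convention: the first U of UGU is +1, the upstream
cytosine is −1, and there is no position 0. The built-in pattern set
(`puf_patterns()`) contains the compact 8-nt element `CTGTRNAT` (one
degenerate position between +4 and the terminal AU; terminal U at +7) and
the extended 9-nt element `CTGTRNNAT` (two degenerate positions; terminal
U at +8), plus their +4-resolved variants (`CTGTANAT`, `CTGTGNAT`,
`CTGTANNAT`, `CTGTGNNAT`). Sequences are stored as DNA — selection reads
are sequenced as cDNA and the patterns are conventionally written over
`{A,C,G,T}` — and U on input is mapped to T everywhere, so RNA- and
DNA-alphabet inputs give identical results.

Matching uses grep line semantics: `match_pattern()` reports whether a
read contains at least one matching window, and `count_patterns()` counts
matching reads, not occurrences (an occurrence mode exists behind the
`mode` argument). A read matching both a compact and an extended pattern
increments both counts, since the patterns are independent queries. Only
the sense strand is searched: the selected molecules are single-stranded
RNA. Deduplication before counting is off by default and available via
`dedup = TRUE`; published counting conventions for selection data vary,
and the read-level default is stated rather than guessed per dataset.

The matcher itself is `Biostrings` fixed-subject matching with IUPAC
degeneracy in the pattern; the test suite checks it against an
independent naive sliding-window matcher on 10^4 random reads for all six
built-in patterns.

## The selection (SEQRS) retention model

`simulate_selection()` models one selection round as weighted resampling.
Each read receives a retention weight

\[ w_i = \theta_i + b, \qquad
   \theta_i = \frac{P}{P + K_{d,c(i)}}, \]

where \(P\) is the free protein concentration (nM), \(K_{d,c(i)}\) is the
dissociation constant of the read's best (lowest-\(K_d\)) matching element
class, \(\theta_i = 0\) for reads matching no class, and \(b\) is a
background retention probability. The next round is a multinomial
resample of `reads_per_round` reads with probabilities \(w_i / \sum w\).

Design choices, and why:

- **Additive background** (\(w = \theta + b\)) rather than multiplicative:
  carrier tRNA and plastic binding retain non-binders independently of
  protein occupancy.
- **Best-match rule**: a read matching several classes is weighted by the
  tightest, since equilibrium capture is dominated by the lowest-\(K_d\)
  site.
- **Neutral PCR**: amplification is modelled as resampling only. No bias
  model is attempted; wash kinetics, sequencing error and
  reverse-transcription dropout are likewise out of scope.

Defaults are the study conditions: a 20-nt random core with i.i.d.
uniform bases (`simulate_library()`, flanks empty by default since the
library's constant flanks do not affect any statistic computed here),
five rounds, 100 nM protein, background retention 0.01, and class
affinities set to the measured values — compact-G4 10.3 nM (the cFBE
element), compact-A4 56.8 nM (the PBE-like element), extended-G4 12.4 nM
(the *gld-1* FBEa), extended-A4 12.0 nM. `reads_per_round` defaults to
10^5, which keeps Monte-Carlo error on class frequencies near
\(3\times10^{-3}\) while the whole five-round simulation runs in seconds;
the sequencing depth of real selection experiments is not part of the
model.

Under these defaults the compact-G4 class has the highest occupancy
(\(\theta = 0.91\) vs 0.64 for compact-A4), so its frequency is expected
to be non-decreasing over rounds and to overtake the PBE-affinity class —
the property the acceptance suite verifies within three binomial standard
errors.

What the simulation does *not* emulate: real selection libraries have
constant primer-binding flanks that can create chance element matches,
position-dependent nucleotide composition, PCR jackpots, and
cross-contamination between rounds. Passing tests on this generator shows
the analysis stack is correct under the stated equilibrium model, not
that it reproduces every artefact of a wet selection experiment.

## Motif summaries

`build_pfm()` aligns reads on their first match to an anchor pattern and
tabulates base frequencies over the window −2…+9 (11 columns; position 0
does not exist). Reads whose window would run off either end are dropped.
Information content per column is \(2 + \sum_b p_b \log_2 p_b\) bits with
\(0\log 0 \equiv 0\) and a uniform background; the pseudocount defaults
to 0 so single-site matrices are exactly one-hot. This is a deliberate
desk-scale substitute for EM-based motif discovery: the anchor fixes the
alignment, which is appropriate here because every element of interest
shares the CTGT prefix.

## One-site binding fits

EMSA titrations are fit with the one-site specific binding model
\(Y = B_\mathrm{max} X / (K_d + X)\) — no Hill coefficient, no
nonspecific-background term, matching the named model used for the
published affinities. `fit_one_site()` minimises least squares by
Levenberg–Marquardt on \(\log K_d\) and \(\log B_\mathrm{max}\), which
enforces positivity without constrained optimisation; starting values are
the concentration nearest half-maximal signal and the maximum signal.
Convergence tolerances are 10^-12 (relative) with up to 500 iterations;
noiseless curves on the standard 15-point series are recovered to better
than 10^-6 relative error, and the tests compare fits against a dense
grid-search oracle.

Conventions around the fits:

- The standard concentration series is the two-fold dilution 4000 →
  0.49 nM plus a zero point (`emsa_concentration_series()`); at least 5
  distinct concentrations are required.
- When the partner protein is added from a 10X stock,
  `adjust_concentrations()` multiplies the series by 0.9 before fitting.
- Replicates are fit independently; `aggregate_replicates()` reports the
  mean \(K_d\) and SEM \(= s/\sqrt{n}\), which matches the
  technical-replicate reporting convention. A single replicate is an
  error, not SEM = 0.
- `compute_krel()` is the ratio of mean \(K_d\)s against a reference RNA
  measured under the same protein condition; report tables round
  \(K_{rel}\) to 2 significant figures and \(K_d\) to 3.
- The fit consumes a generic bound-signal column. Whether the signal is
  raw band intensity or fraction bound affects \(B_\mathrm{max}\) but not
  \(K_d\) under this model, so no normalisation is imposed.
- `simulate_titration()` adds Gaussian noise with standard deviation
  `noise_sd * bmax`, truncated at zero — a plain model of densitometry
  noise chosen for transparency; it does not emulate gel smearing or
  saturation.

## Motif-stratified enrichment

`stratify_targets()` splits a gene universe into compact-matching,
extended-matching, either, and compact-only sets by scanning each gene's
sequence. `hypergeom_enrich()` then tests each annotation term with the
upper-tail hypergeometric probability \(P(X \ge k)\) for \(k\) annotated
genes among the \(n\) targets, given \(K\) annotated genes in the
universe of \(N\), and corrects across terms with Benjamini–Hochberg.
The test is one-sided (enrichment only), terms are opaque labels with no
ontology-graph propagation, and the universe defaults to all supplied
genes — for target-list analyses the natural comparison set is the target
list itself. Terms with no annotated genes are skipped with a warning
rather than reported at p = 1.

`generate_gene_fixtures()` builds synthetic universes for this stage:
random 200-nt UTR-like sequences, independent term annotation at a fixed
rate (default 0.1), and optional planting of a concrete element instance
into every gene annotated to a chosen term (100% penetrance). Planted
fixtures are a positive control — the planted term must attain the
minimum q — and unplanted universes provide a null under which the
fraction of terms with q < 0.05 must stay at the FDR target; both are
exercised in the acceptance tests. Real target lists differ in length
distribution, composition bias and correlated annotations, so these
fixtures validate the statistics, not biological conclusions.

## Numerical and degenerate-input conventions

- The compact:extended ratio is undefined when the extended count is 0:
  `compact_extended_ratio()` raises an error, `ratio_table()` returns
  `NA`, and the TSV writer prints `"."`.
- Ratios and \(K_{rel}\) are returned unrounded; display rounding
  (2 significant figures) is applied only at reporting boundaries.
- All generators draw from one seeded generator per call (`withr`-scoped,
  so user RNG state is untouched) and are byte-deterministic given the
  seed; `run_full_pipeline()` derives per-stage seeds from the master
  seed and records them in `manifest.json`, which suffices to regenerate
  every output byte-identically.
- Windows are 0-based half-open internally; every reported coordinate
  uses the −2…+9 biological convention.

## Known limitations

- The retention model ignores partner-concentration dynamics: the
  partner is treated as saturating (a fixed per-class \(K_d\)), not as a
  ternary equilibrium.
- Pattern counts from real selection data depend on counting-unit
  conventions (reads vs unique sequences vs occurrences) that published
  tables do not always state; the package exposes both `mode` and
  `dedup` but exact reproduction of any given published raw count
  requires knowing that convention and the underlying reads.
- The enrichment stage is a methodological stand-in for web-service
  enrichment tools; it does not reproduce any specific ontology release.
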