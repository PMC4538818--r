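---
title: "Simulating the microtargetome: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the microtargetome: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirbooking)
```

## The model in one page

A cellular condition is a pair of absolute abundance tables — miRNA
copies/cell and transcript copies/cell — together with mature miRNA
sequences and annotated transcript sequences. The simulation answers: at
equilibrium, which miRNA copies sit on which 7-nt sites of which
transcripts?

Three ingredients drive the assignment:

1. **Hybridization probabilities.** The seed (mature miRNA nucleotides
   2–8) pairs antiparallel with a 7-nt window. Its duplex free energy is
   Boltzmann-normalized over all $4^7 = 16{,}384$ heptamers with $kT = 1$,
   giving $\mathrm{HP}(s{::}h) \in [0,1]$ with
   $\sum_h \mathrm{HP}(s{::}h) = 1$. HP is the single score every
   downstream module consumes, and it is symmetric in use: the same value
   ranks a site for a miRNA and a miRNA for a site.
2. **Candidate filtering.** A (seed, window) pair is admissible when the
   window is complementary with at most two mismatches (G:U wobbles count
   as mismatches for this filter) *and* $\mathrm{HP} \ge \tau$. The two
   filters are applied conjunctively; at the default $\tau$ essentially
   all perfect-complement duplexes survive while only a small minority of
   1-mismatch duplexes do, which the test suite asserts.
3. **Stable-marriage booking.** Sites are visited in descending order of
   their transcript's abundance; at each site, admissible seeds propose in
   preference order. A successful proposal books
   $Q = \min(q_{\mathrm{avail}} \cdot \log_\alpha q(\mathrm{seed}) \cdot
   \mathrm{HP},\; q(\mathrm{seed}))$ copies, further capped by
   $q_{\mathrm{avail}}$ itself (the dilution–HP product can exceed 1, and
   a site can never hold more copies than its transcript has). Booking
   depletes the miRNA's current abundance and the availability of every
   site whose 46-nt RISC footprint overlaps. Each seed::site pair books at
   most once; proposals below `q_min` are rejected and retried on later
   passes, and the run ends when a full pass books nothing. The outcome is
   stable — an independent verifier in the test suite confirms no
   alternative pair could still book — and byte-reproducible.

Per-gene summaries: occupancy $O$ = bound copies / $n$, and the silencing
score $\mathrm{miS} = \sum \mathrm{copies} \cdot \mathrm{HP} \cdot W / n$
with $W = 1$ in the 3′UTR and $W = 0.1$ in the 5′UTR or CDS. miS is a
relative score; no attempt is made to map it onto measured fold-changes.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `tau` | 0.0179 | probability | HP admission threshold; higher = stricter complementarity |
| `alpha` | 512 | — | dilution log base; higher spreads fewer copies over more sites |
| `footprint` | 46 | nt | RISC occupancy span, centered on the site |
| `q_min` | 1.0 | copies | smallest bookable quantity; also guarantees termination |
| `sort_order` | `hp-first` | — | per-site seed preference key order |

The defaults for $\tau$ and $\alpha$ are the optimum of an MCC grid search
over virtual overexpression experiments
($\tau \in [0.0050, 0.2000]$, $\alpha \in \{2, 4, \ldots, 2^{24}\}$); the
`grid_search()` function reruns that procedure on any labelled dataset and
resolves MCC ties to the lowest $\tau$, then the lowest $\alpha$. The
46-nt footprint is the reported minimum RISC span. $kT$ is fixed at 1 —
energies are in model units, so only relative scale matters — and is
exposed on `energy_model()` purely for sensitivity analysis.

## Energy backends

MC-Fold-style duplex energies with non-canonical pairs are not
reproducible from first principles here, so the energy model is a
pluggable interface with three implementations:

- **`table`** — exact import of a precomputed seed::heptamer ΔG TSV
  (16,384 rows per seed). This is the fidelity path when an external
  energy table is available; export/import round-trips are bit-exact
  (energies are printed with 17 significant digits).
- **`nearest-neighbor`** (default) — the sum of Watson–Crick dinucleotide
  stack energies (Turner-style helix values) over adjacent paired
  positions, plus fixed per-position penalties: +2.5 for a mismatch, +1.0
  for a G:U wobble. The milder wobble penalty reflects that wobbles are
  energetically tolerated even though the complementarity filter counts
  them as mismatches. With these constants the perfect complement is
  always the energy minimum (and HP maximum), perfect duplexes always
  clear the default $\tau$, and roughly 3–5% of 1-mismatch duplexes do —
  terminal mismatches being mildest.
- **`uniform`** — ΔG ≡ 0, HP = 1/16384 everywhere; a null model used in
  tests.

HP is computed in log space with max-subtraction before exponentiation,
so extreme energy tables cannot overflow.

## What the synthetic generator emulates — and what it does not

`fixture_spec()`/`generate_system()` build toy systems with log-uniform
abundances (miRNAs 50–50,000 copies, transcripts 10–5,000 copies,
spanning the observed physiological ranges), fixed region geometry
(50 nt 5′UTR, 150 nt CDS, 300 nt 3′UTR by default) and planted sites at
controlled mismatch counts, regions and (optionally) offsets. Two
guarantees make the manifest an *exact* ground truth:

- planted sites are at least 13 nt apart, so no 7-nt window overlaps two
  plants, and
- the background is scrubbed so no non-planted window is within two
  mismatches of any seed. A freshly drawn background occasionally
  contains a window overlapping a plant that stays complementary whatever
  its free bases are; such draws are rejected and re-drawn from a seed
  derived deterministically from the spec seed, so identical specs still
  produce identical files.

The generator does **not** emulate: realistic 3′UTR length distributions
or sequence composition, multiple-isoform genes, miRNA families sharing
seeds, expression correlation structure, or measurement noise. Passing
tests on these fixtures therefore demonstrate the *mechanics* of the
simulator (conservation, stability, footprint capacity, sponge
propagation) — not predictive accuracy on real transcriptomes, which
requires real expression data and a measured energy table.

Two purpose-built fixtures encode the competition phenomenology:
`sponge_system()` (one limiting miRNA shared by a leader and a follower;
raising the leader monotonically starves the follower) and
`chain_system()` (A shares miRNA 1 with bridge X, X shares miRNA 2 with
B; the two bridge sites sit 20 nt apart inside one footprint, so sponging
miRNA 1 off the bridge frees capacity that miRNA 2 fills, depleting what
reaches B — an indirect, negative leader→follower correlation with no
shared miRNA). In `chain_system()` miRNA 2 is deliberately scarce (600
copies); with an abundant miRNA 2 the follower's booking saturates at its
copy number and the propagated signal vanishes.

## Quantification choices

Relative miRNA intensities are converted to copies/cell by a log-affine
map solved in closed form so the input's positive-value median lands on
633 and its maximum on 52,567 copies/cell (absolute anchors measured in
liver). The median of an even-length vector is the mean of the two
central order statistics; zeros mean "not expressed" and pass through
unchanged. Because the map is monotone, odd-length inputs hit the median
anchor exactly; even-length inputs can deviate marginally when the two
central values differ. mRNA tables are matched to a user-supplied
absolute reference by mean/sd of log values (the original eight-gene
absolute reference is not reconstructable, so the reference is an
explicit argument). Between-array offsets are removed by equalizing the
mean log expression of GAPDH and ACTB against the first table. When
several transcripts map to one gene, the longest 3′UTR wins, with a
lexicographic id tie-break for determinism.

## Numerical and tie-break conventions

- Coordinates are 0-based half-open throughout; a window is labelled by
  the region containing its center nucleotide (start + 3), which gives
  boundary-straddling windows a single unambiguous label.
- Footprints overlap iff site centers differ by less than the footprint
  length; overlap reduces a shared per-transcript availability pool
  rather than deleting sites.
- The dilution factor $\log_\alpha q$ is clamped at 0 for $q \le 1$
  (a negative booking is meaningless).
- Booked copies are real-valued; `q_min = 1` gates sub-copy bookings.
- All orderings end in a lexicographic id key, so every run is
  deterministic; two runs on identical inputs produce byte-identical
  output files.
- Seed preference at a site is HP-descending, then current-abundance-
  descending ("sorted by abundance, then sorted by HP" read as a stable
  sort whose last key is primary); the alternative key order is available
  as `sort_order = "abundance-first"`.
- Rejected proposals are retried on the next pass, not within the pass.
- Degenerate inputs: transcripts shorter than 7 nt warn and yield no
  sites; all-equal calibration inputs, zero-variance log vectors, missing
  control genes, id collisions and out-of-range positions raise errors
  naming the offender.
- miS normalization divides by $n$ (per-copy) by default so scores are
  comparable across expression levels; the raw sum is available via
  `normalization = "total"` because the defining formula can be read
  either way.
- In `synchrony_matrix()`, a follower whose miS does not vary over a
  sweep gets correlation 0 with a flag (rather than NA propagating);
  negative correlations are reported truthfully, not clipped. The
  diagonal is blank. Ward clustering (`ward.D2` on Euclidean distances)
  imputes flagged/blank entries as 0 for ordering only.
- In fold-change labelling, the noise band $[-0.2, 0.2]$ is excluded from
  confusion counts by default; a flag counts band members as negatives
  instead. Genes above the band are negatives.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic
systems sized for a laptop core: 5–8 transcripts of ~500 nt, up to 6
miRNAs, 200 random stability instances, and 60-point abundance sweeps
(100–6000 copies in steps of 100). These sizes exercise every code path
— multi-pass retries, overlapping footprints, indirect propagation —
while keeping a full run under a few minutes. Scaling to a real
transcriptome (tens of thousands of transcripts) is a matter of runtime,
not algorithmics: the engine is quadratic in sites per footprint
neighbourhood and linear in passes.

## Known limitations

- The default energy model is a coarse stand-in for measured duplex
  energetics: no non-canonical pair geometry beyond the wobble penalty,
  no position-dependent seed weighting, no 3′-supplementary pairing. The
  table backend exists precisely so measured energies can be dropped in.
- Full-length duplex folding, site accessibility and cooperative binding
  between adjacent sites are deliberately out of scope (reported not to
  improve predictions).
- miS is monotone in occupancy but unitless; comparisons are meaningful
  within a condition pair, not across datasets.
- The booking equilibrium is combinatorial, not kinetic: no ODEs, no
  rate constants, and no attempt to model degradation dynamics.
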