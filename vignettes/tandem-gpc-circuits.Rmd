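---
title: "Modeling tandem recombinase cascades: compiler, stage process, and assay models"
author: "gpcsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tandem recombinase cascades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcsim)
```

## The system being modeled

A gene perturbation cassette (GPC) is a self-excising DNA unit: a split
site-specific recombinase (Cre, Flp, or PhiC31) reconstituted by chemically
induced dimerization (CID), one or more payloads, and a strong terminator,
all flanked by the recombinase's own recognition sites. Arranged in tandem
behind a single promoter, GPCs form a state machine: only the
promoter-proximal cassette is transcribed (the terminator blocks everything
downstream), so adding the cognate ligand — gibberellin (GIB) or abscisic
acid (ABA) — excises exactly the proximal cassette and exposes the next one.
Because downstream recombinases are inert until exposed, two ligands suffice
to drive an arbitrarily long cascade, and GIB can be reused at a later stage
even though an earlier GIB-gated cassette used it first.

`gpcsim` treats this system at two levels:

1. a **compiler** that turns a declarative design into annotated DNA for
   every post-excision stage, tracking the accumulating scar;
2. a **population simulator** that propagates many cells through a ligand
   schedule as a continuous-time stochastic stage process, with assay models
   that convert the simulated population into flow-cytometry fractions,
   scar-amplicon read counts, indel frequencies, and qPCR ratios.

## Compiler model

The stage-1 layout is

```
promoter . leader . [pad . L-site . 2A-recombinase . payloads . terminator . R-site . pad] x N . terminal payloads
```

optionally wrapped in an attP/attB pair and piggyBac ITRs. Excision replaces
the whole `L-site..R-site` span with the pair's single scar site; for the
symmetric loxP and FRT pairs that is literally "one site remains", while the
asymmetric attB x attP pair leaves an attL-like hybrid. Coordinates are
0-based half-open on the top strand internally; GenBank output converts to
1-based inclusive.

**Translated scars (v2).** Version-1 circuits leave the growing scar in the
5'UTR, where structure can depress translation. Version-2 circuits put an
initiation codon upstream of the array so the scar is translated and cleaved
off by the 2A peptide at the start of each recombinase. Two design choices
follow:

* The default v2 leader is exactly `ATG` (Kozak context is carried at the 3'
  end of the promoter part). This keeps the stage-1 scar peptide a bare
  methionine, which makes the bookkeeping easy to reason about: every
  subsequent residue of the scar peptide is contributed by a scar unit.
* Each scar unit must be a whole number of codons and stop-free, which
  canonical sites are not (loxP is 34 bp; FRT read at offset 0 contains a
  TAG). The compiler therefore brackets each unit with a deterministic
  pre/post pad — `pre + scar_site + post`, total length divisible by 3, pads
  chosen by a fixed search so no in-frame stop survives. A 3'-only pad
  cannot fix FRT (the stop is internal at offset 0), which is why the pad is
  split around the site; both halves sit outside the excised span and
  survive excision. The padding strategy of the published constructs is not
  described anywhere we could check, so this rule is an explicit assumption,
  and `frame_pad = FALSE` turns it off (validation then reports the frame
  break).

**Placeholder parts.** Source plasmid sequences are not public. loxP and FRT
are the canonical 34-bp sites; everything else (att sites, promoter,
terminator, ITRs, coding sequences) is a deterministic synthetic placeholder
of canonical length, generated by a small multiplicative LCG so presets are
reproducible, and labeled NON-PHYSIOLOGICAL in GenBank comments. All
length-dependent logic reads the actual strings; nothing is hard-coded to
placeholder lengths.

**att-wrapped circuits.** For a design with an att wrapper, activating the
PhiC31 stage recombines the upstream attP with the cassette's attB, which
removes everything from the wrapper's left site through its right site. The
post-deletion construct therefore retains only the ITR flanks and one att
scar. The exact junction of the published construct is not specified; we
model the deletion as a single excision spanning the whole wrapped region.

## The stage process

Each circuit copy performs a pure-birth continuous-time Markov process on
stages `1..N+1` (plus an absorbing `deleted` state for wrapped designs).
Expression gating means only the proximal cassette contributes hazard:

* cognate ligand at activity `a(t)`: hazard
  `h(t) = q_leak + (q_exc - q_leak) * a(t)`, which interpolates between the
  ligand-free leak rate and the full excision rate;
* all downstream cassettes: hazard exactly 0;
* at the PhiC31 stage of an att-wrapped design the event is whole-circuit
  deletion with `q_sd` in place of `q_exc`.

The CID assembly, recombinase reconstitution and recombination sub-steps are
lumped into this single first-order event because only window-level
completion is observable at the calibration sources. When both ligands are
present, hazards act on their cognate cassettes independently; no
interference is modeled.

**Ligand pharmacokinetics.** Activity is 1 inside an exposure window. After
washout, GA4 and ABA presets clear instantly (both are fully cleared well
within the 12-h inter-window gap), while the GA3-AM preset (an AM-ester
trapped intracellularly) decays first-order with a 4-h half-life, floored to
0 below 1% — the floor keeps the piecewise description finite and is far
below any activity that matters kinetically.

**Event sampling.** Event times are drawn by exact inversion of the
integrated hazard over the piecewise activity profile: within constant-rate
pieces the inverse is linear; within decay pieces the cumulative hazard has
a closed form and the inverse is found by `uniroot`. There is no fixed time
step, hence no discretization error. Per-cell random substreams are derived
from `(seed, cell index)`, so cell *i*'s path is identical whatever the
population size — useful both for reproducibility and for regression tests.

**Analytic twin.** `expected_occupancy()` solves the same Markov chain by
stepping matrix exponentials of the generator over the piece grid; pieces
with decaying activity are subdivided (40 subintervals by default) with
exactly averaged activity per subinterval. For instant-clearance schedules
the propagation is exact; tests compare it against an independent stiff ODE
integration at `1e-8` and against Monte-Carlo occupancy at three binomial
standard errors with 10,000 cells.

## Parameter calibration (`kinetic_preset("paper-2021")`)

| parameter | default | rationale |
|---|---|---|
| `excision_hazard` | 0.2 h^-1 | a single GPC excises near-completely (99.2%) within a 24-h window |
| `leak_hazard` | 5e-4 h^-1 | ~10% loss of a held stage over 8 ligand-free days, matching the memory experiment |
| `payload_protein_halflife` | 2 h | PEST-tagged payloads; fluorescence tracks the current stage |
| `sgRNA_halflife` | 12 h | editing/activation readouts approach equilibrium by ~96 h |
| `self_deletion_hazard` | `-ln(0.22)/48` h^-1 | 78% circuit removal over one 48-h GIB window |

The cascade-completion consistency checks use an excision hazard of
0.087 h^-1, i.e. ~98.5% completion per 48-h window — the multi-stage
cascade's per-window efficiency — rather than the single-GPC 24-h figure;
no reported per-stage probability is available to calibrate more finely,
which is why both values are stated explicitly rather than blended.

Schedules default to 48-h windows with 12-h gaps (96-h windows for the sgRNA
presets, where target readouts need ~96 h to equilibrate).

## Assay models

**Flow cytometry.** Payloads are produced at unit rate while proximal and
decay with the PEST half-life; a payload 48 h after its stage ended retains
less than 2^-24 of steady state, so residual double-positivity is
negligible. Cell-to-cell variability is log-normal with CV 0.3 (mean 1) —
the distributions in the source data are clearly dispersed but were never
fitted, so this is a conventional choice, applied per cell x payload. A
payload is "positive" above 20% of its steady-state level by default. The
switching metric `%after+ / (%after+ or %before+)` is computed exactly as
the flow analysis defines it.

**Editing kinetics.** An sgRNA is at unit abundance while its cassette is
proximal and decays exponentially after excision, so editing continues with
a lag after the cassette is gone. Per allele, the indel probability is
`1 - exp(-h * G(t))` with `G` the integrated abundance; alleles flip when a
per-allele exponential threshold is crossed, which makes every frequency
curve monotone by construction (indels do not revert). Frequencies are
allele-level with ploidy 2, matching how amplicon-sequencing pipelines
report indel fractions.

**Scar-amplicon sequencing.** Per-cycle efficiency declines linearly with
length, `E(L) = clamp(e_max - k_len L, 0, 1)`; after `C` cycles amplicon
weights are multiplied by `(1 + E(L))^C`. The preset uses `e_max = 0.9`,
`C = 25`, and `k_len` solved so the 156-bp stage-1 amplicon of an equimolar
mixture is ~2.8-fold overrepresented against a ~196-bp amplicon (the middle
of the reported 2.72-2.84 range; the 195 vs 198 bp split cannot pin both
endpoints with one linear coefficient). The true cycle count of the source
experiment is unprinted, so `C` is a free preset parameter: only the
composite `(1+E)^C` fold is constrained. `bias_correct()` inverts the
expectation exactly and wraps a multinomial bootstrap (percentile CIs, 1,000
resamples by default) around the estimates. The same machinery demonstrates
why a post-synchronization stage-3 estimate from raw reads is an
underestimate: residual short early-stage amplicons are inflated by the bias.

**qPCR.** The circuit-retention ratio is simply the fraction of copies not
yet self-deleted; the ITR flanks persist and serve as the denominator.

## What the synthetic populations do and do not emulate

The simulator reproduces: expression-gated sequencing of excisions, ligand
orthogonality, leak-driven run-ahead, ligand-order robustness, stage memory,
synchronization by selection (including the multi-copy rescue caveat: one
resistant copy saves the cell), self-deletion, and the post-excision editing
lag. It does **not** model cell division or growth competition, resource
burden, recombinase protein-level dynamics, inter-copy recombination when a
cell carries multiple circuits (flagged as a risk, not simulated), indel
spectra, or read-level sequencing artifacts beyond the length-bias model.
Passing tests therefore validate the kinetic logic and the bookkeeping, not
cell-biological detail the model never encodes.

## Problem sizes and numerical choices

Calibration-consistency runs use 10,000 single-copy cells (binomial SE
~0.2-0.5 percentage points at the fractions of interest); compiler property
sweeps use 200 random designs of 1-4 stages in both architecture versions;
bootstrap CIs use 400-1,000 resamples; the Markov propagator subdivides
decay pieces 40-fold. Ties and degenerate inputs: zero-hazard processes
never fire (the sampler returns infinity past the horizon); empty cascades
compile to promoter-leader-payload; a zero-read correction input is an
error, not a silent zero.

## Known limitations

* Placeholder sequences make absolute amplicon lengths synthetic; only
  relative, stage-dependent growth is meaningful.
* Per-recombinase leak differences are not quantified anywhere we could
  calibrate from, so one shared leak hazard is used unless overridden.
* The att-wrapper junction and the v2 frame-padding rule are explicit
  assumptions (see above).
* The Zeo marker's position inside the first cassette follows the schematic
  order but its exact position in the 2A chain is unstated; it does not
  affect any modeled observable.
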