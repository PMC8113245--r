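# gpcsim

Compile and simulate tandem recombinase gene-perturbation-cassette (GPC)
circuits.

A GPC is a self-excising DNA unit: a split site-specific recombinase
(Cre/loxP, Flp/FRT, or PhiC31/attB-attP) activated by chemically induced
dimerization — gibberellin (GIB) or abscisic acid (ABA) — plus payload genes
and a strong terminator, flanked by the recombinase's own recognition sites.
Arranged in tandem behind one promoter, GPCs implement a multi-stage state
machine: only the promoter-proximal cassette is expressed, so each ligand
pulse excises exactly one cassette, leaves a scar of recognition sites, and
exposes the next stage. Two alternating ligands can therefore drive
arbitrarily long cascades of gene expression, sgRNA release, selection
markers, and finally whole-circuit self-deletion through an attP wrapper.

`gpcsim` is for people designing or analyzing such circuits. It provides:

* **Circuit compiler** — `compile_design()`, `excise_stage()`,
  `enumerate_stages()` turn a declarative design (R constructors or YAML)
  into annotated constructs for every post-excision stage, with scar
  bookkeeping, v2 reading-frame checks (`scar_peptide()`), PCR amplicon
  prediction (`predict_amplicon()`), design linting (`validate_design()`),
  and GenBank/FASTA/CSV export.
* **Population simulator** — `simulate_population()` runs single cells
  (each with one or more circuit copies) through a ligand schedule as a
  continuous-time pure-birth stage process. Per copy at its proximal stage
  the transition hazard is

  `h(t) = q_leak + (q_exc - q_leak) * a(t)`

  where `a(t)` is the intracellular ligand activity (1 in a window, then
  instant or first-order clearance) and `q_leak` the ligand-free leak of
  split-recombinase reconstitution. Downstream cassettes have hazard 0
  (expression gating). Event times are sampled by exact inversion of the
  integrated hazard — no time-step discretization. `expected_occupancy()`
  is the closed-form Markov twin used for verification;
  `apply_selection()`, `self_delete()` and `fit_hazard_from_timecourse()`
  cover synchronization, circuit removal and rate estimation.
* **Assay models** — `flow_readout()` (payload-positive fractions and the
  switching metric `%after+/(%after+ or %before+)`), `simulate_editing()`
  (per-allele indel accumulation `1 - exp(-h∫g)` with post-excision sgRNA
  decay lag), `pcr_observe()`/`bias_correct()`/`estimate_stage_fractions()`
  (scar-amplicon sequencing with PCR length bias `(1 + E(L))^C` and its
  bootstrap-CI inversion), and `qpcr_excision_ratio()`.
* **Presets** — `load_preset()` ships the four-color fluorescence cascade
  (`gpcv2-fluor`), two sgRNA cascades (`gpcv2-crispra`, `gpcv2-crispr`) and
  the self-deleting `attp-gpcv2-crispr`, with calibrated kinetic defaults
  (`kinetic_preset("paper-2021")`) and a random-design generator
  (`random_design()`) for property tests. Part sequences are deterministic
  placeholders, clearly labeled non-physiological.
* **CLI** — `cmd_compile()/cmd_simulate()/cmd_assay()/cmd_validate()` plus
  the `inst/cli/gpc.R` Rscript wrapper; every stochastic run writes a JSON
  manifest that reproduces its outputs bit-for-bit.

## Worked example

Compile the four-color cascade and simulate 10,000 cells through the
alternating GIB/ABA/GIB schedule (48-h windows, 12-h gaps):

```r
library(gpcsim)

preset <- load_preset("gpcv2-fluor")
stage_table(preset$design)
#>   stage expressed_payloads length_bp scar_bp frame_ok
#> 1     1            BFP+Zeo      2195       0     TRUE
#> 2     2                GFP      1537      36     TRUE
#> 3     3            mCherry      1005      72     TRUE
#> 4     4            iRFP720       455     126     TRUE

schedule <- preset_schedule(preset)   # GIB 0-48 h, ABA 60-108 h, GIB 120-168 h
traj <- simulate_population(preset$design,
                            kinetic_params(excision_hazard = 0.087,
                                           leak_hazard = 5e-4),
                            schedule = schedule, n = 10000, seed = 1,
                            times = c(48, 108, 168))
round(traj$occupancy, 4)
#>      stage1 stage2 stage3 stage4
#> [1,] 0.0167 0.9675 0.0050 0.0108
#> [2,] 0.0165 0.0141 0.9404 0.0290
#> [3,] 0.0002 0.0293 0.0143 0.9562

fs <- flow_readout(traj$population, gating_config(preset$design), time = 168)
round(fs$positive_fraction, 3)
#>     BFP     Zeo     GFP mCherry iRFP720
#>   0.000   0.000   0.029   0.022   0.955
```

Reading the numbers: each row of `traj$occupancy` is a window-end readout.
After the first GIB window 96.8% of cells have switched BFP→GFP (stage 2);
1.7% are stragglers and ~1.6% ran ahead through ligand-free leak. By the end
of the run 95.6% of cells express the terminal iRFP720 payload, mirrored by
the flow readout after PEST-driven decay of the earlier payloads. The scar
column shows the 36-bp padded scar unit each excision adds while keeping
the v2 reading frame intact (`frame_ok`).

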