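# mrmpanel

Design and validation of targeted LC-MRM-MS peptide transition panels for
bacterial protein biomarkers.

## The problem

*Dehalococcoides mccartyi* (*Dhc*) strains detoxify chlorinated ethenes
(PCE, TCE, *cis*-DCE, vinyl chloride) in contaminated groundwater through
reductive dehalogenase (RDase) enzymes. Gene-level monitoring (qPCR of 16S
rRNA or RDase genes) shows that the organisms are *present* but not that
they are *active*: transcript and gene abundances correlate poorly with
dechlorination rates. Detecting the proteins themselves — housekeeping
markers (GroEL, EF-Tu, rpL7/L12, S-layer) for presence and
dechlorination-linked markers (FdhA, TceA, BvcA) for activity — by targeted
proteomics closes that gap. `mrmpanel` implements the computational side of
building and applying such an assay:

1. **Panel design** — in-silico tryptic digestion of target proteomes;
   proteotypic-candidate filtering (7–18 residues, no methionine);
   enumeration of MRM transitions (2+ precursor → singly charged y3 …
   y(n−1) fragments) with monoisotopic m/z and a linear collision-energy
   model; deterministic vendor-style transition-list CSV export.
2. **Specificity screening** — exact matching of each candidate against
   labeled background proteomes, with a three-tier verdict:
   *specific* (target strains only → keep), *semi-specific* (also in
   related organohalide-respiring bacteria → keep with caveat),
   *non-specific* (in unrelated bacteria → remove). Pairwise peptidome
   similarity (Jaccard or overlap coefficient, in %) quantifies how
   distinct the target strains are from background organisms.
3. **Panel refinement** — per-peptide transition ranking by fractional
   contribution to total chromatographic AUC (top 5 retained),
   cross-strain merging of shared peptides, and multi-load linearity
   flags.
4. **Detection validation** — rule-based verdicts per peptide, replicated
   run and sample:
   (A) co-elution of all transitions (apex spread ≤ 0.2 min by default);
   (B) mean transition-intensity dot product against a pure-culture
   reference pattern, strictly > 0.80, where
   `dotp(a, b) = Σaᵢbᵢ / (‖a‖·‖b‖)`;
   (C) reproducible signal in **all** technical replicates.
   Spike-in standard support: area increase, dotp > 0.80 against the
   standard's pattern, and retention-time agreement within 3 min
   (inclusive).
5. **Synthetic data** — a seeded generator for proteome registries with
   peptides planted at known specificity tiers and Gaussian-peak MRM
   chromatograms with controlled noise, retention-time jitter and decoy
   corruptions (pattern permutation, RT shift, transition dropout,
   absent analyte), so the whole pipeline is testable without instrument
   data.

## Worked example

Transitions for the TceA tryptic peptide `YFGASSVGAIK` (11 residues →
y3…y10, eight transitions at the 2+ precursor):

```r
library(mrmpanel)
enumerate_transitions("YFGASSVGAIK")[, c("fragment_label", "precursor_mz",
                                         "product_mz", "collision_energy")]
#>   fragment_label precursor_mz product_mz collision_energy
#> 1             y3    550.29274  331.23397        22.023953
#> 2             y4    550.29274  388.25543        22.023953
#> 3             y5    550.29274  487.32384        22.023953
#> ...
#> 8            y10    550.29274  936.51488        22.023953
```

The precursor m/z is `(M + 2·1.007276)/2` for the peptide's monoisotopic
mass M; each product m/z is the protonated C-terminal fragment; collision
energy is `0.034·m/z + 3.314` eV (editable placeholder coefficients).

Simulated end-to-end detection — three genuinely present peptides and two
intensity-pattern decoys, three technical replicates each:

```r
cfg <- sim_config(seed = 7)
study <- simulate_study(cfg, n_faithful = 3, n_decoy = 2)
res <- cmd_validate(study$groups, study$references)
res$verdicts[, c("peptide", "coelution_pass", "mean_dotp", "detected")]
#>            peptide coelution_pass mean_dotp detected
#> 1        DCAFLSLFR           TRUE    0.9996     TRUE
#> 2      ELNHLYVTSIR           TRUE    0.4029    FALSE
#> 3       FSEILEFIAR           TRUE    0.9999     TRUE
#> 4 QQLFTYPDTAPTDLWK           TRUE    0.9999     TRUE
#> 5    WLYLTNECQTPYK           TRUE    0.2298    FALSE
```

The two decoys co-elute (they are real peaks) but their transition
intensity ratios disagree with the reference pattern, so criterion B
(mean dotp > 0.80) rejects them; the three faithful peptides pass all
criteria.

A shell entry point wrapping these stages (subcommands `design`, `screen`,
`refine`, `validate`, `simulate`; exit code 0 = clean, 2 = peptides removed
by the screen, 1 = usage/IO error) is installed at:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "mrmpanel.R", package = "mrmpanel"))') design --help
```

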