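# heliomod

Analysis toolkit for studies of **heliorhodopsins (HeRs)** — inverted-topology
microbial rhodopsins whose genes frequently share operons with, and appear to
regulate, neighboring genes such as ATP-binding cassette (ABC) transporters.
The package is aimed at groups combining comparative genomics with binding
and activity measurements of a HeR–partner pair, and implements the four
computational layers such a study needs:

1. **Operon neighborhoods** — locate HeR anchor genes in annotated genomes
   (GFF3 + protein FASTA + homology hit table), predict co-transcription of
   flanking genes by the strand + intergenic-distance heuristic (same-operon
   gene pairs peak between −20 and 30 bp), classify anchors into ten
   neighbor-gene groups, and summarize cohorts.
2. **Residue conservation** — per-reference-position amino-acid frequencies
   per group from a labeled alignment ("frequency per HeR": counts
   normalized by group size, gaps tracked as NA), differential frequencies
   against the non-co-transcription background flagged when |Δ| > 0.19,
   amino-acid-class aggregation, and charged-residue conservation by
   intracellular loop.
3. **Binding thermodynamics** — one-site (Wiseman) and sequential two-site
   ITC isotherms, Levenberg–Marquardt fitting, and the derived quantities
   ΔG = RT·ln K_d, −TΔS = ΔG − ΔH at 25 °C, with positive cooperativity
   flagged when K_d,2 < K_d,1.
4. **Kinetics and assays** — Michaelis–Menten fits (v = V_max·S/(K_m+S))
   with k_cat = (V_max/[E])/60 and k_cat/K_m; 4-parameter logistic
   dose–response y = A1 + (A2−A1)/(1+10^((Logx0−x)·p)) with
   IC50 = 10^Logx0; exponential decay y = y0 + A1·e^(−x/t1) with
   t½ = t1·ln 2; Henderson–Hasselbalch pKa; phosphate calibration; MIC80;
   fluorescence-trace normalization.

Seeded synthetic-data generators produce every input format with planted
ground truth, so the whole pipeline is testable offline; the methods
vignette (`vignettes/heliomod-methods.Rmd`) documents the models,
conventions and generator regimes in detail.

## Worked example

Generate a 448-anchor synthetic cohort with a 38.6% planted co-transcription
rate, run the neighborhood pipeline, then fit a noisy one-site titration of
the weak-binding regime (K_d = 91.6 µM, ΔH = 48.9 kcal/mol):

```r
library(heliomod)

gen     <- generate_genome_cohort(n_genomes = 448, co_rate = 173/448, seed = 1)
anchors <- find_anchor_genes(gen$genes, hits = gen$hits)
units   <- lapply(anchors$gene_id, function(id) neighborhood(gen$genes, id))
summarize_cohort(classify_cohort(units))
#> Anchor cohort summary
#>   anchors: 448  with adjacent gene: 173 (38.6%)  frequent-neighbor: 173
#>   glutamine_synthetase   17
#>   ...
#>   non_co_transcription   275

expt <- generate_itc(list(n = 1, Ka = 1/91.6e-6, dH = 48.9, q_offset = 0),
                     "one_site", noise_sd = 0.02, seed = 1)
fit_binding(expt, "one_site")
#> ITC binding fit: one_site model
#>   Kd = 91.6 uM  dH = 48.4 kcal/mol  -TdS = -53.9  dG = -5.51 (T = 298.15 K)
#>   n = 1.02 sites, q_offset = 0 ucal
#>   RSS = 2582, saturation coverage (max molar ratio) = 3.56
```

The recovered K_d (91.6 µM) matches the planted value; the saturation
coverage notes that the titration reaches molar ratio ≈ 3.6 without full
saturation, as expected for so weak an interaction. The packaged reference
table of published binding parameters closes thermodynamically:

```r
thermo_closure_report(read_thermo_table())
#>  variant partner ...   dG closure_dG rtln_dG pass
#>       WT      DE ... -5.4       -5.4   -5.51 TRUE
#>    W225A      DE ... -6.5       -6.5   -6.51 TRUE
#>    R229Q      DE ... -7.2       -7.2   -7.22 TRUE
#> overall: PASS
```

Here `closure_dG` is ΔH + (−TΔS), which reproduces the printed ΔG exactly,
and `rtln_dG` is RT·ln K_d, which reproduces it to within printed rounding.

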