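# famsurvey

Genome-wide gene-family surveys in R: domain-based member identification,
duplication-mode classification, Ka/Ks divergence dating, subfamily
classification, protein descriptors, and tissue-expression typing of
duplicate pairs — the full analysis arc of a plant gene-family survey,
modelled on the amino acid transporter (AAT) family of soybean, packaged
as tested, reusable functions.

## Who this is for

Anyone running or reviewing a "genome-wide identification and expression
analysis of family X" style study: the package factors that workflow into
auditable stages with pinned parameters, and ships a fully seeded
synthetic-genome generator that plants known family structure (tandem
arrays, collinear duplicate blocks with controlled synonymous divergence,
truncated-domain decoys, an 11-tissue count matrix) so every stage can be
validated against ground truth without downloading a genome.

## The core computations

- **Identification** — proteins are scanned with position-weight log-odds
  profiles (bits against a uniform background) of the family's diagnostic
  domains; candidates whose best hit covers < 50% of the profile are
  rejected as "short or incomplete". The score threshold is calibrated on
  a random-sequence null.
- **Duplication** — tandem arrays are connected components of homologous
  family genes within ≤ 1 intervening non-family gene; WGD/segmental
  blocks are chains of anchor pairs, strictly rank-monotonic on both
  chromosomes (dynamic programming, ≥ 3 anchors). Genes can be
  `tandem`, `wgd_segmental`, `both`, or `none`.
- **Dating** — Nei–Gojobori (1986) Ka/Ks on codon alignments threaded
  through protein alignments: per-codon site fractions by
  single-nucleotide neighbour enumeration, differences averaged over
  minimal substitution pathways, Jukes–Cantor correction
  d = −(3/4)·ln(1 − 4p/3), then T = Ks / (2 × 6.1×10⁻⁹) × 10⁻⁶ My.
  Ka/Ks < 1 purifying, > 1 positive; dates ≤ 25 My map to the recent
  Glycine-specific WGD (~13 Mya), ≤ 65 My to the ancient event (~59 Mya).
- **Classification** — p-distance (1 − identity from BLOSUM62 global
  alignments) k-nearest-reference votes over the 12 subfamilies
  (AAP, LHT, ProT, GAT, AUX, ANT, ATLa, ATLb, TTP, CAT, ACT, PHS), plus
  neighbour-joining trees with optional bootstrap.
- **Descriptors** — molecular weight, isoelectric point (bisection on the
  Henderson–Hasselbalch net charge), Kyte–Doolittle transmembrane spans,
  and occurrences of the family's 20 published consensus motifs.
- **Expression** — RPKM; genes classed silent (< 1 RPKM everywhere),
  uniform (< 2-fold range), or regulated (with preferred tissues);
  duplicate pairs typed I (same pattern), II (one copy uniformly higher),
  or III (divergent) from log-scale correlation and median fold shift.

## Worked example

The packaged fixture transcribes the 23 published (Ka, Ks) pairs of the
family's segmental duplicates; `table1_check()` recomputes the derived
ratio and date columns:

```r
library(famsurvey)
table1_check()
#>               pair    ka    ks   ratio ratio_printed time_my date_printed
#> 3    GmCAT7-GmCAT9 0.163 0.933 0.17471         0.174  76.475        76.51
#> 5    GmPHS1-GmPHS2 0.061 0.348 0.17529         0.176  28.525        28.53
#> 10 GmATL11-GmATL12 0.244 0.228 1.07018         1.070  18.689        18.65
#> 23     LHT14-LHT15 0.114 0.243 0.46914         0.470  19.918        19.92
#> ...
#> ratios < 0.6: 21 | dates <= 25 My: 20 | range 6.80-76.48 My
```

Reading the output: 21 of the 23 pairs evolved under strong purifying
selection (Ka/Ks < 0.6); 20 pairs date to the recent whole-genome
duplication (≤ 25 My; the three exceptions are the CAT7/CAT9, PHS1/PHS2
and ACT4/ACT6 pairs); dates span 6.8–76.5 My. Each recomputed date is
within 1% of print; the handful of ratio deviations (e.g. 0.05785 vs the
printed 0.061) are three-decimal rounding of the published table's
unrounded inputs and are listed, not hidden.

The end-to-end survey runs on a generated genome with planted truth:

```r
bundle <- generate_genome(generator_config())   # 189 members + 17 decoys
res <- run_pipeline(bundle, outdir = "survey_out")
res$summary$n_candidates            # 206 genes carry a domain hit
res$summary$n_accepted              # 189 pass the completeness filter
res$summary$duplication_modes
#> $tandem  30   $wgd_segmental  40   $both  6   $none  113
```

i.e. the survey recovers exactly the planted family: 36 tandem genes
(30 + 6), 46 WGD genes (40 + 6), 6 genes in both modes — and
`survey_out/` holds per-stage TSVs, the NJ tree and a JSON summary.

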