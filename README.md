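# icescreen

Hybrid targeted/untargeted UHPLC-HRMS screening of water-soluble
organic tracers in ice cores and snow.

Melted ice and snow samples carry trace organic records of past
wildfires (methoxyphenols such as vanillic and syringic acid,
released by lignin pyrolysis) and of biogenic secondary organic
aerosol (pinic acid from α-pinene oxidation). Modern high-resolution
mass spectrometry measures these both ways at once: a **targeted**
assay quantifies a fixed tracer panel against internal-standard
calibration curves, while an **untargeted** (non-target screening)
pass annotates every detected [M−H]⁻ feature from its exact mass.
`icescreen` implements the complete computational workflow for both
sides, for analytical chemists and paleoclimate groups working with
peak tables exported from any instrument software.

## What it computes

**Untargeted side**

* Molecular formula assignment: exhaustive enumeration of neutral
  formulas whose deprotonated-ion m/z lies within a ppm tolerance,
  filtered by RDBE ≥ 0 (integer, even-electron anions), 0 ≤ H/C ≤ 3,
  O/C ≤ 3, ranked by |ppm|.
* Kendrick mass defect analysis with the CH₂ base,
  KM = m × 14 / m(CH₂), KMD = round(KM) − KM, and automatic mining of
  CH₂-homologue series (e.g. the linear dicarboxylic acids
  C₂O₄H₂(CH₂)ₙ at KMD key 0.105 and the ω-hydroxy fatty acids
  CₙH₂ₙO₃ at 0.068).
* Van Krevelen (H/C vs O/C) and Kroll diagrams, with the average
  carbon oxidation state OS_C = 2·O/C − H/C and the standard region
  rules (aromatics H/C < 1; OOA 1.2 < H/C < 1.9, 0.3 < O/C < 1;
  SV/LV-OOA band −1 < OS_C < 0.5).
* Identification confidence on the five-level scale, combining
  reference-standard retention times (Level 1 when ΔRT < 0.1 min with
  spectral support), spectral library scores (Level 2 at score ≥ 80),
  and formula uniqueness (Level 4).

**Targeted side**

* Internal-standard calibration (response ratio vs concentration,
  OLS): slope = response factor RF.
* Validation panel: LOD = 3.3 σ/S (pg on-column via 20 µL injection),
  MDL = 3 × SD of procedural blanks, accuracy (O − T)/T %, precision
  %RSD, matrix effect (RF_UPW − RF_matrix)/RF_UPW %, spike recovery
  with level-independence ANOVA.
* Sample quantification with recovery correction and MDL flagging.
* Frozen-vs-unfrozen storage comparisons (glass vial vs frozen SPE
  cartridge): per-compound area ratios, Welch t-tests, and 0.8–1.2 /
  0.9–1.1 agreement-band censuses.

A seeded synthetic-data generator (`synth_config()`,
`simulate_untargeted()`, `simulate_calibration()`,
`simulate_storage()`) produces every input table with known ground
truth, and `run_pipeline()` chains all stages deterministically.

## Worked example

Ten high-abundance suspects from an alpine ice-core sample, with
their library scores and the lab's reference standards (shipped as
`inst/extdata/belukha_suspects.csv` / `belukha_standards.csv`):

```r
library(icescreen)
feats <- read_feature_table(system.file("extdata", "belukha_suspects.csv",
                                        package = "icescreen"))
stds  <- read_standards(system.file("extdata", "belukha_standards.csv",
                                    package = "icescreen"))
ann <- annotate_features(feats)          # formula assignment, 3 ppm
idd <- identify_features(ann, stds)      # confidence levels
idd[, c("id", "rt", "formula", "ppm", "level", "matched_standard")]
```

```
    id    rt  formula      ppm level      matched_standard
1  B01  3.89   C4H6O4  0.06650     1         succinic acid
2  B02  7.51  C8H12O4  0.68739     4                  <NA>
3  B03  7.98  C7H10O4  0.17608     4                  <NA>
4  B04 10.42  C9H16O4  0.30712     1          azelaic acid
5  B05  4.58   C5H8O4 -0.01742     1         glutaric acid
6  B06  8.19  C6H10O4  0.39747     2 3-methylglutaric acid
7  B07  5.86   C5H8O4 -0.09374     2   methylsuccinic acid
8  B08  4.08   C5H8O3  0.19417     1        levulinic acid
9  B09  9.70 C10H16O3  0.01136     4                  <NA>
10 B10  7.82  C9H14O5  1.00909     4                  <NA>
```

Every mass resolves to a single formula within 3 ppm (all CHO). Four
suspects are confirmed at Level 1 by standards co-eluting within
0.1 min; the two isomer cases (RT off by > 0.1 min despite strong
spectral matches) land at Level 2; the four without standards or
library hits keep their unequivocal formulas at Level 4:

```r
level_census(idd$level)
#>  1  2  3  4  5
#>  4  2  0  4  0
```

Homologue mining groups five of the diacids into the KMD 0.105
series (succinic → azelaic, 0–5 CH₂ repeats above the base member):

```r
detect_homologues(idd)[, c("series_id", "kmd_key", "id", "formula", "n_ch2")]
#>   series_id kmd_key  id formula n_ch2
#> 1         1   0.105 B01  C4H6O4     0
#> 2         1   0.105 B05  C5H8O4     1
#> 3         1   0.105 B07  C5H8O4     1
#> 4         1   0.105 B06 C6H10O4     2
#> 5         1   0.105 B04 C9H16O4     5
#> 6         2   0.118 B03 C7H10O4     0
#> 7         2   0.118 B02 C8H12O4     1
```

And the oxidation-state descriptors place levulinic acid squarely in
the oxygenated-organic-aerosol region:

```r
classify_compound("C5H8O3")
#> $os_c -0.4   $vk_region "OOA"   $kroll_band TRUE
```

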