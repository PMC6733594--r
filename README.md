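# phresh

Simulation and quantification of photoconvertible-reporter signalling
histories (PHRESH) in the zebrafish spinal cord.

## The problem

A Kaede reporter driven by a pathway target gene converts irreversibly
from green to red fluorescence under 405 nm light. Converting the whole
tissue at a chosen time t0 and imaging 6 h later separates each cell's
signalling history: red-only cells ended their response before t0
("past"), green-only cells began after t0 ("new"), and double-positive
cells responded continuously ("continued"). Repeating the conversion
across developmental time yields a spatiotemporal map of pathway
activity — here, of Hedgehog (`ptc2` reporter) and Notch (`her12`
reporter) response during spinal-cord patterning (24–78 hpf), and of
the Notch→Hh epistasis probed with cyclopamine, the gamma-secretase
inhibitor LY-411575, and heat-shock NICD / rSmoM2 / EGFP-Gli1
transgenes.

The package is for people building or validating this kind of analysis:
it implements the full measurement chain used on real stacks and pairs
it with a synthetic embryo whose ground truth is calibrated to the
published quantitative results, so every stage is testable against
planted truth without any external data.

## What is in the box

* **Ground-truth fields** — `notchActivity()` / `hhActivity()`:
  per-cell pathway activity a(x, t) in [0, 1] over the three phases of
  cord signalling (activation 24–42 hpf: DV-uniform Notch, ventrally
  graded Hh with the active domain spanning the ventral 75% of cord
  height; consolidation 42–66 hpf: shrinkage to a medial band 1–2 cell
  tiers dorsal to the canal; termination: return to basal), with the
  full drug/transgene/genotype catalogue and the Notch gate on cord Hh
  response (exponential relaxation, half-time 0.8 h).
* **Reporter kinetics** — `stepReporter()`, `photoconvert()`,
  `simulateReporter()`: dG/dt = αa(t) − δG, dR/dt = −δR, with an
  instantaneous conversion G → R (efficiency η, exactly conserving
  G + R) at t0.
* **Image synthesis** — `renderStack()`, `resliceTransverse()`,
  TIFF + JSON sidecar I/O: two-channel lateral confocal stacks with
  Gaussian optics, Poisson shot noise and read noise; transverse
  reslicing as a pure axis permutation.
* **PHRESH quantification** — `unconvertedReference()`,
  `dvProfile()` / `mlProfile()` (three lines through the canal, one
  line dorsal to it, % of the unconverted-region green maximum),
  `averageOverSomites()`, `classifyResponse()`, `buildMap()`.
* **Domain morphometry** — `segmentExpression()`,
  `domainPercentage()` (100 × domain area / cord area),
  `normalizeToControlMax()` (DMSO mean as "control maximum"),
  `timecourseReduction()`, and the cohort recipes
  `notchInhibitionTimecourse()` and `gli1RescueExperiment()`.
* **Statistics and driver** — `mannWhitneyU()` (exact for small
  tie-free samples, normal approximation otherwise),
  `starAnnotation()`, `summarizeGroups()` (mean ± SD), and
  `runPipeline()` with YAML configs (`inst/extdata/embryo.yaml`) and a
  thin CLI (`inst/scripts/phresh.R`).

## Worked example

The canonical divergence experiment: embryos treated with LY-411575
from 20 hpf for 1 or 2 h versus DMSO controls, measured for the ptc2
(Hh target) and sox2 (progenitor) domains by the full
render → reslice → segment → normalize pipeline (8 embryos × 8
sections per condition):

```r
library(phresh)
res <- notchInhibitionTimecourse(timepoints = c(1, 2),
                                 nEmbryos = 8, nSections = 8, seed = 1)
res$reductions
#>  marker   condition timepoint_h n normalized_mean reduction_pct
#>    ptc2 LY411575_1h           1 8        53.57426     46.425745
#>    ptc2 LY411575_2h           2 8        49.37244     50.627558
#>    sox2 LY411575_1h           1 8        92.39610      7.603903
#>    sox2 LY411575_2h           2 8        51.32686     48.673144
```

After one hour of Notch inhibition the Hh target domain has collapsed
by ~46% while the progenitor domain has barely moved (~8%); by two
hours both are roughly halved — the Hh response is lost *before* the
progenitor state, which is the ordering the experiment was designed to
establish. The group comparison mirrors the published statistics:

```r
norm <- res$normalized
mannWhitneyU(norm$pct_normalized[norm$marker == "ptc2" &
                                 norm$condition == "LY411575_1h"],
             norm$pct_normalized[norm$marker == "ptc2" &
                                 norm$condition == "DMSO"])
#> Mann-Whitney U test (exact, two.sided): U = 0, n = (8, 8), p = 0.0001554 ***
```

The epistasis recipe recovers the Gli-level rescue: ectopic EGFP-Gli1
enlarges the olig2 domain by ~25% in DMSO, and restores it to ~63% of
the wild-type control maximum under Notch inhibition:

```r
gl <- gli1RescueExperiment(nEmbryos = 8, nSections = 8, seed = 2)
c(enlargement = gl$enlargementPct, rescue = gl$rescueNormalizedMean)
#> enlargement      rescue
#>    24.59189    63.12094
```

## Documentation

The methods vignette (`vignettes/phresh-methods.Rmd`) describes the
ground-truth models and their calibration, the kinetic and optical
defaults, the segmentation design (counterstain-referenced relative
expression with a mass-conserving threshold, and why plain Otsu is
biased here), the cohort variance structure, numerical choices, and
the limits of what synthetic validation shows about real data.
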