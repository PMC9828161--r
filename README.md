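# dichromatR

Quantifying avian-perceived plumage sexual dichromatism across a clade, and
testing its ecological correlates — breeding timing, spacing and sympatry —
with Bayesian phylogenetic binomial regression.

## The scientific problem

In many passerines, males and females differ in plumage colouration.
Whether a bird *perceives* that difference depends on its own visual
system, not ours: songbirds have four single-cone classes (including an
ultraviolet/violet-sensitive cone) plus a double cone used for achromatic
(luminance) vision. `dichromatR` implements the full analysis chain for a
comparative study of dichromatism in a clade such as the true thrushes:

1. **Receptor-noise-limited (RNL) colour vision.** Reflectance spectra
   R(λ) measured at 300–700 nm are converted to photoreceptor quantum
   catches
   `Q_i = ∫ R(λ) S_i(λ) I(λ) dλ`
   with cone sensitivities `S_i` (rebuilt from published λmax values with
   the A1 pigment template) and illuminant `I`. Log receptor signals
   `f_i = ln Q_i` are compared between stimuli; discriminability is the
   RNL distance ΔS in *just-noticeable differences* (JND), with channel
   noise `e_i = ν √(η_ref/η_i)` set by the Weber fraction ν and relative
   cone abundances η. The achromatic contrast is
   `ΔL = |ln(Q_D(A)/Q_D(B))| / e_D` through the double cone. For two
   receptors ΔS reduces to `|Δf_1 − Δf_2| / √(e_1² + e_2²)`; the package
   implements the general n-receptor quadratic form.
2. **Dichromatism scoring.** For each species, every male is compared with
   every female (3 × 3 specimens → 9 pairs per patch) on five plumage
   patches (belly, breast, throat, crown, mantle). A species' dichromatism
   score is the number of patches k ∈ [0, 5] whose mean JND exceeds a
   threshold t ∈ {1, 2, 3}, per channel (chromatic, achromatic, or their
   union).
3. **Sympatry and life history.** Breeding ranges are handled as
   presence–absence grids; range overlap is the percentage of the focal
   species' cells shared with a congener, and the sympatric count is the
   number of congeners overlapping > 30%. Breeding season length is
   z-scored; migration (none/partial/full) and landmass (mainland/island)
   enter as dummies.
4. **Phylogenetic binomial regression.** Counts are modelled as
   `k_s ~ Binomial(5, logit⁻¹(α + x_sᵀβ + u_s))` with species effects
   `u ~ MVN(0, σ²C)`, where C is the Brownian-motion correlation from the
   clade phylogeny. Priors: Student-t(3, 0, 10) on the intercept and σ,
   flat on coefficients. Sampling is Hamiltonian Monte Carlo (non-centred,
   dual-averaged step size, adapted diagonal mass); convergence is gated
   at split-Rhat ≤ 1.01. Reported per predictor: posterior median odds
   ratio, 90% highest-density interval, probability of direction (pd),
   and the phylogenetic signal `λ = σ²/(σ² + π²/3)`. Models (timing,
   spacing, sympatry, intercept-only) are compared by K = 16-fold
   cross-validated expected log pointwise predictive density (ELPD).
5. **Synthetic data.** A seed-deterministic generator builds complete
   study bundles — Yule tree, traits, gridded ranges, binomial counts with
   known ground truth, and reflectance spectra whose sex offsets are
   calibrated by root finding to realise the intended JNDs — so the whole
   pipeline is testable offline.

## Worked example

A 25-species synthetic study, end to end:

```r
library(dichromatR)

vs <- blackbirdVisualSystem()                       # packaged visual system
bundle <- simulateStudy(simulationConfig(nSpecies = 25), seed = 4, vs = vs)

means  <- averageReplicates(bundle$spectra)          # specimen means
pc     <- patchContrasts(means, vs)                  # male-female JNDs
head(pc, 3)
#>    species  patch meanChromatic meanAchromatic nPairs
#> 1    sp001  belly    3.52941416     1.37573393      9
#> 26   sp001 breast    0.14600086     0.11794055      9
#> 51   sp001  crown    0.05089928     0.09438322      9

scores <- scoreSpecies(pc)
monomorphicProportion(scores, "combined", 2)
#> [1] 0.44

comb <- scores[scores$channel == "combined" & scores$threshold == 1, ]
k    <- setNames(comb$k, comb$species)[bundle$traits$species]
C    <- phyloCorrelation(bundle$tree, bundle$traits$species)
fit  <- fitDichromatismModel(k, designMatrix(bundle$traits, "sympatry"), C,
                             chains = 4, iter = 4000, seed = 4,
                             maxLeapfrog = 32, label = "sympatry")
summarizePosterior(fit)$predictors
#>    parameter    or hdiLower hdiUpper    pd reliable
#> 1  Intercept 0.127    0.030    0.247 0.999     TRUE
#> 2 nSympatric 1.309    0.956    1.713 0.938     TRUE
```

Reading the output: `sp001`'s belly patch differs between the sexes by
3.5 chromatic JND (clearly discriminable to the modelled observer) while
its breast and crown do not; 44% of the simulated species have no patch
above 2 JND in either channel; and each additional sympatric congener
multiplies the odds that a patch is dichromatic by ≈ 1.31 (90% HDI
0.96–1.71, pd = 0.94 — flagged as a reliable direction under the pd ≥ 0.90
rule). The generating truth for this bundle used an odds ratio of 1.4 per
sympatric species.

The same pipeline runs from the shell via
`inst/scripts/dichromatism-pipeline.R` with a YAML configuration
(stages: `simulate jnd score sympatry fit kfold report`).

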