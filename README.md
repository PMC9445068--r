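# dyadkin

Quantitative analysis of emotional body language in **dyadic point-light
interactions**. Given two-agent motion-capture trajectories (15 markers per
agent, 3-D coordinates in mm, 100 Hz, 4-s clips), the package

1. extracts **8 intrapersonal** kinematic/postural features — velocity
   (VEL), acceleration (ACC), vertical movement (VM), bounding-box volume
   and its SD (VOL, VOL_STD), posture symmetry (SM), limb angles (LA), limb
   contraction (LC) — and **12 interpersonal** features — interpersonal
   distance and its SD (IPD, IPD_STD), personal-space occupancy (PS),
   interpersonal orientation and its balance (IPO, IPO_BAL), distance
   correlations (DC_VEL, DC_ACC, DC_VOL, DC_LC), velocity/acceleration
   synchronisation (SYNC_VEL, SYNC_ACC) and motion-energy balance (ME_BAL);
2. tests **emotion specificity** of each feature with one-way ANOVAs
   (F, η² = SS_between/SS_total, Bonferroni post hocs; Fisher-Z for
   correlation-valued features) and recognition rates against the 25%
   chance level;
3. classifies the emotion of a scene with **bagged decision trees**
   (bootstrap-aggregated CART, majority vote) from intrapersonal (M1),
   interpersonal (M2) or combined (M3) predictors, using balanced
   leave-one-per-category cross-validation and impurity-decrease predictor
   importance;
4. runs a **representational similarity analysis**: model, feature,
   per-rater behavioural and combination RDMs (48 × 48), Kendall's τ_A
   (ties in the denominator only), Pearson correlations for valence,
   permutation and Wilcoxon signed-rank inference with Holm/FDR control,
   noise ceilings and classical MDS.

Because no mocap corpus ships with the package, a first-class
**synthetic-scene module** generates archetype-driven dyads (4 emotions ×
12 scenes by default: happy = fast and bouncy, affectionate = close and
mutually oriented, sad = slow, angry = distant and unbalanced) plus a
simulated 31-rater cohort with a plausible confusion structure, so the whole
pipeline is testable end-to-end.

## Worked example

```r
library(dyadkin)
scenes   <- generate_dataset(seed = 1)          # 48 = 4 x 12 scenes
features <- extract_features(scenes)            # 48 x 22 table

aggregate(features[, c("VEL", "VM", "IPD", "IPO", "ME_BAL")],
          list(emotion = features$emotion), function(x) round(mean(x), 1))
#>     emotion   VEL    VM    IPD  IPO ME_BAL
#> 1 affection 200.2 218.0  424.9 80.0    0.9
#> 2     anger 271.5 388.9 1166.9 23.4    0.8
#> 3 happiness 357.1 690.6 1018.3 36.1    0.9
#> 4   sadness 133.5 114.5  865.9 34.5    0.8

feature_anova_table(features)$VEL
#> VEL: F(3,44) = 236.97, p = 3.64e-27, eta^2 = 0.94

compare_models(features, features$emotion, n_trees = 200, seed = 1)$table
#>   model overall happiness affection sadness anger
#> 1    M3   1.000         1     1.000   1.000     1
#> 2    M1   0.979         1     0.917   1.000     1
#> 3    M2   0.979         1     1.000   0.917     1

ratings <- simulate_ratings(scenes, rater_model(seed = 2))
recognition_vs_chance(ratings)[, c("emotion", "accuracy", "t", "p_bonferroni")]
#>     emotion accuracy    t p_bonferroni
#> 1 happiness    0.903 45.0     1.67e-28
#> 2 affection    0.793 26.2     1.33e-21
#> 3   sadness    0.844 33.0     1.60e-24
#> 4     anger    0.895 39.4     8.67e-27

beh <- behavioural_rdms(ratings)
emo <- relate_features_to_behaviour(feature_rdms(features), beh$emotion, "tau_a")
head(emo$table, 5)
#>   feature mean_cor   p_raw  p_holm fdr_significant
#> 1      VM     0.22 4.7e-10 9.3e-09            TRUE
#> 2     VEL     0.20 4.7e-10 9.3e-09            TRUE
#> 3     IPD     0.19 4.7e-10 9.3e-09            TRUE
#> 4      LC     0.18 4.7e-10 9.3e-09            TRUE
#> 5 IPO_BAL     0.16 4.7e-10 9.3e-09            TRUE
unlist(emo$ceiling)
#> lower upper
#> 0.268 0.292
```

Reading the output: the simulated archetypes make happy dyads fastest and
bounciest, affectionate dyads closest and most mutually oriented, and sad
dyads slowest — so the velocity ANOVA is strongly significant; the combined
classifier (M3) is at least as accurate as either feature level alone;
per-rater recognition is far above the 25% chance level; and the feature
whose representational geometry best matches the raters' emotion judgements
is vertical movement, with the across-rater noise ceiling (≈ 0.27–0.29)
bounding what any single feature could explain.

`run_all(run_config(seed = 1, out_dir = "run"))` executes the whole
simulate → features → anova → classify → rsa chain into one directory with a
`summary.json`. The same stages are scriptable:

```sh
Rscript -e 'dyadkin::dyadkin_cli()' simulate --seed 1 --out scenes/
Rscript -e 'dyadkin::dyadkin_cli()' features --scenes scenes/ --out features.csv
Rscript -e 'dyadkin::dyadkin_cli()' run --seed 1 --out run/
```

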