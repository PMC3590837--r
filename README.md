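# pitchload

Shoulder kinetics and pain association for youth baseball pitching.

`pitchload` is an R package for biomechanics and sports-medicine
researchers who work with 6-DOF motion-capture recordings of pitching. It
computes the shoulder joint-reaction force over the delivery, extracts the
two kinetic parameters most often implicated in youth shoulder injury —
**peak anterior force (PAF)** during arm cocking and **peak proximal force
(PPF)** during arm acceleration — and relates them to reported shoulder
pain with the study design's statistical chain.

## The model

Kinetics: the torso and throwing arm are modelled as four rigid links
joined by ball-and-socket joints. After zero-lag Butterworth filtering
(4th order net, 13.4 Hz cutoff, 144 Hz capture), functional estimation of
the glenohumeral centre by least-squares pivot fitting, and construction
of ISB-convention anatomical frames, the recursive Newton–Euler pass gives
the force applied by the torso to the proximal humerus:

    F_shoulder = sum over distal bodies of  m_i (a_i − g),

with the 0.145 kg ball carried in the hand until release. The force is
resolved in the humerus anatomical frame (anterior / superior / proximal),
normalized to percent bodyweight (100·F / m·g), and reduced to
phase-windowed peaks: PAF = max anterior over [stride-foot contact,
maximum external rotation], PPF = max proximal over [maximum external
rotation, ball release].

Statistics: point-biserial correlation screens each exposure against
binary pain status; exposures with p < 0.05 enter a single-predictor
logistic model fitted by iteratively reweighted least squares,

    logit P(pain) = β₀ + β₁ · PPF,

with Wald inference (OR = exp β₁, 95% CI = exp(β₁ ± 1.959964·SE)),
a likelihood-ratio model chi-square, and classification analysis at a 0.5
threshold.

Because no raw per-subject data are deposited with the source study, the
package includes a synthetic-data module: forward-kinematics pitch
recordings with analytically known ground-truth forces and events
(`generate_pitch_motion()`), and cohorts drawn from the published
exposure–risk model, PPF ~ N(201.59, 48.68²) N with
pain ~ Bernoulli(logit⁻¹(0.046·PPF − 10.126)) (`generate_cohort()`).

## Worked example

```r
library(pitchload)

# simulate one pitch (142.6 cm, 41.1 kg right-hander) and run the pipeline
pitch <- generate_pitch_motion(height_cm = 142.6, mass_kg = 41.1,
                               profile = pitch_profile(seed = 5))
pk <- pitch_kinetics(pitch$recording, pitch$landmarks,
                     height_cm = 142.6, mass_kg = 41.1)
print(pk)
#> Pitch events (frames): SFC = 86  MER = 138  BR = 173
#> Peak shoulder kinetics:
#>   PAF = 29.27 N (7.3 %BW) at frame 95 [cocking 86-138]
#>   PPF = 86.15 N (21.4 %BW) at frame 173 [acceleration 138-173]
#> GH pivot fit residual: 0.68 mm (condition 2.3)
```

The events bound the two phases; the peaks are reported in Newtons and in
percent bodyweight, and the pivot-fit residual says how well the
glenohumeral centre was located from the recording itself.

```r
# a 19-subject cohort from the published generative model, analysed
cohort <- generate_cohort(cohort_params(n = 19, seed = 7))
run_association(cohort)
#> Pain-association analysis: n = 19 (pain prevalence 47.4%)
#> ...
#> PAF vs pain: r = -0.201, t(17) = -0.846, p = 0.409
#> PPF vs pain: r = 0.722, t(17) = 4.308, p = 0.000
#> ...
#> Exposure selected at p < 0.05 : PPF
#>                 B  S.E.  Wald df     p Exp(B)
#> intercept -10.812 5.344 4.093  1 0.043  0.000
#> slope       0.050 0.026 3.819  1 0.051  1.051
#> slope 95% CI for Exp(B): 1.000-1.106
#> model chi-square = 12.961, df = 1, p = 0.000; log-likelihood = -6.663
#> Classification at threshold 0.50: overall 78.9% correct; pain cases 77.8%; no-pain cases 80.0%
```

Only PPF passes the correlation screen (as in the study design), the
fitted slope of ~0.05 logit/N means each extra Newton of proximal force
raises the odds of reported pain by ~5%, and the classification table
shows how the fitted model scores against the observed labels. At n = 19
the estimates are naturally noisy; at large n they converge to the
generating values (see the test suite).

A command-line surface with the same functionality is available through
`run_cli()` / `inst/cli/pitchload.R`:

```sh
Rscript inst/cli/pitchload.R simulate-cohort --n 19 --seed 7 --out cohort.csv
Rscript inst/cli/pitchload.R associate --cohort cohort.csv --out report/
```

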