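# storyEncoding

Voxelwise encoding models and concatenated searchlight decoding for
naturalistic story-reading fMRI.

## The problem

When people read a natural story word by word, many subprocesses run at
once: perceiving letter strings, parsing sentences, retrieving word
meanings, tracking characters and dialogue. `storyEncoding` implements a
generative modelling approach that studies all of them simultaneously.
A story presented by rapid serial visual presentation (one word per
0.5 s) is annotated with per-word features — visual (word length),
syntactic, semantic and discourse-level columns — and the package learns,
for each voxel, how each feature modulates the fMRI signal over time.

## The model

Word-level annotations are collapsed onto the scanner's sampling grid by
summing the feature vectors of the four consecutive words presented in
each TR = 2 s interval, giving feature magnitudes x_f(t). Because the
hemodynamic response persists roughly 8 s, the signal of voxel v at time
t is modelled as

    y_v(t) = sum_f sum_{d=1..4} w_{v,f,d} * x_f(t - d) + noise,

a linear combination of every feature at the four preceding TRs. The
4-point weight vectors w_{v,f,·} are nonparametric temporal *response
signatures* — no hemodynamic shape is assumed. They are estimated by
ridge regression with a **separate penalty per voxel**, selected by inner
cross-validation over contiguous time blocks with the one-standard-error
rule; noisy voxels receive very large penalties and are effectively
silenced (automatic voxel selection).

Model quality is evaluated by cross-validated two-alternative passage
classification: predict the fMRI time series for a held-out 20-TR passage
and a random alternative passage, concatenate predictions across subjects
(voxels are pooled, never averaged), and pick the passage whose predicted
group time series is closer in Euclidean distance to the observed one.
Chance is 50%. A *concatenated searchlight* repeats the task per feature
set inside small cubes of MNI coordinates, pooling each subject's own
voxels in the cube, and permutation tests with Benjamini–Hochberg FDR
control turn the accuracy maps into representation maps.

A seeded synthetic module generates stories, ground-truth signatures
(double-gamma shaped), and multi-subject fMRI with AR(1) noise and
per-subject anatomical jitter directly from the model equation, so the
whole pipeline is testable without scanner data.

## Worked example

```r
library(storyEncoding)

story <- generateStory(nWords = 2400, nFeatures = 10, seed = 1)
story
#> AnnotatedStory: 2400 words, 10 features, 1200.0 s
#>   feature sets: visual(2), syntax(3), semantics(3), discourse(2)

sim <- generateSubjects(story, nSubjects = 2, snr = 0.5, seed = 2)
sim$subjects[[1]]
#> SubjectData sub01 : 600 TRs x 200 voxels, 3 mm voxels

res <- runClassification(sim$subjects, story, seed = 3)
res
#> ClassificationResult: accuracy 1.000 over 60 trials
```

At a signal-to-noise ratio of 0.5 per driven voxel the model identifies
every held-out 20-TR passage against a random alternative (60 trials: 10
folds × 3 segments × 2 pairings). Replacing the signal with pure noise
(`snr = 0`) brings the accuracy to chance; single replicates are noisy
(their standard deviation is about 0.10), so calibration is visible in
the average over replicates:

```r
accs <- sapply(1:100, function(r) {
  story <- generateStory(nWords = 2400, seed = r)
  sim <- generateSubjects(story, nSubjects = 2, snr = 0, seed = 1000 + r)
  accuracy(runClassification(sim$subjects, story, seed = 2000 + r))
})
mean(accs)
#> [1] 0.5006667
```

The same task restricted to cubes of voxel coordinates maps *where* each
feature set is decodable (`searchlightMap`), `empiricalNull` estimates
chance by circularly shifting the feature series before training, and
`searchlightSignificance` attaches permutation p-values and FDR q-values.

A thin command-line wrapper covers the same pipeline:

```sh
Rscript inst/scripts/storyencoder simulate --seed 1 --out data/
Rscript inst/scripts/storyencoder classify --data data/ --out results/
```

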