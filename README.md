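# actihmm

Classification of epoch-level accelerometer counts into physical-activity
ranges, for researchers who analyze actigraphy in epidemiological studies.
The package implements both the traditional **cutpoint method** — each
epoch's impulse count is thresholded into light / moderate / vigorous
activity (Pate thresholds: `<420`, `420–841`, `>841` counts per 15 s) —
and its **hidden Markov model extension**, which removes most of the
misclassification the raw thresholding suffers when an activity's typical
count lies near a threshold.

The HMM extension treats the day as a hidden activity sequence
$Q_1,\dots,Q_T$ following a Markov chain $(\delta, \Gamma)$, with the
observed counts $x_t$ drawn from a state-dependent distribution with mean
$\mu_i$ (the state's *PA-level*). The procedure is:

1. **Train** $\lambda = (\delta, \Gamma, \Theta)$ on the day's counts by
   Baum–Welch EM (or direct numerical ML), for $m = 2,\dots,6$ states, and
   pick $m$ by AIC/BIC (on disagreement: the smaller model).
2. **Decode** the most likely activity sequence (Viterbi, or local
   posterior decoding) and replace each count by its decoded PA-level
   $\hat\mu_{q_t}$.
3. **Assign** ranges by applying the cutpoints to the decoded PA-levels
   instead of the raw counts.

Emission families: Poisson, generalized Poisson
($P(x) = \theta(\theta+\varphi x)^{x-1}e^{-\theta-\varphi x}/x!$, mean
$\theta/(1-\varphi)$), and Gaussian. A labeled-day simulator
(Markov-chain activity sequence, negative-binomial counts around the
lowest PA-level of 400 counts/epoch, Gaussian counts around the upper
levels) provides ground truth for method comparison, and
`evaluate_study()` scores misclassification rate (MCR), bout detection
and activity-count detection against that truth.

## Worked example

```r
library(actihmm)

cfg <- sim_config(seed = 7)           # calibrated default: 1440 epochs, 4 PA-levels
day <- generate_day(cfg, 3)           # one labeled day
day$true_bout_count                   # 12
day$true_activity_count               # 4

ct <- classify_traditional(day)
ct
#> <classification [cutpoint] day 3: 1440 epochs, 190 bouts>
misclassification_rate(day$true_range, ct$ranges)
#> 9.375

hm <- classify_hmm(day, family = "gauss", seed = 1)
hm
#> <classification [hmm-gauss] day 3: 1440 epochs, 12 bouts, 4 activities>
misclassification_rate(day$true_range, hm$ranges)
#> 0.06944444
```

The same day, same cutpoints: thresholding the raw counts fragments the
day into 190 bouts and misclassifies 9.4% of epochs, while the Gaussian
HMM pipeline recovers the exact bout count (12), the true number of
activities (4), and misclassifies a single epoch (0.07%). On a 50-day
study (`evaluate_study()` with seed 102), mean MCR is 10.7% for the
cutpoint method, 9.9% for the Poisson HMM, 1.4% for the Gaussian HMM and
1.1% for the generalized Poisson HMM; mean identified bouts drop from 227
(cutpoint) to 32 (Gaussian HMM) against a true mean of about 23.

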