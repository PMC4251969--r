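Package: actihmm
Title: Hidden Markov Model Extension of the Accelerometer Cutpoint Method
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of epoch-level accelerometer impulse counts into
    physical-activity ranges. Implements the traditional cutpoint method and
    its hidden Markov model (HMM) extension: HMMs with Poisson, generalized
    Poisson or Gaussian state-dependent distributions are trained on a day's
    count series by the Baum-Welch algorithm (or direct numerical maximum
    likelihood), the number of hidden activities is chosen by AIC/BIC, the
    most likely activity sequence is decoded globally (Viterbi) or locally
    (smoothed posteriors), and the decoded activity levels are assigned to
    ranges via published cutpoints. Includes a Markov-chain simulator for
    labeled accelerometer days, evaluation metrics (misclassification rate,
    bout and activity detection), delimited-text input/output and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
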