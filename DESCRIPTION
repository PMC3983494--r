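Package: spikevar
Title: Stochastic Variational Learning in Recurrent Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative modelling of spike trains with recurrent networks of
    stochastic Spike Response Model neurons carrying two switchable synapse
    sets: a generative network defining a joint point-process distribution
    over visible and hidden spike trains, and a recognition network whose
    clamped dynamics approximate the posterior over hidden spikes. Learning
    minimizes the variational free energy with score-function (REINFORCE)
    gradients, optionally baseline-corrected for variance reduction, either
    in batch mode or as an online three-factor Hebbian rule modulated by a
    global novelty signal. Includes importance-sampling estimation of the
    marginal data likelihood, an exhaustive-enumeration oracle for exact
    checks on tiny networks, and synthetic benchmark generators (sequential
    "stairs" spike patterns and a maze environment with rate-coded room
    views).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
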