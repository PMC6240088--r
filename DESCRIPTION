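Package: vfemea
Title: Variational Free-Energy Analysis of Multi-Electrode Array Learning Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying blind source separation and Bayesian learning
    in stimulated neuronal cultures recorded on 8x8 multi-electrode arrays.
    Implements the stochastic stimulation protocol in which two hidden binary
    sources drive 32 electrode sites through a fixed likelihood mapping; a
    discrete-state active-inference agent that infers the joint source state
    by softmax (free-energy minimising) updates and learns the likelihood by
    Dirichlet count accumulation; a synthetic spike-count generator emulating
    the cultures (Poisson counts with stimulation-evoked responses, slow
    drift and emerging source-selective responses); detection of functional
    specialisation with general linear models using discrete cosine temporal
    basis functions, partial F statistics, F maps and canonical variates
    analysis with surrogate-source controls; and the mapping from detected
    specialisation to empirical posterior beliefs, empirical variational free
    energy and its accuracy/complexity decomposition in a variational
    information plane.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
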