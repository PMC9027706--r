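Package: opinionet
Title: Multi-Agent Active Inference Simulations of Opinion Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates opinion formation on social networks with agents that
    perform active inference in a discrete partially observed Markov decision
    process. Each agent holds a categorical generative model over an abstract
    binary Idea, the beliefs of its neighbours ("meta-beliefs"), and its own
    posting and attention states; it infers hidden states from observed
    hashtag posts under an epistemic confirmation bias, selects whom to read
    by expected free energy combined with learned Dirichlet attendance
    habits, and posts hashtags proportional to its own belief. Networks of
    such agents produce consensus, polarisation, and echo-chamber dynamics,
    quantified by a polarisation index, re-attendance rate, consensus
    classification, and per-component cluster outcomes. Includes seeded
    trial and parameter-sweep runners, CSV/JSON input-output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
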