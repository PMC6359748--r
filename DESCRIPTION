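Package: mcchain
Title: Chain Molecular-Communication Simulator: Hormonal, Calcium and
    Neural Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a chain molecular-communication link in which binary
    information is on-off keyed onto hormone release, carried by passive
    diffusion to astrocytes, relayed through IP3-gated calcium oscillations
    into neural spike trains, transmitted along a passive axonal cable and
    across a chemical synapse with finite vesicle pools and a batched-arrival
    finite-capacity neurotransmitter queue, and decoded from the postsynaptic
    waveform. Includes the analytic layer for binary channel capacity via
    mutual information over the hormone-calcium-spike Markov chain and for
    end-to-end transmission delay, so that parameter sweeps over release
    quantity, firing rate, astrocyte count, vesicle-pool size and refill time
    can be re-run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
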