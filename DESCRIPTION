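Package: empathysim
Title: Spiking-Network Simulation of Affective Empathy and Altruistic Rescue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the developmental emergence of mirror and anti-mirror
    neurons in a three-population leaky integrate-and-fire spiking network
    trained by spike-timing-dependent plasticity during action execution and
    re-afference. Bodily damage is detected as an internal pain state by a
    free-energy prediction-error score over the agent's body pose, and the
    empathized pain of a conspecific serves as intrinsic reward for a tabular
    Q-learning rescue policy in a two-zone grid world. Includes the network
    simulator, the pain model, the grid-world environment, the two-agent
    rescue task, and reproducible experiment drivers with CSV and plot
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
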