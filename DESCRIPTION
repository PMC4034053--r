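Package: fgspike
Title: Figure-Ground Segregation and Shape Coding with a Feed-Forward Spiking Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.net", role = c("aut", "cre"))
Description: Simulates a five-area feed-forward network of Izhikevich spiking
    neurons that segregates figure from ground in binary displays through
    local excitation, global inhibition and post-inhibitory rebound spiking,
    and classifies polygon shapes by the dominance of vertical versus
    horizontal borders, read out as the first-spike order of two output
    cells. Includes a deterministic generator for framed polygon and circle
    stimuli and their mirror-, contrast- and figure-ground-reversed
    transforms, raster analysis (spike counts, firing onsets, spiking-area
    ratios, point rates), experiment drivers producing machine-readable
    reports, PGM/PNG image input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
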