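Package: cryoraman
Title: Automated Raman Hyperspectral Image Analysis of Cryoprotectant
    Partitioning in Frozen Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the partitioning of a penetrating cryoprotectant
    (DMSO) between the inside of a frozen cell and the unfrozen solution
    channels between extracellular ice crystals, from per-pixel Raman
    spectral image cubes. Implements derivative-thresholded peak
    integration with minimum-value background subtraction, robust
    cosmic-ray despiking with image-level quality rejection, classical
    morphological segmentation of the cell / ice / unfrozen-channel
    compartments, and the derived statistics (partitioning ratio,
    intracellular coefficient of variation, intracellular ice area
    fraction, line scans, extracellular gap profiles, nucleus-to-cytosol
    ratio, replicate summaries). Ships a ground-truthed synthetic phantom
    generator so every stage is testable without instrument data.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), png, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
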