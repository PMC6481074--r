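Package: csgs
Title: Multi-Spot Computer-Generated Holograms via Compressive-Sensing
    Gerchberg-Saxton Algorithms
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesis of phase-only computer-generated holograms (CGH) that
    focus a coherent beam into an arbitrary three-dimensional cloud of
    diffraction-limited spots, as used for holographic optogenetic
    photostimulation with liquid-crystal spatial light modulators (SLM).
    Implements the random superposition (RS), Gerchberg-Saxton (GS) and
    weighted Gerchberg-Saxton (WGS) multi-spot algorithms together with their
    compressive-sensing accelerations (CS-GS, CS-WGS), which iterate on a
    random subset of pupil pixels and finish on the full pupil. Includes
    hologram quality metrics (efficiency and uniformity), benchmark pattern
    generators, compression sweeps, convergence traces, spot-list and optical
    configuration I/O, 8/16-bit phase-mask export for SLM upload, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
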