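Package: handlat
Title: Handedness and Hemispheric Laterality Analysis of Dense Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study hemispheric specialization of the hand-motor
    system from dense (grayordinate-by-time) resting-state functional MRI.
    Implements global, ipsilateral and contralateral functional connectivity
    density (gFCD) hub mapping over the thresholded dense connectome,
    seed-based connectivity of the left- and right-hand motor areas, a
    normalized handedness index and a connectivity laterality index,
    interhemispheric homologous vertex matching and asymmetry mapping, a
    functional specialization index, and a vertex-wise group-statistics layer
    with Benjamini-Hochberg false discovery rate control.  A seeded
    synthetic-cohort generator emulates the statistical structure of a large
    developmental resting-state study (mirror-symmetric surfaces, band-limited
    signals with homotopic coupling, posterior hubs, handedness-dependent
    motor coupling, motion traces) so the full pipeline is testable without
    access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
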