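Package: finpam
Title: Passive Acoustic Monitoring Analysis of Fin Whale 20-Hz Pulses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-year passive acoustic monitoring of
    fin whale (Balaenoptera physalus) 20-Hz pulses from moored autonomous
    recorders: hydrophone count-to-SPL calibration, Welch power spectral
    densities and long-term spectrograms built on quietest-window selection,
    band signal-to-noise (FIN) indices with running-mean smoothing, automated
    downsweep detection with call-abundance and daily-occurrence metrics,
    solar-altitude light-regime classification with Kruskal-Wallis diel tests,
    ADCP mean volume backscatter (Deines sonar equation) and sea-ice radius
    averaging, plus a seeded synthetic-data generator emulating duty-cycled
    polar recorders so every stage runs on ground-truthed input.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    geosphere,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
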