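Package: metamel
Title: Metameric Multi-Channel LED Spectra and the Melanopic Tuning Range
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing metameric light spectra for
    integrative (circadian-aware) lighting. Synthesises multi-channel LED
    luminaires (6-, 8- and 11-channel presets), harvests metameric spectra at
    fixed chromaticity and photopic illuminance with a seeded stochastic
    search, gates them by ANSI/IES TM-30 style colour-fidelity criteria, and
    maps the achievable melanopic tuning range (melanopic equivalent daylight
    illuminance, melanopic daylight efficacy ratio and Michelson contrast)
    across chromaticity targets along the Planckian locus. Bundles the CIE
    1931 2-degree colour-matching functions, the photopic luminous efficiency
    function, the CIE standard illuminant D65 and a melanopic action spectrum
    constructed from the opsin nomogram with standard-observer ocular-media
    filtering.
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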