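Package: hexanlo
Title: Inverse Design of Hexaphyrin-Based Nonlinear-Optical Switches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the rational design of hexaphyrin-based nonlinear-optical
    (NLO) molecular switches. Computes the hyper-Rayleigh-scattering first
    hyperpolarizability (beta_HRS) and its orientational averages from a full
    3x3x3 beta tensor, with a Monte-Carlo rotational-averaging oracle; evaluates
    ratio- and difference-based switch-contrast figures of merit with the
    OFF-state clamping rule; models the meso-substitution chemical compound
    space of hexaphyrins (substitution patterns, fragment libraries,
    enumeration, canonical keys); runs a best-first-search site-by-site
    optimizer with pluggable property evaluators (packaged DFT reference
    tables, seeded synthetic landscapes, file-based external evaluators); and
    derives macrocycle topology descriptors (torsional ring strain, signed
    pi-conjugation index, Hueckel/Moebius classification, inversion-center
    detection) from XYZ geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
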