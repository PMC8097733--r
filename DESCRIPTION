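Package: devils
Title: Local Tone Mapping for High Dynamic Range Fluorescence Microscopy Stacks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Display enhancement for large fluorescence microscopy stacks with
    a high dynamic range, built around a one-parameter local tone-mapping
    operator: each plane is divided by a Gaussian-blurred copy of itself,
    square-root compressed, and cleared of residual background with an exact
    rolling-ball (grayscale opening) subtraction. Includes a lazy multi-page
    TIFF stack reader, deterministic parallel plane-wise processing to
    per-plane TIFF folders, BigDataViewer-compatible HDF5/XML export, per-plane
    intensity statistics, comparison display operators (gamma, square root,
    pseudo-flat-field division, auto-contrast, linear display mapping), a
    synthetic disk-grid phantom benchmark that quantifies per-object intensity
    amplification, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    parallel,
    rhdf5,
    stats,
    tiff,
    tools,
    utils,
    withr,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
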