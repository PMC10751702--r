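Package: dnatrackmc
Title: Event-by-Event Monte Carlo of Low-Energy Electron Damage to Atomistic DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Track-structure Monte Carlo simulation of low-energy (4-500 eV)
    electron transport through an atomistic B-DNA target in vacuum. Builds a
    procedural B-DNA double helix (straight or condensed) or reads atomic
    coordinates from PDB files, representing every atom as a van der Waals
    sphere annotated with its owning molecule (base, deoxyribose or phosphate
    group), strand and base-pair index. Electrons are transported event by
    event: free flight lengths are sampled from per-molecule cross-section
    tables covering elastic scattering, vibrational and electronic excitation,
    ionization with a simplified Auger multiplicity rule, and dissociative
    electron attachment (DEA). Scored interaction events are converted into
    DNA single- and double-strand breaks with per-channel threshold rules and
    opposite-strand clustering, and summarized as doses (Gy), per-electron
    break yields, per-Gray-per-Dalton yields and interaction-count spectra
    with repeat-based uncertainties.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    bio3d,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
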