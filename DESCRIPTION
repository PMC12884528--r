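Package: plasmovib
Title: Atomistic Fluctuating-Charge Plasmonics and Surface-Enhanced
    Vibrational Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fully atomistic frequency-domain plasmonic response models for
    metal nanoparticles and graphene nanostructures, based on fluctuating
    charges (wFQ) and fluctuating charges and dipoles (wFQFmu).  Each atom of
    the substrate carries a complex charge (and, for noble metals, a complex
    dipole governed by an interband polarizability); Drude conduction between
    nearest neighbours, damped by a Fermi-like quantum-tunneling function,
    yields the plasmonic response from a complex linear system.  Builders for
    Mackay icosahedral clusters and graphene disks, absorption cross-sections
    and plasmon resonance frequencies, a point-multipole molecular vibrational
    surrogate, and SEIRA/SERS intensities with per-mode enhancement factors
    (EF, AEF, MEF) are provided, together with Lorentzian band convolution and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
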