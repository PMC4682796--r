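Package: nanovasc
Title: Vascularized Tumor Growth and Therapy with Vasculature-Targeted
    Nanoparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled multiscale simulation of two-dimensional vascularized
    tumor growth, sprouting angiogenesis, shear-dependent nanoparticle
    adhesion to the tumor vasculature, drug release from vessel-bound
    nanoparticles, and the resulting tumor regression. The tumor is a
    level-set continuum with proliferating, hypoxic and necrotic regions
    classified by a quasi-steady oxygen field; blood flow through the
    pre-existing capillary grid and the angiogenic neovasculature is
    solved as a Poiseuille network; nanoparticle transport follows a
    conservative advection-deposition scheme on the flowing network with
    a size- and shear-dependent adhesion probability; released drug
    diffuses and decays in tissue and suppresses proliferation. Treatment
    efficacy is summarized by the drug potency required to halve tumor
    area (IC50 bisection) across sweeps of nanoparticle diameter,
    vascular affinity and drug diffusivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
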