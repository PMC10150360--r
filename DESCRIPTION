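Package: macrospace
Title: Macrocycle Chemical Space and Oral Bioavailability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the chemical space of macrocyclic drugs
    and drug candidates. Computes a ten-descriptor physicochemical panel
    under physiological (pH 7.0) charge-state counting conventions,
    including custom hydrogen-bond donor/acceptor rules, the Kier
    flexibility index and the AB-MPS multiparameter score. Derives
    oral-versus-parenteral descriptor cutoffs from kernel-density
    intersections, evaluates conjunctive bi-descriptor classifiers with
    confusion-matrix statistics (sensitivity, specificity, GMean,
    accuracy, Cohen's kappa), profiles hydrogen-bond donor chemotypes,
    characterises 3D ligand shape by normalised principal moments of
    inertia, and maps descriptor space by principal component analysis
    with class centroids and confidence ellipses. A synthetic-data
    generator emulates labelled two-class macrocycle populations so the
    whole pipeline is testable without proprietary descriptor software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
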