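Package: growspace
Title: Exhaustive Enumeration of Small-Molecule Chemical Space and
    Scaffold Superstructure Growth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for exploring fragment-based chemical space. Implements
    staged exhaustive enumeration of chemically stable small molecules up to
    a heavy-atom limit (graph generation, saturation, strain filtering,
    unsaturation, heteroatom mutation, functional-group decoration),
    activation of substituents and scaffolds with growing-vector tags for
    five connection mechanisms (single, double, triple bond, ring fusion,
    spiro), combinatorial generation of scaffold superstructures, exponential
    growth-curve fitting and chemical-space size extrapolation, and
    screening-support computations (constrained SMARTS substructure search,
    structural alert filters, reaction-based library enumeration, greedy
    docking-rank leader clustering, and common-core RMSD pose filtering).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
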