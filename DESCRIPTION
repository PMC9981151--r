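Package: allosite
Title: Allosteric Site and Key Allosteric Residue Prediction from
    Evolutionary Couplings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers a Potts (direct coupling analysis) model from a protein
    family multiple sequence alignment by pseudo-likelihood maximization,
    scores candidate surface pockets by the summed evolutionary coupling
    strength of their residues to the orthosteric pocket, and identifies key
    allosteric residues through pairwise t-test significance counts over
    residue coupling profiles. Includes ligand-proximity pocket derivation
    from PDB structures, Shrake-Rupley solvent accessibility, sequence
    reweighting with effective sequence counts, and a Potts Gibbs sampler
    for generating synthetic protein families with planted orthosteric and
    allosteric coupling architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    bio3d,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
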