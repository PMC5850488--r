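Package: torusevol
Title: Evolutionary Modeling of Protein Sequence and Local Structure on the Torus
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A generative probabilistic model of joint protein sequence and
    local-structure evolution for pairs of homologous proteins. Aligned sites
    are modeled by a hidden Markov model whose states couple reversible
    amino-acid and secondary-structure substitution processes with a
    wrapped-normal diffusion on the torus for the backbone dihedral angles
    (phi, psi), together with a site-class jump mechanism that captures
    large, directionally coupled sequence-structure changes. Includes
    statistical alignment under the TKF92 fragment insertion-deletion model,
    stochastic-EM parameter fitting with BIC model selection,
    evolutionary-time estimation, conditional simulation of missing
    observations, and detection of jump-event evolutionary motifs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    seqinr,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
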