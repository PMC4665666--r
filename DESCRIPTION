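Package: rsalogit
Title: Logistic Regression Prediction of Solvent-Accessible Protein Residues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts binary residue solvent accessibility (buried versus
    exposed) for protein chains from sequence- and homology-based
    descriptors.  Per-position Shannon sequence entropies over 20 amino
    acid types (E20) and over six physicochemical classes (E6), fractions
    of strongly hydrophobic (FSHP) and small (FSR) aligned residues, the
    query residue type (AA, dummy-coded with valine baseline), adjacent
    query neighbours (AQN) and an externally supplied disorder propensity
    (LGDP) enter a mixed qualitative/quantitative logistic model fitted by
    maximum likelihood with Wald inference.  Includes parsers for
    BLAST-style tabular alignments with aligned sequence strings, NACCESS
    .rsa files and per-residue CSV tables; bit-score filtering of homolog
    hits; relative-solvent-accessibility thresholding into buried/exposed
    labels; flagging of likely protein-protein interface residues from
    paired single-chain and complex-context accessibilities; a stratified
    two-branch evaluation strategy (optimum versus non-optimum homology,
    oligomer versus non-oligomer, interface-removed); a linear
    least-squares baseline; and a seeded synthetic-fixture generator so
    the whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    seqinr,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
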