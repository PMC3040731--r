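Package: unionscan
Title: Union-Based Multi-Locus Association Testing for Case-Control Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a one-degree-of-freedom union test for joint association
    of common and rare variants in case-control studies. Genotypes are coded
    under dominant or recessive models with respect to the minor allele, logical
    unions are formed over consecutive non-overlapping windows of markers with
    three-valued (Kleene) missing-data semantics, and each union is tested with
    Fisher's exact test on the 2x2 table of union indicators among cases and
    controls. Multiplicity is controlled with a Bonferroni correction over the
    union-size-aware testing burden. Includes a PLINK text PED/MAP reader and
    writer, a genome-wide scan driver, and a simulation engine for type-I error
    and power studies under logistic disease models with correlated markers,
    epistasis, and differential correlation between cases and controls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
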