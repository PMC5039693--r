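Package: tmevol
Title: Ancestral Reconstruction of Tympanic Middle Ear Evolution in Anurans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Dependency-aware coding of the three tympanic middle ear (TME)
    structures of frogs and toads (tympanic membrane, tympanic annulus,
    columella), unordered parsimony ancestral-state reconstruction with
    gain/loss bounds over most-parsimonious reconstructions, two-state Mk
    likelihood with equal-rates (ER) and all-rates-different (ARD) fits
    compared by AIC, and stochastic character mapping under unconstrained,
    root-constrained and Dollo (no-regain) scenarios with a strict
    greater-than-50-percent node-support change-counting rule. Includes
    simulators for Yule trees, binary Markov characters with recorded true
    change histories, and hierarchically dependent structure triples, so the
    whole pipeline is testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
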