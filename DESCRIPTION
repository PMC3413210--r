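Package: clashaudit
Title: All-Atom Model Building and Nonbonded-Contact Auditing for Protein Structures
Version: 0.1.0
Authors@R: person("clashaudit", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds all-atom protein models from united-atom crystal structures
    (riding-hydrogen placement from ideal geometry plus rule-based discrete
    optimization of the variable hydrogen-bond network: hydroxyl, sulfhydryl and
    phenolic torsions, Asp/Glu and His protonation and tautomeric states,
    Asn/Gln/His flips, and water orientations) and audits models for nonbonded
    close contacts ("clashes" at a center-to-center distance of at most 0.8
    times the summed van der Waals radii, "severe clashes" at 0.7 times) with
    Rowland-Taylor radii, hydrogen-bond exclusion rules, an alternative
    Richardson-system overlap mode, and summary molecular-geometry statistics
    (bond/angle r.m.s.d. and r.m.s. Z scores against Engh-Huber-style targets,
    side-chain planarity r.m.s.d., omega-angle deviation), reported per 100
    residues. Includes a deterministic synthetic-structure generator for
    fixtures with exact known geometry and engineered contacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
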