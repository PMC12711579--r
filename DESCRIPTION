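Package: meioco
Title: Meiotic Crossover Interference Analysis from F2 Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing meiotic crossover (CO) interference from
    marker-level F2 genotype tables. Calls crossovers from parental/heterozygous
    genotype transitions, extracts cis-double-crossovers (parental-heterozygous-
    parental genotype triples), builds resampled random-placement null distance
    distributions, fits gamma distributions to inter-crossover distances, runs
    permutation tests for positional bias of short double crossovers, computes
    coefficient-of-coincidence (CoC) profiles and windowed crossover landscapes,
    and compares genotype groups with rank-based tests. Includes a synthetic
    meiosis simulator (gamma-renewal, Poisson and clustered crossover placement
    with configurable interference) that produces F2 populations with known
    crossover truth, so every analysis stage can be validated without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    fitdistrplus,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
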