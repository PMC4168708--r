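Package: xmb
Title: X-Phased Multibridging Assembly of Noisy Shotgun Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De novo assembly toolkit built around repeat-aware overlap
    detection and polymorphism phasing. Provides a parametric repeat-bearing
    genome simulator, a shotgun read simulator with substitution or indel
    noise, exact and flanked repeat statistics by suffix-array enumeration,
    the repeat-aware (RA) overlap rule with its Kullback-Leibler anchor
    calibration, three assemblers of increasing data efficiency (greedy,
    multibridging over a K-mer-cluster De Bruijn graph, and X-phased
    multibridging which phases polymorphism across repeat copies), Monte
    Carlo calibration of the phasing error components, information-requirement
    curves for read length and coverage, and assembly evaluation against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
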