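Package: strmps
Title: Sequence-Based STR Genotyping, Quality Control and Databasing
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for evaluating massively parallel sequencing (MPS) of
    forensic short tandem repeat (STR) panels for DNA databasing. Implements
    read-count thresholded allele calling, repeat-unit and capillary
    electrophoresis (CE) equivalent allele designation including flanking
    indel micro-variant arithmetic, isometric (same-length, different
    sequence) allele detection, profile-level quality control (relative
    marker performance, heterozygote balance, length-defined stutter ratios
    with read-depth categories), CE versus MPS concordance classification,
    and forensic population-genetic parameters with exact Hardy-Weinberg
    testing. A synthetic-cohort simulator generates paired MPS read-count
    and CE genotype datasets with the statistical structure the analyses
    assume, plus deterministic scenario builders for worked examples.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
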