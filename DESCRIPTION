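Package: pangraphr
Title: Pangenome Graph Analytics for Haplotype-Resolved Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing pangenome graphs built from multiple
    haplotype-resolved assemblies: GFA v1.0/1.1 input and output with
    PanSN-named haplotype paths, path-sequence reconstruction and
    graph/path length accounting, bubble-based cataloguing of SNVs,
    indels and structural variants (including nested variation) from
    haplotype paths, greedy attribution of accessory sequence to
    samples, path-coverage duplication detection, genotyping of complex
    structural variants from graph alignments by diagnostic-edge read
    support with exact binomial tests, short-read simulation with a
    configurable error model and mapping-accuracy curves, reference-bias
    estimation at putative heterozygous sites from linear alignments,
    and genotype-set concordance between variant-calling pipelines.
    Ships a seeded synthetic-pangenome generator with a known truth set
    so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    Rsamtools,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
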