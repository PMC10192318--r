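Package: myxoloss
Title: Decontamination and Apoptotic-Gene-Loss Analysis for Parasitic Cnidarian Assemblies
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing gene loss in parasitic cnidarians (Myxozoa)
    from mixed genome and transcriptome assemblies. Implements host-genome
    contig exclusion from best-hit identity and e-value thresholds, three-way
    contig classification (target clade / contamination / not clear) from
    dual-database best-hit e-value and bit-score fold rules, GC-content
    rescue of ambiguous contigs with an automatic bimodal cutoff estimator,
    six-frame open-reading-frame extraction with a minimum-length floor,
    construction of taxon-by-actor presence/absence matrices with a
    parasitism loss-gradient summary, and in-frame stop-codon (pseudogene)
    scanning of aligned candidate genes split by lineage-specific insertions.
    Includes a synthetic-data generator with ground-truth labels for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
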