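Package: homeosplitr
Title: Disentangling Homeologous Gene Copies in Allopolyploid
    Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects de novo assembled contigs that merge the two
    homeologous copies of a gene in an allo-tetraploid and splits each
    into two sequences by maximum likelihood under a per-accession
    differential-expression model of nucleotide counts. Provides
    reading and writing of per-accession nucleotide-count (ALR) files,
    conversion of SAM/BAM read mappings into counts, screening for
    sites with an excess of heterozygous accessions, an exhaustive and
    a heuristic search over candidate splits scored by a two-binomial
    likelihood, genotype calling with per-site Fis fixation indices to
    classify SNPs as homologous or homeologous, a diffSym benchmark of
    splits against diploid reference consensus sequences, and a fully
    seeded simulator of allo-tetraploid RNA-seq count data with known
    homeolog truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
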