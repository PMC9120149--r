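Package: paralintron
Title: Tracing Spliceosomal Intron Positions Through Ancient Gene Duplications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the early evolution of spliceosomal introns
    through gene duplications. Maps intron positions from genome annotations
    (GFF3 + FASTA) onto protein multiple alignments with codon phase,
    builds species-by-position intron presence/absence tables, reconstructs
    ancestral intron content on a rooted species tree with a
    maximum-likelihood branch-specific gain/loss model (Felsenstein pruning,
    posterior node probabilities, observability correction), calls introns
    present in the last eukaryotic common ancestor (LECA), detects intron
    positions shared between paralogous orthogroups in merged family
    alignments, infers pre-duplication introns on duplication-annotated gene
    trees by Dollo parsimony, and provides the accompanying statistical
    toolkit (chi-squared, Fisher exact, Kolmogorov-Smirnov,
    Benjamini-Hochberg FDR, Wilson score intervals, intron phase
    distributions). A forward simulator of intron evolution through a
    duplicating stem lineage and a post-LECA species tree generates fully
    ground-truthed synthetic datasets (genomes, annotations, alignments,
    trees) so every pipeline stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
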