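Package: ssrforge
Title: Microsatellite Marker Development for Large Repetitive Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for developing codominant microsatellite (SSR) markers
    from whole-genome shotgun data of species with large, highly repetitive
    genomes. Reconstructs contig fragments by merging overlapping paired-end
    reads, mines perfect 2-6 bp tandem repeats with canonical strand/rotation
    motif classes, applies a seven-criterion candidate filter cascade
    (compound repeats, repeat-element hits, multi-mapping, coverage and
    length, genome copy number, motif class, GC content) and exports Primer3
    input. Characterizes genotyped markers with the standard codominant-locus
    statistics (allele counts, observed and unbiased expected heterozygosity,
    inbreeding coefficient, exact Hardy-Weinberg tests with sequential
    Bonferroni correction, null-allele frequency estimators, polymorphic
    information content, probability of identity) and performs individual
    level proportion-of-shared-alleles distance analysis with bootstrapped
    neighbor-joining trees. Includes seeded simulators for contigs with
    planted SSRs, paired reads and multi-population diploid genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
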