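Package: eruptpop
Title: Pre- and Post-Eruption Population Genomics of Bottlenecked Rodent Populations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Heterochronous population-genomic comparison of populations sampled
    before and after an abrupt demographic decline, built around diploid SNP
    genotype matrices read from VCF. Implements neutrality site filters
    (Hardy-Weinberg exact test, an FDIST-style FST-outlier scan), diversity
    statistics (observed heterozygosity, per-site Watterson's theta and
    nucleotide diversity, Tajima's D in sliding windows, folded site frequency
    spectra, method-of-moments inbreeding coefficients, private and shared
    alleles), differentiation statistics (Weir-Cockerham FST, genotype PCA,
    EM admixture), the resampling designs used to compare unequal samples
    (equalized bootstrap over individuals, locus subsampling, one-per-burrow
    and sex partitions, the loci-count versus standard-deviation curve), and
    demographic-signal analyses (mismatch distributions, Harpending's
    raggedness index, a random-survivorship drift simulation). A forward
    Wright-Fisher simulator generates study-structured synthetic datasets,
    including presets emulating two tuco-tuco (Ctenomys) populations sampled
    across a volcanic eruption.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
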