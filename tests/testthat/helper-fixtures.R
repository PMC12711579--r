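# Shared fixtures for the test suite. Everything is built in code; no files.

# one 10-Mb chromosome, centromere at 5 Mb, pericentromere 4-6 Mb
tiny_genome <- function() {
  genome_map("Chr1", 10e6, 5e6, 4e6, 6e6)
}

# five 30-Mb chromosomes mirroring the synthetic study genome
study_genome <- function(n_chrom = 5) {
  synthetic_genome(n_chrom = n_chrom, chrom_length = 30e6, peri_fraction = 0.2)
}

# a hand-built segment table for one individual/chromosome
seg_table <- function(genotype, first, last, support = NULL,
                      individual = 1L, chrom = "Chr1") {
  data.frame(individual = individual, chrom = chrom, genotype = genotype,
             first = first, last = last,
             support = support %||% rep(2L, length(genotype)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force caller: one event per adjacent pair of differing marker
# genotypes (the min_support = 1 oracle)
brute_force_events <- function(positions, genotypes) {
  keep <- !is.na(genotypes)
  positions <- positions[keep]; genotypes <- genotypes[keep]
  if (length(positions) < 2L) return(data.frame(left = numeric(0),
                                                right = numeric(0)))
  d <- which(genotypes[-1] != genotypes[-length(genotypes)])
  data.frame(left = positions[d], right = positions[d + 1L])
}

# per-marker genotype by direct parity lookup (oracle for genotype_markers)
brute_force_genotype <- function(maternal, paternal, positions) {
  allele <- function(g, x) {
    a <- if (g$founder == "P1") 0L else 1L
    (a + sum(g$co < x)) %% 2L
  }
  vapply(positions, function(x) {
    c("AA", "AB", "BB")[allele(maternal, x) + allele(paternal, x) + 1L]
  }, character(1))
}
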