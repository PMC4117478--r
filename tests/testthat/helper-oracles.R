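# Independent oracles used across tests. These deliberately avoid the
# package's formula class: masses are summed atom by atom from a literal
# table, and overlaps/alignments are brute-force scans.

oracle_atomic <- c(C = 12.0, H = 1.0078250319, N = 14.0030740,
                   O = 15.9949146, P = 30.97376151)

# atom-count vectors typed out per building block
oracle_atoms <- list(
  A = c(C = 10, H = 13, N = 5, O = 4, P = 0),
  C = c(C = 9,  H = 13, N = 3, O = 5, P = 0),
  G = c(C = 10, H = 13, N = 5, O = 5, P = 0),
  U = c(C = 9,  H = 12, N = 2, O = 6, P = 0),
  CH2 = c(C = 1, H = 2, N = 0, O = 0, P = 0),
  H2O = c(C = 0, H = 2, N = 0, O = 1, P = 0),
  PPP = c(C = 0, H = 5, N = 0, O = 10, P = 3)
)

# brute-force [M-H]- anion mass for a cap of two bases and k total methyls
oracle_cap_anion_mass <- function(base1, base2, n_methyls) {
  atoms <- oracle_atoms[[base1]] + oracle_atoms[[base2]] +
    n_methyls * oracle_atoms$CH2 + oracle_atoms$PPP - 2 * oracle_atoms$H2O
  sum(atoms * oracle_atomic[names(atoms)]) - 1.00727646
}

# base pair and total methyl count for each assigned published structure
oracle_assigned_caps <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
label       base1 base2 methyls
3mGpppAm    G     A     4
3mGpppmAm   G     A     5
2mGpppAm    G     A     3
mGpppmAm    G     A     3
3mGpppA     G     A     3
3mGpppCm    G     C     4
3mGpppGm    G     G     4
3mGpppUm    G     U     4
mGpppGm     G     G     2
mGpppAm     G     A     2
mGpppCm     G     C     2
mGpppUm     G     U     2
mGpppG      G     G     1
mGpppA      G     A     1
GpppCm      G     C     1
GpppGm      G     G     1
GpppG       G     G     0
GpppA       G     A     0
GpppmAm     G     A     2
")
}

# brute-force max-priority annotation of one interval against a feature table
oracle_annotate_one <- function(chrom, start, end, strand, features,
                                ignore_strand = FALSE) {
  prio <- c("unknown", "intron", "exon", "miRNA", "snRNA", "snoRNA", "tRNA")
  ov <- features$chrom == chrom &
    features$start < end & start < features$end &
    (ignore_strand | features$strand == strand)
  if (!any(ov)) return("unknown")
  prio[max(match(features$biotype[ov], prio))]
}

# naive quadratic substring scan on both strands, 0-based half-open
oracle_align_one <- function(seq, genome_named) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  out <- NULL
  for (chrom in names(genome_named)) {
    g <- genome_named[[chrom]]
    n <- nchar(g); k <- nchar(seq)
    if (k == 0 || k > n) next
    for (i in 1:(n - k + 1)) {
      window <- substr(g, i, i + k - 1)
      if (window == seq)
        out <- rbind(out, data.frame(chrom = chrom, start = i - 1,
                                     end = i - 1 + k, strand = "+"))
      if (window == rc)
        out <- rbind(out, data.frame(chrom = chrom, start = i - 1,
                                     end = i - 1 + k, strand = "-"))
    }
  }
  out
}

random_features <- function(n, chroms = c("chr1", "chr2"), span = 50000) {
  starts <- sample.int(span - 300, n, replace = TRUE)
  data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    start = starts,
    end = starts + sample(20:250, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    biotype = sample(c("intron", "exon", "miRNA", "snRNA", "snoRNA", "tRNA"),
                     n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
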