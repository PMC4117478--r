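# Priority-resolved annotation, length bins, composition, site profiles,
# cluster enrichment.

test_that("annotation picks the highest-priority overlapping biotype", {
  feats <- data.frame(
    chrom = "chr1", start = c(100, 120, 100, 500, 510),
    end = c(200, 180, 150, 600, 590), strand = "+",
    biotype = c("exon", "snoRNA", "intron", "intron", "tRNA"),
    stringsAsFactors = FALSE)
  aln <- data.frame(chrom = "chr1", start = c(130, 300, 520, 110),
                    end = c(140, 320, 530, 115), strand = "+",
                    stringsAsFactors = FALSE)
  # the last tag [110,115) precedes the snoRNA at 120: exon beats intron
  expect_equal(resolve_annotation(aln, feats),
               c("snoRNA", "unknown", "tRNA", "exon"))
  # a tag over intron + exon + tRNA resolves to tRNA
  feats2 <- data.frame(chrom = "chr1", start = 0, end = 100, strand = "+",
                       biotype = c("intron", "exon", "tRNA"),
                       stringsAsFactors = FALSE)
  expect_equal(resolve_annotation(
    data.frame(chrom = "chr1", start = 10, end = 20, strand = "+"), feats2),
    "tRNA")
})

test_that("annotation is strand-aware by default, strand-blind on request", {
  feats <- data.frame(chrom = "chr1", start = 100, end = 200, strand = "+",
                      biotype = "miRNA", stringsAsFactors = FALSE)
  anti <- data.frame(chrom = "chr1", start = 150, end = 170, strand = "-",
                     stringsAsFactors = FALSE)
  expect_equal(resolve_annotation(anti, feats), "unknown")
  expect_equal(resolve_annotation(anti, feats, ignore_strand = TRUE), "miRNA")
})

test_that("annotation rejects biotypes outside the vocabulary", {
  feats <- data.frame(chrom = "chr1", start = 1, end = 10, strand = "+",
                      biotype = "lncRNA", stringsAsFactors = FALSE)
  aln <- data.frame(chrom = "chr1", start = 2, end = 5, strand = "+",
                    stringsAsFactors = FALSE)
  expect_error(resolve_annotation(aln, feats), "vocabulary")
})

test_that("resolution equals the brute-force scan on random instances", {
  set.seed(21)
  feats <- random_features(500)
  tag_start <- sample.int(50000, 200)
  aln <- data.frame(chrom = sample(c("chr1", "chr2"), 200, replace = TRUE),
                    start = tag_start,
                    end = tag_start + sample(18:60, 200, replace = TRUE),
                    strand = sample(c("+", "-"), 200, replace = TRUE),
                    stringsAsFactors = FALSE)
  got <- resolve_annotation(aln, feats)
  want <- vapply(seq_len(nrow(aln)), function(i)
    oracle_annotate_one(aln$chrom[i], aln$start[i], aln$end[i],
                        aln$strand[i], feats), "")
  expect_equal(got, want)
  got_ns <- resolve_annotation(aln, feats, ignore_strand = TRUE)
  want_ns <- vapply(seq_len(nrow(aln)), function(i)
    oracle_annotate_one(aln$chrom[i], aln$start[i], aln$end[i],
                        aln$strand[i], feats, ignore_strand = TRUE), "")
  expect_equal(got_ns, want_ns)
})

test_that("length bins partition 0..200 and map the documented boundaries", {
  expect_equal(as.character(length_bin(c(27, 50, 100, 101, 18, 19, 0))),
               c("19-29", "30-50", "51-100", "101-200", "0-18", "19-29",
                 "0-18"))
  expect_equal(as.character(length_bin(NA)), "unmeasured")
  expect_equal(as.character(length_bin(250)), ">200")
  expect_error(length_bin(-1), "negative")
  # every length 0..200 falls in exactly one of the five ranges
  bins <- length_bin(0:200)
  expect_false(anyNA(bins))
  expect_equal(as.integer(table(bins)[c("0-18", "19-29", "30-50", "51-100",
                                        "101-200")]),
               c(19L, 11L, 21L, 50L, 100L))
})

test_that("composition fractions sum to one within every group", {
  set.seed(31)
  tags <- data.frame(
    library_id = sample(c("L1", "L2"), 300, replace = TRUE),
    length_bin = sample(c("0-18", "19-29", "30-50"), 300, replace = TRUE),
    biotype = sample(biotype_priority(), 300, replace = TRUE),
    stringsAsFactors = FALSE)
  comp <- composition_table(tags)
  sums <- tapply(comp$fraction, paste(comp$library_id, comp$length_bin), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(sum(comp$count), 300L)
  # degenerate inputs
  expect_equal(nrow(composition_table(tags[0, ])), 0L)
  allu <- composition_table(data.frame(biotype = rep("unknown", 5)),
                            group_by = character())
  expect_equal(allu$fraction, 1)
})

test_that("site windows count 5' ends, half-open, strand of the tag", {
  sites <- data.frame(chrom = "chr1", position = c(1000, 5000),
                      strand = c("+", "+"), name = c("tssA", "tssB"),
                      stringsAsFactors = FALSE)
  # tags planted inside the [site-50, site+50) windows
  aln <- data.frame(chrom = "chr1",
                    start = c(960, 1049, 950, 4990, 5049, 5050),
                    end = c(980, 1070, 970, 5010, 5070, 5070),
                    strand = "+", stringsAsFactors = FALSE)
  prof <- site_window_profile(aln, sites, window = 100)
  expect_equal(prof$per_site$count, c(3L, 2L))   # 5050 is outside [4950,5050)
  expect_equal(prof$fraction_in_window, 5 / 6)
  # a minus-strand tag is counted by its right end
  minus <- data.frame(chrom = "chr1", start = 900, end = 1000, strand = "-",
                      stringsAsFactors = FALSE)
  expect_equal(site_window_profile(minus, sites, 100)$per_site$count[1], 1L)
  # boundary: a 5' end exactly at the site falls in every covering window
  at <- data.frame(chrom = "chr1", start = 1000, end = 1010, strand = "+",
                   stringsAsFactors = FALSE)
  expect_equal(site_window_profile(at, sites, 100)$per_site$count, c(1L, 0L))
  expect_equal(site_window_profile(aln, sites[0, ], 100)$n_in_window, 0L)
  expect_error(site_window_profile(aln, sites, 0), "positive")
})

test_that("cluster enrichment normalizes to CPM and uses the pseudocount", {
  # treatment: 8 of 10 tags in the cluster; control: 1 of 10
  mk <- function(n_in, n_out) {
    data.frame(chrom = "chr1",
               start = c(rep(100, n_in), seq(5000, by = 200,
                                             length.out = n_out)),
               end = c(rep(130, n_in), seq(5030, by = 200,
                                           length.out = n_out)),
               strand = "+", stringsAsFactors = FALSE)
  }
  libs <- list(trt = mk(8, 2), ctl = mk(1, 9))
  enr <- cluster_and_enrich(libs, "trt", "ctl", pseudocount = 1)
  row <- enr[enr$start == 100, ]
  cpm_t <- 8 / 10 * 1e6; cpm_c <- 1 / 10 * 1e6
  expect_equal(row$cpm_trt, cpm_t)
  expect_equal(row$cpm_ctl, cpm_c)
  expect_equal(row$fold_change_log2, log2((cpm_t + 1) / (cpm_c + 1)))
  expect_equal(row$mean_expression, (cpm_t + cpm_c) / 2)
  # identical counts give zero fold change
  same <- cluster_and_enrich(list(a = mk(4, 0), b = mk(4, 0)), "a", "b")
  expect_equal(same$fold_change_log2, 0)
  # swapping treatment and control negates the fold change exactly
  swapped <- cluster_and_enrich(libs, "ctl", "trt", pseudocount = 1)
  expect_equal(swapped$fold_change_log2[order(swapped$start)],
               -enr$fold_change_log2[order(enr$start)])
  expect_error(cluster_and_enrich(list(), "a", "b"), "empty")
})
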