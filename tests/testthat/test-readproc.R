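# Adapter clipping, rRNA dusting, the toy aligner and CAGE truncation.

adapter <- default_adapter()

test_that("adapter clipping recovers insert lengths", {
  set.seed(11)
  insert <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                  collapse = "")
  read <- paste0(insert, adapter,
                 paste(sample(c("A", "C", "G", "T"), 53, replace = TRUE),
                       collapse = ""))
  tag <- clip_adapter(read)
  expect_equal(tag$inferred_length, 30L)
  expect_equal(tag$sequence, insert)
  expect_true(tag$measured)
})

test_that("inference fails exactly when fewer than min_match adapter bases fit", {
  r92 <- paste0(strrep("A", 92), substr(adapter, 1, 8))
  r93 <- paste0(strrep("A", 93), substr(adapter, 1, 7))
  expect_equal(clip_adapter(r92)$inferred_length, 92L)
  expect_false(clip_adapter(r93)$measured)
  expect_true(is.na(clip_adapter(r93)$inferred_length))
  # unmeasured tags carry the whole read through
  expect_equal(nchar(clip_adapter(r93)$sequence), 100L)
})

test_that("adapter-only reads clip to an empty, flagged insert", {
  tag <- clip_adapter(adapter)
  expect_equal(tag$inferred_length, 0L)
  expect_true(tag$empty)
})

test_that("clipping validates its inputs", {
  expect_error(clip_adapter(""), "empty read")
  expect_error(clip_adapter("ACGT", min_match = 18), "adapter length")
  expect_error(clip_adapter("ACGT", min_match = 0), "adapter length")
})

test_that("length bookkeeping: insert + matched adapter + tail = read length", {
  set.seed(7)
  for (rep_i in 1:25) {
    ins_len <- sample(0:60, 1)
    tail_len <- sample(0:20, 1)
    insert <- paste(sample(c("A", "C", "T"), ins_len, replace = TRUE),
                    collapse = "")  # no G: cannot shadow the adapter start
    tail <- paste(sample(c("A", "C", "T"), tail_len, replace = TRUE),
                  collapse = "")
    read <- paste0(insert, adapter, tail)
    tag <- clip_adapter(read)
    expect_equal(tag$inferred_length + nchar(adapter) + tail_len, nchar(read))
  }
})

test_that("detectability bound on a short read: inferable lengths are 0..R-m", {
  R <- 40L; m <- 8L
  measurable <- vapply(0:R, function(k) {
    avail <- R - k
    read <- paste0(strrep("T", k), substr(adapter, 1, min(avail, 17)))
    read <- substr(paste0(read, strrep("T", R)), 1, R)
    clip_adapter(read, min_match = m)$measured
  }, TRUE)
  expect_equal(which(measurable) - 1L, 0:(R - m))
  expect_equal(min(which(!measurable)) - 1L, R - m + 1L)
})

test_that("rRNA dusting removes exact substrings on either strand, idempotently", {
  set.seed(3)
  ref <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
  verbatim <- substr(ref, 101, 130)
  mismatched <- paste0("A", substr(verbatim, 2, 30))
  if (mismatched == verbatim) mismatched <- paste0("C", substr(verbatim, 2, 30))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(ref, 201, 240))))
  unrelated <- strrep("AC", 15)
  tags <- data.frame(read_id = paste0("t", 1:4),
                     sequence = c(verbatim, mismatched, rc, unrelated),
                     stringsAsFactors = FALSE)
  res <- rrna_filter(tags, ref)
  expect_setequal(res$removed$read_id, c("t1", "t3"))
  expect_setequal(res$kept$read_id, c("t2", "t4"))
  # second pass removes nothing
  res2 <- rrna_filter(res$kept, ref)
  expect_equal(nrow(res2$removed), 0L)
  expect_identical(res2$kept, res$kept)
  expect_error(rrna_filter(tags, ""), "empty reference")
})

test_that("toy aligner reports all exact hits with uniqueness flags", {
  set.seed(5)
  g <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
             collapse = "")
  once <- substr(g, 501, 525)
  twice <- substr(g, 1001, 1020)
  g2 <- paste0(g, twice)   # plant a second copy at the end
  genome <- c(chr1 = g2)
  tags <- data.frame(read_id = c("u", "m", "x"),
                     sequence = c(once, twice, strrep("ACGT", 8)),
                     stringsAsFactors = FALSE)
  aln <- toy_align(tags, genome)
  u <- aln[aln$read_id == "u", ]
  expect_equal(nrow(u), 1L)
  expect_true(u$unique)
  expect_equal(u$start, 500L)       # 0-based
  expect_equal(u$end, 525L)         # half-open
  m <- aln[aln$read_id == "m", ]
  expect_equal(nrow(m), 2L)
  expect_false(any(m$unique))
  expect_false("x" %in% aln$read_id)
})

test_that("toy aligner equals a naive quadratic scan, both strands", {
  set.seed(9)
  genome <- c(chrA = paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                           collapse = ""))
  seqs <- c(substr(genome[[1]], 300, 320),
            as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(substr(genome[[1]], 700, 730)))),
            strrep("TTTTAAAA", 4))
  for (s in seqs) {
    mine <- toy_align(data.frame(read_id = "q", sequence = s,
                                 stringsAsFactors = FALSE), genome)
    ref <- oracle_align_one(s, genome)
    if (is.null(ref)) {
      expect_equal(nrow(mine), 0L)
    } else {
      expect_equal(mine[order(mine$start, mine$strand),
                        c("chrom", "start", "end", "strand")],
                   ref[order(ref$start, ref$strand), ],
                   ignore_attr = TRUE)
    }
  }
})

test_that("CAGE truncation cuts to the 5'-most bases and no further", {
  expect_equal(nchar(cage_truncate(strrep("A", 80))), 27L)
  expect_equal(cage_truncate("ACGTACGTACGTACGTACGT"), "ACGTACGTACGTACGTACGT")
  expect_equal(nchar(cage_truncate(strrep("G", 27))), 27L)
  df <- data.frame(sequence = strrep("A", 80), inferred_length = 80L)
  out <- cage_truncate(df)
  expect_equal(out$inferred_length, 27L)
  expect_equal(nchar(out$sequence), 27L)
})
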