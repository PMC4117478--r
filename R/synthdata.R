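# Seeded generators for every input the pipeline consumes: synthetic genome
# and annotation, four short-RNA library types, LC-MS mass observations and
# TLC spot tables, each with ground truth for parameter-recovery tests.

.BIOTYPES <- c("intron", "exon", "miRNA", "snRNA", "snoRNA", "tRNA")

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators with the default
#' study conditions: a 100-kb random genome, 20 planted features per
#' biotype, 100-nt reads with the 17-nt 3' adapter, a 27-nt CAGE truncation,
#' 5% rRNA contamination, 1.5-ppm mass noise, and three TLC replicates.
#' Library biotype mixtures emulate the four library chemistries: an
#' sRNA library dominated by 20-24-nt miRNAs, a capped sRNA library with a
#' broader snoRNA/tRNA-rich mixture, a CAGE library rich in snRNA with long
#' inserts (truncated enzymatically downstream), and a methylguanosine-cap
#' immunoprecipitation library strongly enriched for snRNA fragments against
#' a background control.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param genome_length Genome size in nt.
#' @param features_per_biotype Planted feature count per biotype.
#' @param read_length Read length in nt.
#' @param adapter 3' adapter sequence.
#' @param cage_tag_length EcoP15I truncation length in nt.
#' @param rrna_fraction Fraction of reads drawn from the synthetic rDNA
#'   segment.
#' @param rdna_length Length of the designated rDNA segment.
#' @param reads_per_library Default library depth.
#' @param mass_noise_ppm SD of the relative mass error, in ppm.
#' @param tlc_replicates TLC replicate plates per fraction.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 100000L,
                       features_per_biotype = 20L, read_length = 100L,
                       adapter = default_adapter(), cage_tag_length = 27L,
                       rrna_fraction = 0.05, rdna_length = 2000L,
                       reads_per_library = 1500L, mass_noise_ppm = 1.5,
                       tlc_replicates = 3L) {
  cfg <- list(
    seed = as.integer(seed),
    genome_length = as.integer(genome_length),
    features_per_biotype = as.integer(features_per_biotype),
    read_length = as.integer(read_length),
    adapter = adapter,
    cage_tag_length = as.integer(cage_tag_length),
    rrna_fraction = rrna_fraction,
    rdna_length = as.integer(rdna_length),
    reads_per_library = as.integer(reads_per_library),
    mass_noise_ppm = mass_noise_ppm,
    tlc_replicates = as.integer(tlc_replicates),
    # feature length ranges (nt) per biotype
    feature_length = list(
      intron = c(150L, 400L), exon = c(80L, 200L), miRNA = c(22L, 28L),
      snRNA = c(100L, 160L), snoRNA = c(60L, 150L), tRNA = c(70L, 90L)),
    # per-library biotype mixture weights (sum to 1)
    mixtures = list(
      sRNA        = c(intron = 0.08, exon = 0.12, miRNA = 0.60,
                      snRNA = 0.05, snoRNA = 0.08, tRNA = 0.07),
      capped_sRNA = c(intron = 0.08, exon = 0.15, miRNA = 0.25,
                      snRNA = 0.10, snoRNA = 0.30, tRNA = 0.12),
      sRNA_CAGE   = c(intron = 0.10, exon = 0.20, miRNA = 0.05,
                      snRNA = 0.35, snoRNA = 0.15, tRNA = 0.15),
      IP_K121     = c(intron = 0.05, exon = 0.10, miRNA = 0.05,
                      snRNA = 0.55, snoRNA = 0.15, tRNA = 0.10),
      IP_control  = c(intron = 0.20, exon = 0.25, miRNA = 0.30,
                      snRNA = 0.05, snoRNA = 0.10, tRNA = 0.10)),
    # per-biotype insert-length distributions: truncated normal
    # (mean, sd, min, max); the paper gives ranges, not distributions
    insert_length = list(
      intron = c(35, 10, 18, 80), exon = c(30, 10, 15, 80),
      miRNA = c(22, 1.2, 20, 24), snRNA = c(40, 8, 25, 80),
      snoRNA = c(38, 10, 20, 80), tRNA = c(34, 8, 20, 60)),
    # CAGE inserts are long 5' tags; cleaved to cage_tag_length downstream
    cage_insert_length = c(60, 15, 30, 95)
  )
  for (w in cfg$mixtures)
    stopifnot(abs(sum(w) - 1) < 1e-9, all(w >= 0))
  class(cfg) <- "sim_config"
  cfg
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.rtruncnorm_int <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo - 0.5, mean, sd),
                    stats::pnorm(hi + 0.5, mean, sd))
  pmin(pmax(as.integer(round(stats::qnorm(u, mean, sd))), lo), hi)
}

#' Generate a synthetic genome with planted annotation
#'
#' Builds a random genome, reserves a synthetic rDNA segment, and plants
#' non-overlapping features per biotype with random strands. Each feature's
#' sequence is verified to occur exactly once in the genome so the toy
#' aligner is unambiguous.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_genome`: `genome` (named character, one
#'   chromosome), `features` (data frame `chrom`, `start`, `end` 0-based
#'   half-open, `strand`, `biotype`, `name`), `rdna` (the rDNA segment
#'   sequence), `rdna_interval`.
#' @export
gen_genome_and_annotation <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_feat <- config$features_per_biotype * length(.BIOTYPES)
  lens <- unlist(lapply(.BIOTYPES, function(b) {
    r <- config$feature_length[[b]]
    sample(r[1]:r[2], config$features_per_biotype, replace = TRUE)
  }))
  need <- sum(lens) + config$rdna_length
  if (need > 0.5 * config$genome_length)
    stop("genome too small for the requested features")
  genome <- .rand_dna(config$genome_length)

  # reserve intervals greedily without overlap (rDNA segment first)
  taken <- matrix(numeric(0), ncol = 2)
  place <- function(len) {
    for (try in 1:2000) {
      s <- sample.int(config$genome_length - len, 1L)  # 1-based start
      e <- s + len - 1L
      if (nrow(taken) == 0 || all(e < taken[, 1] | s > taken[, 2])) {
        taken <<- rbind(taken, c(s, e))
        return(c(s, e))
      }
    }
    stop("genome too small for the requested features")
  }
  rd <- place(config$rdna_length)
  iv <- if (n_feat > 0) t(vapply(lens, place, numeric(2)))
        else matrix(numeric(0), ncol = 2)
  features <- data.frame(
    chrom = rep("chr1", n_feat),
    start = as.integer(iv[, 1]) - 1L,
    end = as.integer(iv[, 2]),
    strand = sample(c("+", "-"), n_feat, replace = TRUE),
    biotype = rep(.BIOTYPES, each = config$features_per_biotype),
    name = if (n_feat > 0)
      paste0(rep(.BIOTYPES, each = config$features_per_biotype), "_",
             sequence(rep(config$features_per_biotype, length(.BIOTYPES))))
      else character(0),
    stringsAsFactors = FALSE
  )
  feat_seq <- if (n_feat > 0)
    substring(genome, features$start + 1L, features$end) else character(0)
  n_hits <- vapply(feat_seq, function(s) {
    m <- gregexpr(s, genome, fixed = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }, 0L, USE.NAMES = FALSE)
  if (any(n_hits != 1L)) stop("planted feature sequences are not unique")
  out <- list(
    genome = c(chr1 = genome),
    features = features,
    rdna = substring(genome, rd[1], rd[2]),
    rdna_interval = c(start = rd[1] - 1L, end = rd[2])
  )
  class(out) <- "sim_genome"
  out
}

# 5'-anchored insert from a feature (strand-aware), jittered 0-4 nt.
.draw_insert <- function(genome, feat, len, jitter) {
  flen <- feat$end - feat$start
  len <- min(len, flen - jitter)
  if (feat$strand == "+") {
    s <- feat$start + jitter
    substring(genome, s + 1L, s + len)
  } else {
    e <- feat$end - jitter
    .revcomp(substring(genome, e - len + 1L, e))
  }
}

#' Generate a synthetic sequencing library
#'
#' Draws each read's source biotype from the library-type mixture, an
#' insert length from that biotype's truncated-normal distribution (CAGE
#' libraries use long 5' inserts instead, emulating pre-cleavage tags),
#' takes a 5'-anchored subsequence of a planted feature, appends the 3'
#' adapter and random fill up to the read length, and injects rRNA
#' contaminant reads drawn from the synthetic rDNA segment at the
#' configured fraction.
#'
#' @param config A [sim_config()].
#' @param sim A `sim_genome` from [gen_genome_and_annotation()].
#' @param library_type One of `"sRNA"`, `"capped_sRNA"`, `"sRNA_CAGE"`,
#'   `"IP_K121"`, `"IP_control"`.
#' @param n_reads Library depth (default `config$reads_per_library`).
#' @param library_id Library identifier (defaults to the type).
#' @param seed_offset Added to the config seed so multiple libraries from
#'   one config differ (each library type gets a distinct default offset).
#' @return A list: `reads` (data frame `read_id`, `read`, `library_id`,
#'   `library_type`) and `truth` (per-read `biotype`, `feature`,
#'   `insert_length`, `is_rrna`).
#' @export
gen_library <- function(config, sim, library_type,
                        n_reads = config$reads_per_library,
                        library_id = library_type, seed_offset = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(sim, "sim_genome"))
  types <- names(config$mixtures)
  if (!library_type %in% types) stop("unknown library type: ", library_type)
  if (is.null(seed_offset)) seed_offset <- match(library_type, types) * 1000L
  set.seed(config$seed + seed_offset)
  genome <- sim$genome[[1]]
  weights <- config$mixtures[[library_type]]
  n_rrna <- stats::rbinom(1L, n_reads, config$rrna_fraction)
  n_src <- n_reads - n_rrna
  bios <- sample(names(weights), n_src, replace = TRUE, prob = weights)
  reads <- character(n_reads)
  truth_bio <- character(n_reads)
  truth_feat <- character(n_reads)
  truth_len <- integer(n_reads)
  is_rrna <- c(rep(FALSE, n_src), rep(TRUE, n_rrna))
  for (i in seq_len(n_src)) {
    b <- bios[i]
    rows <- which(sim$features$biotype == b)
    feat <- sim$features[sample(rows, 1L), ]
    p <- if (library_type == "sRNA_CAGE") config$cage_insert_length
         else config$insert_length[[b]]
    len <- .rtruncnorm_int(1L, p[1], p[2], p[3], p[4])
    # mature miRNA 5' ends are precise; other biotypes get ragged 5' ends
    jit <- if (b == "miRNA") 0L else sample(0:4, 1L)
    insert <- .draw_insert(genome, feat, len, jit)
    reads[i] <- insert
    truth_bio[i] <- b
    truth_feat[i] <- feat$name
    truth_len[i] <- nchar(insert)
  }
  for (i in seq_len(n_rrna)) {
    len <- .rtruncnorm_int(1L, 35, 10, 18, 80)
    s <- sample.int(nchar(sim$rdna) - len, 1L)
    reads[n_src + i] <- substring(sim$rdna, s, s + len - 1L)
    truth_bio[n_src + i] <- "rRNA"
    truth_feat[n_src + i] <- "rDNA"
    truth_len[n_src + i] <- len
  }
  # assemble full-length reads: insert + adapter + random fill
  full <- vapply(reads, function(ins) {
    tail_len <- config$read_length - nchar(ins) - nchar(config$adapter)
    r <- paste0(ins, config$adapter,
                if (tail_len > 0) .rand_dna(tail_len) else "")
    substr(r, 1L, config$read_length)
  }, "", USE.NAMES = FALSE)
  ids <- sprintf("%s_%05d", library_id, seq_len(n_reads))
  list(
    reads = data.frame(read_id = ids, read = full, library_id = library_id,
                       library_type = library_type, stringsAsFactors = FALSE),
    truth = data.frame(read_id = ids, biotype = truth_bio,
                       feature = truth_feat, insert_length = truth_len,
                       is_rrna = is_rrna, stringsAsFactors = FALSE)
  )
}

#' Generate synthetic LC-MS cap mass observations
#'
#' Samples true cap structures from a catalog and perturbs each calculated
#' [M-H]- mass with Gaussian relative noise of the configured ppm SD:
#' `observed = calculated * (1 + e)`, `e ~ N(0, sd_ppm * 1e-6)`.
#'
#' @param config A [sim_config()] (supplies seed and `mass_noise_ppm`).
#' @param catalog A `cap_catalog` from [enumerate_caps()].
#' @param n Number of observations.
#' @param sd_ppm Overrides `config$mass_noise_ppm` when given.
#' @return List: `observations` (data frame `identifier`, `observed_mass`,
#'   `fraction`) and `truth` (adds `true_label`, `true_formula`,
#'   `calculated_mass`).
#' @export
gen_mass_observations <- function(config, catalog, n = 200L,
                                  sd_ppm = config$mass_noise_ppm) {
  stopifnot(inherits(config, "sim_config"), nrow(catalog) > 0)
  set.seed(config$seed + 7000L)
  idx <- sample.int(nrow(catalog), n, replace = TRUE)
  eps <- stats::rnorm(n, 0, sd_ppm * 1e-6)
  obs <- data.frame(
    identifier = sprintf("obs_%04d", seq_len(n)),
    observed_mass = catalog$anion_mass[idx] * (1 + eps),
    fraction = sample(cap_fractions(), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  truth <- cbind(obs,
                 true_label = catalog$label[idx],
                 true_formula = catalog$formula[idx],
                 calculated_mass = catalog$anion_mass[idx],
                 stringsAsFactors = FALSE)
  list(observations = obs, truth = truth)
}

#' Default true TLC spot percentage profiles
#'
#' Ground-truth spot intensity percentages per electrophoresis fraction used
#' by [gen_spot_tables()]; a qualitative emulation of methylguanosine-cap
#' densitometry (trimethylguanosine strongest overall, dimethylguanosine
#' prominent in the tRNA-rich mid fraction), not figure-read values.
#'
#' @return Named list (fraction -> named percentage vector summing to 100).
#' @export
tlc_truth_profiles <- function() {
  list(
    "<50"     = c(Gp = 30, "7mGp" = 8, "2,7mGp" = 7, "2,2,7mGp" = 25,
                  "2,2mGp" = 20, Cmp = 10),
    "50-100"  = c(Gp = 20, "7mGp" = 5, "2,7mGp" = 5, "2,2,7mGp" = 25,
                  "2,2mGp" = 35, Cmp = 10),
    "100-200" = c(Gp = 18, "7mGp" = 7, "2,7mGp" = 10, "2,2,7mGp" = 40,
                  "2,2mGp" = 15, Cmp = 10)
  )
}

#' Generate synthetic TLC spot-intensity tables
#'
#' Raw intensities are the true percentages scaled by a random per-plate
#' exposure, plus a per-plate background and Gaussian noise; a saturated
#' origin spot is added to every plate. With zero noise,
#' [normalize_plate()] recovers the truth exactly.
#'
#' @param config A [sim_config()] (supplies seed and replicate count).
#' @param truth Named list of per-fraction truth percentages
#'   (default [tlc_truth_profiles()]).
#' @param noise_sd SD of additive intensity noise as a fraction of the plate
#'   scale (default 0.01).
#' @return List: `spots` (data frame `plate_id`, `replicate_id`, `fraction`,
#'   `spot_label`, `raw_intensity`, `background`, `saturated`) and `truth`.
#' @export
gen_spot_tables <- function(config, truth = tlc_truth_profiles(),
                            noise_sd = 0.01) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 9000L)
  rows <- list()
  for (frac in names(truth)) {
    pct <- truth[[frac]]
    for (rep_i in seq_len(config$tlc_replicates)) {
      scale <- stats::runif(1, 500, 5000)
      bg <- stats::runif(1, 5, 20)
      raw <- pct / 100 * scale + bg +
        abs(stats::rnorm(length(pct), 0, noise_sd * scale))
      plate <- paste0(frac, "_rep", rep_i)
      rows[[length(rows) + 1L]] <- data.frame(
        plate_id = plate, replicate_id = rep_i, fraction = frac,
        spot_label = c(names(pct), "origin"),
        raw_intensity = c(raw, 65535),
        background = bg,
        saturated = c(rep(FALSE, length(pct)), TRUE),
        stringsAsFactors = FALSE)
    }
  }
  spots <- do.call(rbind, rows)
  rownames(spots) <- NULL
  list(spots = spots, truth = truth)
}
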