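# End-to-end orchestration: simulate -> clip -> dust -> align -> annotate ->
# profile -> enrich, plus the independent MS-matching and TLC branches, with
# a run manifest recording counts at every stage.

#' Write sequences as FASTQ/FASTA
#'
#' @param seqs Named character vector or data frame with `read_id` and
#'   `read`/`sequence` columns.
#' @param path Output file.
#' @param format `"fastq"` (constant placeholder qualities) or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_reads <- function(seqs, path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  if (is.data.frame(seqs)) {
    col <- if ("read" %in% names(seqs)) "read" else "sequence"
    seqs <- stats::setNames(seqs[[col]], seqs$read_id)
  }
  dna <- Biostrings::DNAStringSet(seqs)
  if (format == "fastq") {
    quals <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(dna, path, format = "fastq",
                                qualities = quals)
  } else {
    Biostrings::writeXStringSet(dna, path, format = "fasta")
  }
  invisible(path)
}

#' Read sequencing reads
#' @param path FASTQ or FASTA file (gzipped accepted).
#' @param format File format.
#' @return Named character vector of sequences.
#' @export
read_reads <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  dna <- Biostrings::readDNAStringSet(path, format = format)
  stats::setNames(as.character(dna), sub("\\s.*$", "", names(dna)))
}

#' Write alignments or features as 6-column BED
#'
#' Coordinates are written as stored: 0-based half-open, BED-native. The
#' name column carries `read_id` (alignments) or `biotype:name` (features);
#' score is 1 for unique alignments, 0 otherwise.
#'
#' @param x Alignment or feature data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  name <- if ("read_id" %in% names(x)) x$read_id
          else if (all(c("biotype", "name") %in% names(x)))
            paste0(x$biotype, ":", x$name)
          else "."
  score <- if ("unique" %in% names(x)) as.integer(x$unique) else 0L
  bed <- data.frame(x$chrom, x$start, x$end, name, score, x$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 6-column BED file
#' @param path BED file (0-based half-open).
#' @param features Parse the name column as `biotype:name`?
#' @return Data frame with `chrom`, `start`, `end`, `strand` and either
#'   `read_id`/`unique` or `biotype`/`name`.
#' @export
read_bed <- function(path, features = FALSE) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  out <- data.frame(chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
                    strand = bed[[6]], stringsAsFactors = FALSE)
  if (features) {
    out$biotype <- sub(":.*$", "", bed[[4]])
    out$name <- sub("^[^:]*:", "", bed[[4]])
  } else {
    out$read_id <- bed[[4]]
    out$unique <- bed[[5]] == 1L
  }
  out
}

#' Ingest a minimal SAM alignment subset
#'
#' Converts mapped records of a SAM file (as produced by external aligners)
#' to the package's 0-based half-open alignment frame. Only the FLAG
#' (strand, unmapped), RNAME, POS and SEQ length are used; CIGAR hard/soft
#' clips are ignored (exact-match alignments only).
#'
#' @param path SAM file.
#' @return Alignment data frame (`read_id`, `chrom`, `start`, `end`,
#'   `strand`, `unique`); multi-mapped flagging requires the aligner's own
#'   reporting, so `unique` is `TRUE` unless a read id repeats.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0)
    return(data.frame(read_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), unique = logical()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), 0L)
  keep <- bitwAnd(flag, 4L) == 0L  # mapped only
  f <- f[keep]; flag <- flag[keep]
  ids <- vapply(f, `[`, "", 1L)
  out <- data.frame(
    read_id = ids,
    chrom = vapply(f, `[`, "", 3L),
    start = vapply(f, function(x) as.integer(x[4]), 0L) - 1L,
    end = vapply(f, function(x) as.integer(x[4]) + nchar(x[10]) - 1L, 0L),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    stringsAsFactors = FALSE)
  out$unique <- !(duplicated(ids) | duplicated(ids, fromLast = TRUE))
  out
}

.write_csv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  for (cl in names(df)[num]) {
    if (grepl("mass", cl)) df[[cl]] <- sprintf("%.6f", df[[cl]])
    if (grepl("ppm", cl)) df[[cl]] <- sprintf("%.2f", df[[cl]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' @param seed Top-level seed; all per-stage seeds derive from it.
#' @param ... Overrides for [sim_config()] fields.
#' @return Nested configuration list for [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L, ...) {
  list(
    seed = as.integer(seed),
    simulate = TRUE,
    sim = sim_config(seed = seed, ...),
    libraries = c("sRNA", "capped_sRNA", "sRNA_CAGE", "IP_K121", "IP_control"),
    min_match = 8L,
    tolerance_ppm = 5,
    pseudocount = 1,
    window = 100L,
    unique_only = TRUE,
    n_mass_obs = 200L
  )
}

#' Run the full analysis pipeline on synthetic (or supplied) data
#'
#' Executes clip -> dust -> align -> annotate -> profile -> enrich on each
#' library, and independently the MS matching and TLC normalization
#' branches, writing all stage outputs and a run manifest under `outdir`.
#' Reruns with the same config and seed are deterministic.
#'
#' @param config A [pipeline_config()] list, or the path to a YAML file of
#'   the same shape (missing fields are an error, reported by name).
#' @param outdir Output directory (created).
#' @return The run manifest, invisibly: tool version, config hash, seed,
#'   per-stage record counts and paths, timestamps. At every filtering
#'   stage, reads in = kept + removed.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
    if (!is.null(config$sim)) {
      config$sim <- do.call(sim_config, config$sim[
        names(config$sim) %in% names(formals(sim_config))])
    } else config$sim <- sim_config(seed = config$seed)
  }
  for (field in c("seed", "sim", "libraries", "min_match", "tolerance_ppm"))
    if (is.null(config[[field]]))
      stop("config missing required field: ", field)
  if (is.null(config$sim$adapter))
    stop("config missing required field: adapter")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(lapply(config, function(x)
    if (inherits(x, "sim_config")) unclass(x) else x), cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)

  manifest <- list(tool = "capscape",
                   version = as.character(utils::packageVersion("capscape")),
                   config_hash = cfg_hash, seed = config$seed,
                   started = format(t0), stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    message(sprintf("[%s] %s", stage,
                    paste(names(list(...)), unlist(list(...)),
                          sep = "=", collapse = " ")))
  }

  sim <- gen_genome_and_annotation(config$sim)
  write_reads(sim$genome, file.path(outdir, "genome.fasta"), "fasta")
  write_reads(c(rDNA_synthetic = sim$rdna),
              file.path(outdir, "rdna_synthetic.fasta"), "fasta")
  write_bed(sim$features, file.path(outdir, "features.bed"))
  note("simulate", genome_nt = config$sim$genome_length,
       features = nrow(sim$features))

  annotated_all <- list()
  aligned_by_lib <- list()
  for (lib in config$libraries) {
    gl <- gen_library(config$sim, sim, lib)
    write_reads(gl$reads, file.path(outdir, paste0(lib, ".fastq")))
    tags <- clip_adapter(gl$reads$read, config$sim$adapter, config$min_match,
                         read_id = gl$reads$read_id)
    dust <- rrna_filter(tags, sim$rdna)
    stopifnot(nrow(tags) == nrow(dust$kept) + nrow(dust$removed))
    kept <- dust$kept
    if (lib == "sRNA_CAGE")
      kept <- cage_truncate(kept, config$sim$cage_tag_length)
    aln <- toy_align(kept[nzchar(kept$sequence), ], sim$genome)
    if (isTRUE(config$unique_only)) aln <- aln[aln$unique, , drop = FALSE]
    aln$library_id <- lib
    aligned_by_lib[[lib]] <- aln
    bio <- resolve_annotation(aln, sim$features)
    ann <- cbind(aln, biotype = bio,
                 length_bin = length_bin(
                   kept$inferred_length[match(aln$read_id, kept$read_id)]),
                 stringsAsFactors = FALSE)
    annotated_all[[lib]] <- ann
    write_bed(aln, file.path(outdir, paste0(lib, ".aligned.bed")))
    lh <- table(factor(kept$inferred_length, levels = 0:config$sim$read_length),
                useNA = "ifany")
    utils::write.csv(data.frame(length = names(lh), count = as.integer(lh)),
                     file.path(outdir, paste0(lib, ".lengths.csv")),
                     row.names = FALSE)
    note(paste0("library_", lib), reads_in = nrow(tags),
         tags_kept = nrow(dust$kept), tags_removed = nrow(dust$removed),
         aligned_unique = nrow(aln))
  }

  comp <- composition_table(do.call(rbind, annotated_all))
  .write_csv(comp, file.path(outdir, "composition.csv"))
  note("annotate", groups = nrow(comp))

  # TSS profile: feature 5' ends as sites, CAGE alignments as query
  feats <- sim$features
  sites <- data.frame(chrom = feats$chrom,
                      position = ifelse(feats$strand == "-", feats$end - 1L,
                                        feats$start),
                      strand = feats$strand, name = feats$name,
                      stringsAsFactors = FALSE)
  prof <- site_window_profile(aligned_by_lib[["sRNA_CAGE"]], sites,
                              config$window)
  .write_csv(prof$per_site, file.path(outdir, "tss_profile.csv"))
  note("profile", sites = nrow(sites),
       fraction_in_window = round(prof$fraction_in_window, 4))

  enr <- cluster_and_enrich(aligned_by_lib,
                            treatment_ids = "IP_K121",
                            control_ids = "IP_control",
                            pseudocount = config$pseudocount)
  .write_csv(enr, file.path(outdir, "clusters_ip.csv"))
  note("enrich", clusters = nrow(enr))

  catalog <- enumerate_caps()
  ms <- gen_mass_observations(config$sim, catalog, n = config$n_mass_obs)
  mm <- match_observations(ms$observations, catalog, config$tolerance_ppm)
  .write_csv(mm$assigned, file.path(outdir, "ms_matches.csv"))
  if (!is.null(mm$unknowns))
    .write_csv(mm$unknowns, file.path(outdir, "ms_unknowns.csv"))
  note("match", observations = nrow(ms$observations),
       matched = nrow(ms$observations) -
         (if (is.null(mm$unknowns)) 0L else nrow(mm$unknowns)),
       unknown = if (is.null(mm$unknowns)) 0L else nrow(mm$unknowns))

  tlc <- gen_spot_tables(config$sim)
  norm <- tlc_normalize(tlc$spots)
  summ <- replicate_summary(norm)
  .write_csv(summ, file.path(outdir, "tlc_summary.csv"))
  note("tlc", plates = length(unique(tlc$spots$plate_id)),
       spots = nrow(tlc$spots))

  manifest$finished <- format(Sys.time())
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}
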