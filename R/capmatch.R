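# Enumeration of the candidate cap space, ppm-tolerance assignment of
# observed anion masses to isobar groups, cap-type classification, and the
# detection-matrix / cross-validation reports.

#' Size-fraction vocabulary for LC-fractionated sRNA
#' @return Character vector of the three fraction labels (nt).
#' @export
cap_fractions <- function() c("20-50", "50-100", ">100")

#' Default cap-structure alphabet
#'
#' Methylation ranges covering every structure named in the detection table:
#' guanosine 0-3 base methyls, adenosine 0-1 (N6), none on C/U, and an
#' optional 2'-O-ribose methyl on every nucleoside.
#'
#' @param bases Bases to include.
#' @param base_methyl_max Named integer vector of per-base N-methyl maxima.
#' @param ribose_methyl Logical; allow 2'-O-ribose methylation?
#' @return A list used by [enumerate_caps()].
#' @export
default_alphabet <- function(bases = c("A", "C", "G", "U"),
                             base_methyl_max = c(A = 1L, C = 0L, G = 3L, U = 0L),
                             ribose_methyl = TRUE) {
  if (length(bases) == 0) stop("alphabet must contain at least one base")
  list(bases = bases,
       base_methyl_max = base_methyl_max,
       ribose_methyl = isTRUE(ribose_methyl))
}

.alphabet_nucleosides <- function(alphabet) {
  out <- list()
  for (b in alphabet$bases) {
    mmax <- alphabet$base_methyl_max[[b]]
    if (is.null(mmax)) mmax <- 0L
    for (k in 0:mmax) {
      for (r in if (alphabet$ribose_methyl) c(FALSE, TRUE) else FALSE) {
        out[[length(out) + 1L]] <-
          nucleoside(b, k, r, base_methyl_max = alphabet$base_methyl_max)
      }
    }
  }
  out
}

#' Enumerate all candidate cap dinucleotides under an alphabet
#'
#' Every distinct unordered pair of nucleosides from the alphabet (including
#' self-pairs) joined by the triphosphate bridge, in deterministic order
#' (anion mass, then label).
#'
#' @param alphabet An alphabet from [default_alphabet()].
#' @return A `cap_catalog`: a data frame with columns `label`, `base_pair`,
#'   `total_methyls`, `formula`, `neutral_mass`, `anion_mass`, `cap_type`,
#'   and attribute `caps`, the parallel list of `cap_structure` objects.
#' @examples
#' cat <- enumerate_caps()
#' nrow(cat)
#' head(cat$label)
#' @export
enumerate_caps <- function(alphabet = default_alphabet()) {
  nucs <- .alphabet_nucleosides(alphabet)
  if (length(nucs) == 0) stop("alphabet enumerates no nucleosides")
  caps <- list()
  seen <- character()
  for (i in seq_along(nucs)) {
    for (j in i:length(nucs)) {
      cap <- cap_structure(nucs[[i]], nucs[[j]])
      lab <- cap_label(cap)
      if (!lab %in% seen) {
        seen <- c(seen, lab)
        caps[[length(caps) + 1L]] <- cap
      }
    }
  }
  df <- data.frame(
    label = vapply(caps, cap_label, ""),
    base_pair = vapply(caps, function(cp)
      paste(sort(c(cp$outer$base, cp$inner$base)), collapse = ""), ""),
    total_methyls = vapply(caps, cap_total_methyls, 0L),
    formula = vapply(caps, function(cp)
      format(cap_neutral_formula(cp$outer, cp$inner)), ""),
    neutral_mass = vapply(caps, function(cp)
      formula_mass(cap_neutral_formula(cp$outer, cp$inner)), 0),
    anion_mass = vapply(caps, anion_mass, 0),
    cap_type = vapply(caps, classify_cap_type, ""),
    stringsAsFactors = FALSE
  )
  ord <- order(df$anion_mass, df$label)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "caps") <- caps[ord]
  class(df) <- c("cap_catalog", "data.frame")
  df
}

#' Classify a cap as type 0 or type I-or-higher
#'
#' Cap types count 2'-O-methylated nucleotides following the 5'-5' bridge:
#' type 0 caps carry no ribose methylation on the first transcribed (inner)
#' nucleotide; any inner 2'-O-methyl makes the cap type I or higher.
#'
#' @param cap A `cap_structure`.
#' @return `"type0"` or `"type1_or_higher"`.
#' @examples
#' classify_cap_type(cap_structure(nucleoside("G"), nucleoside("G")))
#' @export
classify_cap_type <- function(cap) {
  stopifnot(inherits(cap, "cap_structure"))
  if (cap$inner$ribose_methyl) "type1_or_higher" else "type0"
}

#' Canonicalize a published structure label
#'
#' Strips the `"/NpppM"` alternate ordering and any parenthetical isomer
#' suffix (retention-time isomers share a mass and cannot be separated by
#' precursor mass alone), e.g. `"2mGpppAm(1)/Amppp2mG(1)"` becomes
#' `"2mGpppAm"`.
#'
#' @param label Character vector of structure labels.
#' @return Canonical labels.
#' @export
canonical_label <- function(label) {
  lab <- sub("/.*$", "", label)
  sub("\\([0-9]+\\)", "", lab)
}

#' Match one observed anion mass against a cap catalog
#'
#' Returns every catalog structure whose calculated [M-H]- mass lies within
#' `tolerance_ppm` of the observation, grouped into isobars (identical
#' elemental formula). Observations with no in-tolerance candidate get
#' status `"unknown"` but still report their nearest out-of-tolerance
#' candidates to aid curation.
#'
#' @param observed_mass Observed [M-H]- mass in Da (positive scalar).
#' @param catalog A `cap_catalog` from [enumerate_caps()].
#' @param tolerance_ppm Match tolerance in ppm (default 5; must be positive).
#' @param fraction Optional size-fraction label (see [cap_fractions()]).
#' @param id Optional observation identifier.
#' @param n_nearest How many nearest candidates to report for unknowns.
#' @return A `cap_match` list: `observation`, `status`, `candidates`
#'   (data frame sorted by |ppm| with an `isobar_group` id), `isobar_groups`
#'   (split of candidates by formula), and for unknowns `nearest`.
#' @examples
#' cat <- enumerate_caps()
#' m <- match_observation(827.1308, cat)
#' m$status
#' @export
match_observation <- function(observed_mass, catalog, tolerance_ppm = 5,
                              fraction = NA_character_, id = NA_character_,
                              n_nearest = 3L) {
  stopifnot(is.numeric(observed_mass), length(observed_mass) == 1L,
            observed_mass > 0)
  if (!is.numeric(tolerance_ppm) || tolerance_ppm <= 0)
    stop("tolerance_ppm must be positive")
  if (!is.na(fraction) && !fraction %in% cap_fractions())
    stop("unknown fraction label: ", fraction)
  ppm <- ppm_error(observed_mass, catalog$anion_mass)
  hit <- abs(ppm) <= tolerance_ppm
  cand <- data.frame(
    label = catalog$label[hit],
    formula = catalog$formula[hit],
    calculated_mass = catalog$anion_mass[hit],
    ppm = ppm[hit],
    cap_type = catalog$cap_type[hit],
    stringsAsFactors = FALSE
  )
  cand <- cand[order(abs(cand$ppm), cand$label), , drop = FALSE]
  cand$isobar_group <- match(cand$formula, unique(cand$formula))
  rownames(cand) <- NULL
  res <- list(
    observation = list(id = id, observed_mass = observed_mass,
                       fraction = fraction, tolerance_ppm = tolerance_ppm),
    status = if (nrow(cand) > 0) "matched" else "unknown",
    candidates = cand,
    isobar_groups = if (nrow(cand) > 0) split(cand, cand$isobar_group)
                    else list()
  )
  if (res$status == "unknown") {
    ord <- order(abs(ppm))[seq_len(min(n_nearest, length(ppm)))]
    res$nearest <- data.frame(
      label = catalog$label[ord],
      calculated_mass = catalog$anion_mass[ord],
      ppm = ppm[ord],
      stringsAsFactors = FALSE
    )
  }
  class(res) <- "cap_match"
  res
}

#' @export
print.cap_match <- function(x, ...) {
  obs <- x$observation
  cat(sprintf("<cap_match> m/z %.4f (%s): %s\n", obs$observed_mass,
              ifelse(is.na(obs$fraction), "no fraction", obs$fraction),
              x$status))
  if (x$status == "matched") {
    print(x$candidates)
  } else if (!is.null(x$nearest)) {
    cat("nearest out-of-tolerance candidates:\n")
    print(x$nearest)
  }
  invisible(x)
}

#' Match a table of observations
#'
#' @param observations Data frame with columns `identifier`, `observed_mass`
#'   and optionally `fraction`.
#' @inheritParams match_observation
#' @return List with `matches` (list of `cap_match`), `assigned` (long data
#'   frame of all candidates across observations) and `unknowns` (data frame
#'   of unmatched observations with their nearest candidate).
#' @export
match_observations <- function(observations, catalog, tolerance_ppm = 5) {
  stopifnot(is.data.frame(observations),
            all(c("identifier", "observed_mass") %in% names(observations)))
  frac <- if ("fraction" %in% names(observations)) observations$fraction
          else rep(NA_character_, nrow(observations))
  matches <- lapply(seq_len(nrow(observations)), function(i)
    match_observation(observations$observed_mass[i], catalog, tolerance_ppm,
                      fraction = frac[i],
                      id = as.character(observations$identifier[i])))
  rows <- lapply(matches, function(m) {
    if (m$status != "matched") return(NULL)
    cbind(identifier = m$observation$id,
          observed_mass = m$observation$observed_mass,
          fraction = m$observation$fraction,
          m$candidates, stringsAsFactors = FALSE)
  })
  unk <- lapply(matches, function(m) {
    if (m$status != "unknown") return(NULL)
    data.frame(identifier = m$observation$id,
               observed_mass = m$observation$observed_mass,
               fraction = m$observation$fraction,
               nearest_label = m$nearest$label[1],
               nearest_ppm = m$nearest$ppm[1],
               stringsAsFactors = FALSE)
  })
  list(matches = matches,
       assigned = do.call(rbind, rows),
       unknowns = do.call(rbind, unk))
}

#' Load the packaged cap detection matrix
#'
#' Verbatim transcription of the published LC-MS summary: one row per
#' structure with per-fraction detection calls, calculated and observed
#' [M-H]- masses, and printed ppm error. Yn rows are observed masses with no
#' assigned structure.
#'
#' @param path Optional path to an alternative CSV with the same columns.
#' @return Data frame with columns `structure`, `frac_20_50`, `frac_50_100`,
#'   `frac_gt100`, `calculated_mass`, `observed_mass`, `error_ppm`.
#' @export
cap_detection_matrix <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1_cap_detection.csv",
                        package = "capscape")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("structure", "frac_20_50", "frac_50_100", "frac_gt100",
              "calculated_mass", "observed_mass", "error_ppm")
  if (!all(needed %in% names(df)))
    stop("detection matrix must have columns: ", paste(needed, collapse = ", "))
  bad <- !unlist(df[, c("frac_20_50", "frac_50_100", "frac_gt100")]) %in%
    c("detected", "ND")
  if (any(bad)) stop("detection values must be 'detected' or 'ND'")
  df
}

.is_unknown_row <- function(structure) grepl("Y[0-9]+", structure)

#' Structures detected in exactly one size fraction
#'
#' Scans a detection matrix for structures called `detected` in the given
#' fraction and `ND` in all others.
#'
#' @param matrix A detection matrix, see [cap_detection_matrix()].
#' @param fraction One of [cap_fractions()].
#' @param include_unknown Include unassigned (Yn) rows?
#' @return Character vector of canonical structure labels.
#' @examples
#' fraction_specific_structures(cap_detection_matrix(), "20-50")
#' @export
fraction_specific_structures <- function(matrix, fraction,
                                         include_unknown = FALSE) {
  fracs <- cap_fractions()
  if (!fraction %in% fracs) stop("unknown fraction: ", fraction)
  if (nrow(matrix) == 0) return(character())
  cols <- c("frac_20_50", "frac_50_100", "frac_gt100")
  target <- cols[match(fraction, fracs)]
  others <- setdiff(cols, target)
  keep <- matrix[[target]] == "detected" &
    Reduce(`&`, lapply(others, function(cl) matrix[[cl]] == "ND"))
  if (!include_unknown) keep <- keep & !.is_unknown_row(matrix$structure)
  canonical_label(matrix$structure[keep])
}

# The two techniques name methylation differently: TLC spots list N-methyl
# POSITIONS ("2,2,7mGp" carries three methyls, "7mGp" one), while
# precursor-mass labels give COUNTS ("3mG" three, "mG" one) because mass
# cannot resolve positions. Both map onto a shared cap-nucleoside key
# (base, n base methyls, ribose methyl).
.finish_key <- function(lab, n_base) {
  ribose <- grepl("^[ACGU]m", lab)
  base <- substr(lab, 1, 1)
  if (!base %in% c("A", "C", "G", "U")) return(NA_character_)
  paste0(base, ":", n_base, "m", if (ribose) ":2'Om" else "")
}

.key_from_spot <- function(label) {
  lab <- gsub(" ", "", sub("p$", "", label))   # TLC spots are monophosphates
  n_base <- 0L
  if (grepl("^[0-9][0-9,]*m[ACGU]", lab)) {
    pos <- sub("m[ACGU].*$", "", lab)
    n_base <- length(strsplit(pos, ",", fixed = TRUE)[[1]])
    lab <- sub("^[0-9][0-9,]*m", "", lab)
  }
  .finish_key(lab, n_base)
}

.key_from_ms <- function(label) {
  lab <- gsub(" ", "", label)
  n_base <- 0L
  if (grepl("^[23]?m[ACGU]", lab)) {
    pre <- sub("m[ACGU].*$", "", lab)
    n_base <- if (pre == "") 1L else as.integer(pre)
    lab <- sub("^[23]?m", "", lab)
  }
  .finish_key(lab, n_base)
}

#' Cross-validate TLC spot identifications against MS cap assignments
#'
#' Joins the two orthogonal identifications on the cap-nucleoside key (base
#' plus methyl count; TLC resolves positions, precursor mass only counts).
#' Rows present in both techniques form the cross-validated report; inputs
#' seen by only one technique are listed in residual sections, never
#' silently dropped.
#'
#' @param tlc_identifications Data frame with columns `spot_label` and
#'   `fraction` (TLC fraction vocabulary, free text carried through).
#' @param ms_matches Data frame with columns `structure` (canonical or
#'   published label; the outer nucleoside is used) and `fraction`.
#' @return List of data frames: `cross_validated` (key, spot labels,
#'   structures, fraction coverage from both techniques), `tlc_only`,
#'   `ms_only`.
#' @export
cross_validate <- function(tlc_identifications, ms_matches) {
  stopifnot(is.data.frame(tlc_identifications), is.data.frame(ms_matches))
  tlc <- tlc_identifications
  ms <- ms_matches
  tlc$key <- vapply(tlc$spot_label, .key_from_spot, "")
  outer_lab <- sub("ppp.*$", "", canonical_label(ms$structure))
  ms$key <- vapply(outer_lab, .key_from_ms, "")
  shared <- intersect(stats::na.omit(tlc$key), stats::na.omit(ms$key))
  cv <- do.call(rbind, lapply(shared, function(k) {
    data.frame(
      key = k,
      spot_labels = paste(sort(unique(tlc$spot_label[tlc$key %in% k])),
                          collapse = ";"),
      structures = paste(sort(unique(canonical_label(
        ms$structure[ms$key %in% k]))), collapse = ";"),
      tlc_fractions = paste(sort(unique(tlc$fraction[tlc$key %in% k])),
                            collapse = ";"),
      ms_fractions = paste(sort(unique(ms$fraction[ms$key %in% k])),
                           collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(cv)) cv <- data.frame(key = character(), spot_labels = character(),
                                    structures = character(),
                                    tlc_fractions = character(),
                                    ms_fractions = character(),
                                    stringsAsFactors = FALSE)
  list(cross_validated = cv,
       tlc_only = tlc[!tlc$key %in% shared, , drop = FALSE],
       ms_only = ms[!ms$key %in% shared, , drop = FALSE])
}
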