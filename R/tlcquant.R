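# Normalization of 2D-TLC spot densitometry into per-plate percentages and
# replicate summaries.

#' Normalize spot intensities on one TLC plate
#'
#' Background-subtracted intensities are expressed as a percentage of the
#' total background-subtracted intensity of all quantified (non-saturated)
#' spots on the same plate:
#' `pct_i = 100 * max(raw_i - bg_i, 0) / sum_j max(raw_j - bg_j, 0)`.
#' Saturated spots (typically the loading origin) are excluded from both
#' numerator and denominator and get `NA`. Negative background-subtracted
#' values clamp to zero with a warning.
#'
#' @param spots Data frame for a single plate with columns `spot_label`,
#'   `raw_intensity`, `background`, and optionally `saturated` (logical).
#' @return The input with columns `net_intensity` and `pct` added;
#'   percentages over non-saturated spots sum to 100.
#' @examples
#' normalize_plate(data.frame(spot_label = c("Gp", "7mGp", "2,2,7mGp"),
#'                            raw_intensity = c(10, 30, 60), background = 0))
#' @export
normalize_plate <- function(spots) {
  stopifnot(is.data.frame(spots),
            all(c("spot_label", "raw_intensity", "background") %in%
                  names(spots)))
  if (any(spots$raw_intensity < 0) || any(spots$background < 0))
    stop("intensities and backgrounds must be non-negative")
  sat <- if ("saturated" %in% names(spots)) spots$saturated
         else rep(FALSE, nrow(spots))
  net <- spots$raw_intensity - spots$background
  if (any(net < 0 & !sat)) {
    warning("negative background-subtracted intensities clamped to 0")
    net <- pmax(net, 0)
  }
  total <- sum(net[!sat])
  if (!any(!sat) || total <= 0)
    stop("no positive non-saturated intensity on plate after background subtraction")
  spots$net_intensity <- ifelse(sat, NA_real_, net)
  spots$pct <- ifelse(sat, NA_real_, 100 * net / total)
  spots
}

#' Normalize a multi-plate spot table
#'
#' Applies [normalize_plate()] within each plate of a table covering
#' several plates/replicates.
#'
#' @param spots Data frame with a `plate_id` column plus the columns
#'   required by [normalize_plate()].
#' @return The input with `net_intensity` and `pct` columns.
#' @export
tlc_normalize <- function(spots) {
  stopifnot("plate_id" %in% names(spots))
  parts <- split(spots, spots$plate_id)
  out <- do.call(rbind, lapply(parts, normalize_plate))
  rownames(out) <- NULL
  out
}

#' Summarize normalized spot percentages across replicates
#'
#' Per (fraction, spot): arithmetic mean, sample standard deviation (n-1
#' denominator; 0 when a single replicate), and replicate count. Spots
#' missing from a replicate are treated as absent, not zero, unless
#' `absent_as_zero` is set, in which case every (fraction, spot) pair is
#' filled to the full replicate count with zeros.
#'
#' @param normalized Data frame from [tlc_normalize()] with columns
#'   `fraction`, `spot_label`, `pct` (and `plate_id` when `absent_as_zero`).
#' @param absent_as_zero Treat missing spots as 0%?
#' @return Data frame: `fraction`, `spot_label`, `mean_pct`, `sd_pct`, `n`.
#' @export
replicate_summary <- function(normalized, absent_as_zero = FALSE) {
  stopifnot(all(c("fraction", "spot_label", "pct") %in% names(normalized)))
  df <- normalized[!is.na(normalized$pct), , drop = FALSE]
  if (isTRUE(absent_as_zero)) {
    n_rep <- tapply(df$plate_id, df$fraction,
                    function(p) length(unique(p)))
    key <- unique(df[c("fraction", "spot_label")])
    filled <- lapply(seq_len(nrow(key)), function(i) {
      sel <- df$fraction == key$fraction[i] &
        df$spot_label == key$spot_label[i]
      pct <- df$pct[sel]
      c(pct, rep(0, n_rep[[as.character(key$fraction[i])]] - length(pct)))
    })
    data.frame(
      fraction = key$fraction, spot_label = key$spot_label,
      mean_pct = vapply(filled, mean, 0),
      sd_pct = vapply(filled, function(x) if (length(x) > 1) stats::sd(x) else 0, 0),
      n = vapply(filled, length, 0L),
      stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(
      df$pct, by = list(fraction = df$fraction, spot_label = df$spot_label),
      FUN = function(x) c(mean = mean(x),
                          sd = if (length(x) > 1) stats::sd(x) else 0,
                          n = length(x)))
    out <- data.frame(fraction = agg$fraction, spot_label = agg$spot_label,
                      mean_pct = agg$x[, "mean"], sd_pct = agg$x[, "sd"],
                      n = as.integer(agg$x[, "n"]),
                      stringsAsFactors = FALSE)
    out[order(out$fraction, out$spot_label), , drop = FALSE]
  }
}
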