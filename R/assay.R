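#' End-point durotactic index
#'
#' Counts cells over the stiff and soft stripes of a patterned substrate
#' and returns the stiff/soft ratio. In the standard assay cells are
#' equally distributed over soft and stiff stripes shortly after plating
#' (index 1) and the index is read out after migration (e.g. 24 h); when
#' a baseline observation is supplied the index is additionally
#' normalized by the baseline's raw index. Cells in the transition band
#' are excluded from both counts by default (reported in `n_excluded`);
#' pass `rule = "midpoint"` to split them at the stiffness midpoint.
#' When `density_normalize` is `TRUE` counts are divided by the
#' respective region areas first, cancelling unequal stripe widths.
#'
#' @param positions n x 2 matrix or data frame with `x`, `y` columns:
#'   cell positions in um, inside the pattern extent.
#' @param pattern A [substrate_pattern()].
#' @param baseline Optional baseline positions (same format), typically
#'   the plating-time observation, whose raw index normalizes the result.
#' @param density_normalize Divide counts by region areas (default
#'   `FALSE`, the plain count ratio).
#' @param rule Transition-band rule passed to [region_of()].
#' @return A `durotaxis_result`: list with `n_stiff`, `n_soft`,
#'   `n_excluded`, `index_raw`, `index_normalized`,
#'   `normalization_baseline`, `saturated` (TRUE when the soft count is
#'   zero, in which case indices are `NA` rather than infinite).
#' @examples
#' p <- substrate_pattern("step_stripes", 4000, 40000)
#' pos <- rbind(c(250, 10), c(50, 10))  # one stiff, one soft
#' durotactic_index(pos, p)$index_raw   # 1
#' @export
durotactic_index <- function(positions, pattern, baseline = NULL,
                             density_normalize = FALSE,
                             rule = c("exclude", "midpoint")) {
  rule <- match.arg(rule)
  pos <- as_position_matrix(positions)
  if (nrow(pos) == 0) stop("no cell positions supplied", call. = FALSE)
  lab <- region_of(pattern, pos, rule = rule)
  n_stiff <- sum(lab == "stiff")
  n_soft <- sum(lab == "soft")
  n_excl <- sum(lab == "transition")
  cs <- n_stiff; cf <- n_soft
  if (density_normalize) {
    ar <- region_areas(pattern)
    cs <- n_stiff / ar["stiff"]
    cf <- n_soft / ar["soft"]
  }
  saturated <- cf == 0
  raw <- if (saturated) NA_real_ else cs / cf
  norm_base <- NA_real_
  normalized <- raw
  if (!is.null(baseline)) {
    base <- durotactic_index(baseline, pattern,
                             density_normalize = density_normalize,
                             rule = rule)
    norm_base <- base$index_raw
    normalized <- if (saturated || is.na(norm_base)) NA_real_ else
      raw / norm_base
  }
  structure(
    list(n_stiff = n_stiff, n_soft = n_soft, n_excluded = n_excl,
         index_raw = raw, index_normalized = normalized,
         normalization_baseline = norm_base, saturated = saturated),
    class = "durotaxis_result"
  )
}

as_position_matrix <- function(positions) {
  if (is.data.frame(positions)) {
    stopifnot(all(c("x", "y") %in% names(positions)))
    positions <- cbind(positions$x, positions$y)
  }
  as_points(positions)
}

# plateau areas of one stripe period times the number of periods that fit
# the extent (approximate for partial periods; exact for whole ones)
region_areas <- function(pattern) {
  if (pattern$kind == "step_stripes" || pattern$kind == "island") {
    p <- stripe_period(pattern)
    frac_stiff <- pattern$stripe_width_stiff / p
    frac_soft <- pattern$stripe_width_soft / p
  } else if (pattern$kind == "linear_gradient") {
    w <- pattern$extent[1]
    tw <- min(pattern$transition_width, w)
    frac_stiff <- (w - tw) / w
    frac_soft <- 0
    if (frac_stiff == 0) frac_stiff <- NA_real_
  } else {
    frac_stiff <- NA_real_; frac_soft <- 1
  }
  tot <- prod(pattern$extent)
  c(stiff = frac_stiff * tot, soft = frac_soft * tot)
}

#' @export
print.durotaxis_result <- function(x, ...) {
  cat(sprintf("<durotaxis_result: %d stiff / %d soft (%d excluded)>\n",
              x$n_stiff, x$n_soft, x$n_excluded))
  if (x$saturated) {
    cat("  index: saturated (zero soft count)\n")
  } else {
    cat(sprintf("  index_raw = %.3g", x$index_raw))
    if (!is.na(x$normalization_baseline)) {
      cat(sprintf(", normalized = %.3g (baseline %.3g)",
                  x$index_normalized, x$normalization_baseline))
    }
    cat("\n")
  }
  invisible(x)
}

#' Categorical durotaxis classification
#'
#' Classifies a durotactic index against the conventional thresholds:
#' `strong` above 6 (mesenchymal stem cells, fibroblasts), `moderate`
#' above 2 (endothelial cells), `confluence_dependent` above 4 for
#' confluent monolayers (collectively migrating epithelia), otherwise
#' `none`. Thresholds are configurable and the rule is non-decreasing in
#' the index.
#'
#' @param index Durotactic index (>= 0).
#' @param confluent Was the assay performed at high confluence?
#' @param thresholds Named numeric: `strong`, `confluent`, `moderate`.
#' @return One of `"strong"`, `"confluence_dependent"`, `"moderate"`,
#'   `"none"`.
#' @export
classify_durotaxis <- function(index, confluent = FALSE,
                               thresholds = c(strong = 6, confluent = 4,
                                              moderate = 2)) {
  stopifnot(is.numeric(index), length(index) == 1L)
  if (is.na(index) || index < 0) {
    stop("durotactic index must be a non-negative number", call. = FALSE)
  }
  if (index > thresholds[["strong"]]) return("strong")
  if (confluent && index > thresholds[["confluent"]]) {
    return("confluence_dependent")
  }
  if (index > thresholds[["moderate"]]) return("moderate")
  "none"
}

#' Durotaxis assay time course
#'
#' Computes a [durotactic_index()] per timepoint, each normalized to the
#' earliest observation (the plating-time baseline, conventionally 4 h,
#' which scores a normalized index of 1 by construction).
#'
#' @param observations Named list: one positions object (matrix or
#'   `x`/`y` data frame) per timepoint, or a data frame with columns
#'   `x`, `y`, `timepoint_h`.
#' @param pattern The shared [substrate_pattern()].
#' @param ... Passed to [durotactic_index()].
#' @return Data frame, one row per timepoint: `timepoint_h`, `n_stiff`,
#'   `n_soft`, `n_excluded`, `index_raw`, `index_normalized`,
#'   `saturated`.
#' @export
assay_timecourse <- function(observations, pattern, ...) {
  if (is.data.frame(observations)) {
    stopifnot(all(c("x", "y", "timepoint_h") %in% names(observations)))
    observations <- split(observations[, c("x", "y")],
                          observations$timepoint_h)
  }
  tp <- as.numeric(names(observations))
  if (anyNA(tp)) stop("observations must be named by timepoint (hours)",
                      call. = FALSE)
  ord <- order(tp)
  observations <- observations[ord]
  tp <- tp[ord]
  base <- durotactic_index(observations[[1]], pattern, ...)
  rows <- lapply(seq_along(tp), function(k) {
    r <- durotactic_index(observations[[k]], pattern, ...)
    norm <- if (r$saturated || is.na(base$index_raw)) NA_real_ else
      r$index_raw / base$index_raw
    data.frame(timepoint_h = tp[k], n_stiff = r$n_stiff,
               n_soft = r$n_soft, n_excluded = r$n_excluded,
               index_raw = r$index_raw, index_normalized = norm,
               saturated = r$saturated)
  })
  do.call(rbind, rows)
}
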