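## OCT stage: quality filtering, combination of opposite-offset boundary
## traces into thickness profiles, fovea localization from the
## outer-segment band, and sampling onto the canonical grid.

#' OCT quality filter
#'
#' Scans are kept only when the instrument quality metric strictly exceeds
#' 20 dB.
#'
#' @param quality_db Quality metric in dB (vector).
#' @return Logical: keep?
#' @export
#' @examples
#' qc_filter_oct(c(25, 20, 19.9)) # TRUE FALSE FALSE
qc_filter_oct <- function(quality_db) {
  stopifnot(all(is.finite(quality_db)))
  quality_db > 20
}

## Merge one boundary from several (typically two opposite-offset) traces:
## per column, average the depths of the traces on which the boundary is
## valid.
merge_boundary_traces <- function(traces) {
  if (inherits(traces, "boundary_trace")) traces <- list(traces)
  cols <- traces[[1]]$columns
  name <- traces[[1]]$boundary_name
  for (tr in traces[-1]) {
    if (!identical(tr$columns, cols)) stop("column axes disagree")
    if (!identical(tr$boundary_name, name)) stop("boundary names disagree")
  }
  depth_mat <- vapply(traces, function(tr) {
    ifelse(tr$valid, tr$depths, NA_real_)
  }, numeric(length(cols)))
  depth_mat <- matrix(depth_mat, nrow = length(cols))
  n_valid <- rowSums(!is.na(depth_mat))
  depths <- rowMeans(depth_mat, na.rm = TRUE)
  depths[n_valid == 0] <- NA_real_
  boundary_trace(cols, depths, n_valid > 0, name)
}

#' Combine anterior and posterior boundaries into a thickness profile
#'
#' Thickness per column is the posterior minus the anterior boundary
#' depth, each boundary taken from whichever offset scan delineates it
#' (two opposite-offset scans supply complementary halves). Columns where
#' either boundary is unavailable are linearly interpolated if they make
#' up at most 10% of the scan, otherwise an error is raised. Negative
#' differences (segmentation noise) are floored at 0 with a warning
#' carrying the count, unless boundaries cross on more than 10% of
#' columns, which is treated as a precondition violation.
#'
#' @param anterior A [boundary_trace()] or list of traces (one per offset).
#' @param posterior A [boundary_trace()] or list of traces.
#' @param meta Scan metadata list; `axial_um_per_px` converts px to um,
#'   `meridian` labels the profile.
#' @return A `thickness_profile` (thickness per column, px and um).
#' @export
combine_boundaries <- function(anterior, posterior, meta) {
  ant <- merge_boundary_traces(anterior)
  post <- merge_boundary_traces(posterior)
  if (!identical(ant$columns, post$columns)) stop("column axes disagree")
  cols <- ant$columns
  n <- length(cols)

  missing <- !(ant$valid & post$valid)
  if (mean(missing) > 0.10) {
    stop("no valid source for a required boundary over >10% of columns")
  }
  thickness <- post$depths - ant$depths
  if (any(missing)) {
    thickness[missing] <- stats::approx(cols[!missing], thickness[!missing],
                                        xout = cols[missing], rule = 2)$y
  }

  neg <- thickness < 0
  if (mean(neg) > 0.10) {
    stop(sprintf(
      "anterior and posterior boundaries cross on %.0f%% of columns",
      100 * mean(neg)))
  }
  n_floored <- sum(neg)
  if (n_floored > 0) {
    warning(sprintf("floored %d negative thickness column(s) at 0",
                    n_floored))
    thickness[neg] <- 0
  }

  axial <- if (!is.null(meta$axial_um_per_px)) meta$axial_um_per_px else NA
  new_thickness_profile(cols, thickness, thickness * axial,
                        meridian = meta$meridian %||% "unknown",
                        n_floored = n_floored)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Centered moving average of width `width`, partial windows at the edges.
moving_average <- function(x, width) {
  half <- (width - 1) / 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Localize the foveal center from the outer-segment band
#'
#' The fovea is the column with the longest photoreceptor outer segment.
#' The band is smoothed with a fixed odd-width moving average before the
#' argmax so single-column jitter cannot move the result; residual exact
#' ties are broken toward the image-center column.
#'
#' @param os_band A [boundary_trace()] of outer-segment length per column.
#' @param smooth_width Odd moving-average width in columns.
#' @return Foveal column (px).
#' @export
locate_fovea_oct <- function(os_band, smooth_width = 11) {
  stopifnot(smooth_width %% 2 == 1)
  if (sum(os_band$valid) < 3) stop("need at least 3 valid columns")
  cols <- os_band$columns
  lens <- os_band$depths
  if (any(!os_band$valid)) {
    lens[!os_band$valid] <- stats::approx(
      cols[os_band$valid], lens[os_band$valid],
      xout = cols[!os_band$valid], rule = 2)$y
  }
  sm <- moving_average(lens, smooth_width)
  peak <- which(sm == max(sm))
  if (length(peak) > 1) {
    center <- (cols[1] + cols[length(cols)]) / 2
    peak <- peak[order(abs(cols[peak] - center), cols[peak])][1]
  }
  cols[peak]
}

#' Sample a thickness profile onto the canonical grid
#'
#' Each grid eccentricity e is converted to a lateral offset of
#' `e * 320 um / lateral_um_per_px` pixels from the foveal column (320
#' um/deg; no axial-length correction) and thickness is read by linear
#' interpolation between columns. One profile is returned per
#' half-meridian: temporal/nasal for a horizontal scan, inferior/superior
#' for a vertical scan.
#'
#' @param profile A `thickness_profile` from [combine_boundaries()].
#' @param foveal_col Foveal column (px), from [locate_fovea_oct()].
#' @param meta Scan metadata list with `lateral_um_per_px` and `meridian`.
#' @return Named list of two [ecc_profile()]s (kind `"thickness"`, px).
#' @export
sample_thickness <- function(profile, foveal_col, meta) {
  grid <- canonical_grid()
  offset_px <- grid * UM_PER_DEG / meta$lateral_um_per_px
  halves <- if (identical(meta$meridian, "vertical")) {
    c(neg = "inferior", pos = "superior")
  } else {
    c(neg = "temporal", pos = "nasal")
  }
  cols <- profile$columns
  span <- range(cols)
  if (foveal_col - max(offset_px) < span[1] ||
      foveal_col + max(offset_px) > span[2]) {
    stop("scan does not span 3 degrees on both sides of the fovea")
  }
  sample_at <- function(x) {
    stats::approx(cols, profile$thickness_px, xout = x)$y
  }
  out <- list(
    ecc_profile(sample_at(foveal_col - offset_px), "thickness",
                meridian = halves[["neg"]]),
    ecc_profile(sample_at(foveal_col + offset_px), "thickness",
                meridian = halves[["pos"]]))
  names(out) <- c(halves[["neg"]], halves[["pos"]])
  out
}

#' Average the four half-meridian thickness profiles
#'
#' Pointwise arithmetic mean of the temporal, superior, nasal and inferior
#' profiles on the canonical grid. A missing meridian is an error: the
#' subject is flagged incomplete rather than imputed.
#'
#' @param profiles List of four [ecc_profile()]s, one per meridian.
#' @return An [ecc_profile()] with meridian `"mean"`.
#' @export
average_meridians <- function(profiles) {
  mers <- vapply(profiles, function(p) p$meridian, character(1))
  if (!setequal(mers, MERIDIANS) || length(profiles) != 4) {
    stop("need exactly one profile per meridian (temporal, superior, ",
         "nasal, inferior); subject incomplete")
  }
  vals <- rowMeans(vapply(profiles, function(p) p$values,
                          numeric(length(canonical_grid()))))
  ecc_profile(vals, "thickness", meridian = "mean")
}

#' Run the OCT stage for one subject
#'
#' Applies the quality filter to all four scans, merges opposite-offset
#' traces per meridian, localizes the fovea from the outer-segment bands,
#' samples thickness at the canonical eccentricities, and averages the
#' four meridians.
#'
#' @param scans List of four scan lists as returned by
#'   [simulate_oct_boundaries()] or read from disk (fields `anterior`,
#'   `posterior`, `os_band`, `meta`, `offset_sign`).
#' @return An [ecc_profile()] of four-meridian mean thickness (px), or an
#'   object of class `qc_drop` carrying the reason if the subject fails QC.
#' @export
oct_subject_thickness <- function(scans) {
  q <- vapply(scans, function(s) s$meta$quality_db, numeric(1))
  if (!all(qc_filter_oct(q))) {
    return(structure(list(reason = sprintf(
      "OCT quality %.1f dB fails the >20 dB criterion", min(q))),
      class = "qc_drop"))
  }
  meridian_of <- vapply(scans, function(s) s$meta$meridian, character(1))
  halves <- list()
  for (mer in c("horizontal", "vertical")) {
    pair <- scans[meridian_of == mer]
    if (length(pair) != 2) stop("need two opposite-offset scans per meridian")
    prof <- combine_boundaries(lapply(pair, `[[`, "anterior"),
                               lapply(pair, `[[`, "posterior"),
                               pair[[1]]$meta)
    fovea <- round(mean(vapply(pair, function(s) {
      locate_fovea_oct(s$os_band)
    }, numeric(1))))
    halves <- c(halves, sample_thickness(prof, fovea, pair[[1]]$meta))
  }
  average_meridians(halves)
}
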