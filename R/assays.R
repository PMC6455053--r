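#' Fit a fluorescence-vs-genome-size ploidy standard curve
#'
#' Flow-cytometric genome-size estimation: strains of known genome size
#' are stained with a stoichiometric DNA dye and the median fluorescence
#' of cells in the 1n and 2n phases of the cell cycle is recorded.  Each
#' standard contributes two points, (G, F_1n) and (2G, F_2n), and a
#' least-squares line of fluorescence versus genome size is fitted.
#'
#' @param standards data.frame with columns strain_id, known_genome_size
#'   (Mbp), median_fluorescence_1n, median_fluorescence_2n.
#' @param use_2n include the 2n-phase points (6-point curve from three
#'   standards); set FALSE for a 1n-only 3-point curve.
#' @return list of class `ploidy_curve`: slope, intercept, r_squared,
#'   n_points, model.
#' @export
fit_standard_curve <- function(standards, use_2n = TRUE) {
  stopifnot(all(c("strain_id", "known_genome_size", "median_fluorescence_1n",
                  "median_fluorescence_2n") %in% names(standards)))
  if (any(standards$median_fluorescence_1n <= 0 |
            standards$median_fluorescence_2n <= 0))
    stop("fluorescence medians must be positive")
  if (any(standards$median_fluorescence_2n <= standards$median_fluorescence_1n))
    stop("2n median must exceed 1n median")
  g <- standards$known_genome_size
  f <- standards$median_fluorescence_1n
  if (use_2n) {
    g <- c(g, 2 * standards$known_genome_size)
    f <- c(f, standards$median_fluorescence_2n)
  }
  if (length(g) < 3) stop("at least 3 points required for the standard curve")
  if (length(unique(g)) < 2) stop("degenerate standards: all genome sizes equal")
  fit <- stats::lm(f ~ g)
  # noiseless standards fit perfectly; the summary warning is expected there
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 n_points = length(g), model = fit),
            class = "ploidy_curve")
}

#' Estimate a genome size from sample fluorescence medians
#'
#' Inverts the standard curve at the sample's 1n and 2n medians; the 2n
#' prediction is halved so both predict the same quantity, and the two
#' estimates are averaged.
#'
#' @param curve a `ploidy_curve` from [fit_standard_curve()].
#' @param sample_median_1n,sample_median_2n sample fluorescence medians.
#' @return Estimated genome size (same units as the standards, Mbp).
#' @export
estimate_genome_size <- function(curve, sample_median_1n, sample_median_2n) {
  stopifnot(inherits(curve, "ploidy_curve"))
  if (sample_median_2n <= sample_median_1n)
    stop("2n median must exceed 1n median")
  if (abs(curve$slope) < .Machine$double.eps)
    stop("standard curve is not invertible (zero slope)")
  g1 <- (sample_median_1n - curve$intercept) / curve$slope
  g2 <- (sample_median_2n - curve$intercept) / curve$slope / 2
  (g1 + g2) / 2
}

#' Specific growth rate from an off-gas CO2 profile
#'
#' During exponential growth the CO2 production rate is proportional to
#' biomass, so ln(CO2 signal) is linear in time with slope mu.  The
#' profile is optionally smoothed with a centered moving average, every
#' window of at least `min_points` consecutive positive readings is
#' fitted by least squares on the log scale, and among windows reaching
#' `min_r2` the longest is selected (ties broken by R^2).  The estimator
#' is invariant to multiplicative scaling of the signal.
#'
#' @param profile data.frame with columns time (hours, strictly
#'   increasing) and co2 (non-negative readings).
#' @param smooth_window odd moving-average width in points (1 = none).
#' @param min_points minimum window size (>= 5).
#' @param min_r2 minimum R^2 for an acceptable exponential window.
#' @return list: status ("ok" or "no exponential phase"), mu (h^-1),
#'   r_squared, window (index range used).
#' @export
growth_rate_from_co2 <- function(profile, smooth_window = 1L,
                                 min_points = 5L, min_r2 = 0.98) {
  stopifnot(all(c("time", "co2") %in% names(profile)))
  t <- profile$time; y <- profile$co2
  if (length(t) < 10) stop("at least 10 profile points required")
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  if (any(y < 0)) stop("CO2 readings must be non-negative")
  if (smooth_window > 1) {
    k <- as.integer(smooth_window)
    if (k %% 2 == 0) k <- k + 1L
    sm <- stats::filter(y, rep(1 / k, k), sides = 2)
    y <- ifelse(is.na(sm), y, as.numeric(sm))
  }
  pos <- y > 0
  n <- length(t)
  best <- NULL
  # incremental least squares over all windows of consecutive positive points
  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (ri in which(runs$values & runs$lengths >= min_points)) {
    i0 <- starts[ri]; i1 <- ends[ri]
    tt <- t[i0:i1]; ly <- log(y[i0:i1])
    m <- length(tt)
    for (a in 1:(m - min_points + 1)) {
      # expanding windows share cumulative sums
      sx <- 0; sy <- 0; sxx <- 0; sxy <- 0; syy <- 0
      for (b in a:m) {
        xi <- tt[b]; yi <- ly[b]
        sx <- sx + xi; sy <- sy + yi
        sxx <- sxx + xi^2; sxy <- sxy + xi * yi; syy <- syy + yi^2
        k <- b - a + 1
        if (k < min_points) next
        vx <- sxx - sx^2 / k
        vy <- syy - sy^2 / k
        cxy <- sxy - sx * sy / k
        if (vx <= 0 || vy <= 0) next
        r2 <- cxy^2 / (vx * vy)
        slope <- cxy / vx
        if (r2 >= min_r2 && slope > 0) {
          if (is.null(best) || k > best$k ||
              (k == best$k && r2 > best$r2)) {
            best <- list(k = k, r2 = r2, slope = slope,
                         window = c(i0 + a - 1L, i0 + b - 1L))
          }
        }
      }
    }
  }
  if (is.null(best)) {
    return(list(status = "no exponential phase", mu = NA_real_,
                r_squared = NA_real_, window = c(NA_integer_, NA_integer_)))
  }
  list(status = "ok", mu = best$slope, r_squared = best$r2,
       window = best$window)
}

#' Write / read TSV helpers for assay inputs
#' @param x data.frame.
#' @param file path.
#' @export
write_tsv <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}
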