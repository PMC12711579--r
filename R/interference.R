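#' Analysis parameters for the interference pipeline
#'
#' @param bin_width distance-histogram and CoC interval width, base pairs.
#' @param n_pairs resampled crossover-midpoint pairs per chromosome used to
#'   build the random-placement expected distance distribution.
#' @param n_perm permutation iterations for the positional-bias test (>= 100).
#' @param short_dco_max upper distance bound (base pairs) defining "short"
#'   cis-double-crossovers entering the positional test.
#' @param min_support minimum markers per genotype segment in the caller.
#' @param window_bp window width for physical crossover landscapes.
#' @param scaled_bins number of equal bins for the telomere-to-centromere
#'   arm-scaled landscape.
#' @param seed optional RNG seed consumed by [co_interference()].
#' @return A list of class `"analysis_params"`.
#' @export
analysis_params <- function(bin_width = 3.15e6, n_pairs = 200, n_perm = 10000,
                            short_dco_max = 5e6, min_support = 3,
                            window_bp = 3e5, scaled_bins = 100, seed = NULL) {
  stopifnot(bin_width > 0, n_pairs > 0, n_perm >= 100, short_dco_max > 0,
            min_support >= 1, window_bp > 0, scaled_bins >= 1)
  structure(list(bin_width = bin_width, n_pairs = n_pairs, n_perm = n_perm,
                 short_dco_max = short_dco_max, min_support = min_support,
                 window_bp = window_bp, scaled_bins = scaled_bins, seed = seed),
            class = "analysis_params")
}

#' Extract cis-double-crossovers from genotype segments
#'
#' A cis-double-crossover (cis-DCO) is a pair of crossovers on the same
#' transmitted haplotype, visible in an F2 genotype track as a
#' parental-heterozygous-parental segment triple with the same parental
#' genotype on both sides (`AA-AB-AA` or `BB-AB-BB`). The `AA-AB-BB` (trans)
#' configuration is excluded. Every qualifying triple yields one event, so a
#' segment may flank two events; such overlaps are flagged.
#'
#' @param segments segment table from [segment_population()].
#' @param genome a [genome_map] (for normalized chromosome-end distances).
#' @return A data.frame with one row per event: `individual`, `chrom`,
#'   `mid1`, `mid2` (flanking crossover midpoints), `distance`
#'   (`mid2 - mid1`), `flank` (`"AA"`/`"BB"`), `midpoint` (event midpoint),
#'   `norm_end_dist` (distance of the event midpoint to the nearest
#'   chromosome end, divided by chromosome length), `overlaps`.
#' @export
extract_cis_dcos <- function(segments, genome) {
  n <- nrow(segments)
  empty <- data.frame(individual = segments$individual[0],
                      chrom = character(0), mid1 = numeric(0),
                      mid2 = numeric(0), distance = numeric(0),
                      flank = character(0), midpoint = numeric(0),
                      norm_end_dist = numeric(0), overlaps = logical(0),
                      stringsAsFactors = FALSE)
  if (n < 3L) return(empty)
  i <- 2:(n - 1L)
  same_track <- segments$individual[i - 1L] == segments$individual[i + 1L] &
                segments$chrom[i - 1L] == segments$chrom[i + 1L] &
                segments$individual[i - 1L] == segments$individual[i] &
                segments$chrom[i - 1L] == segments$chrom[i]
  hit <- same_track &
    segments$genotype[i] == "AB" &
    segments$genotype[i - 1L] == segments$genotype[i + 1L] &
    segments$genotype[i - 1L] %in% c("AA", "BB")
  i <- i[hit]
  if (length(i) == 0L) return(empty)
  mid1 <- (segments$last[i - 1L] + segments$first[i]) / 2
  mid2 <- (segments$last[i] + segments$first[i + 1L]) / 2
  midpoint <- (mid1 + mid2) / 2
  len <- genome$length[genome_row(genome, segments$chrom[i])]
  ev <- data.frame(individual = segments$individual[i],
                   chrom = segments$chrom[i],
                   mid1 = mid1, mid2 = mid2, distance = mid2 - mid1,
                   flank = segments$genotype[i - 1L],
                   midpoint = midpoint,
                   norm_end_dist = pmin(midpoint, len - midpoint) / len,
                   overlaps = c(diff(i) == 2L, FALSE) | c(FALSE, diff(i) == 2L),
                   stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  ev
}

#' Resample expected inter-crossover distances under random placement
#'
#' Builds the random-placement null for cis-DCO distances: per chromosome,
#' `n_pairs` pairs of crossover midpoints are drawn uniformly with
#' replacement from that chromosome's pooled observed midpoints (two
#' independent draws per pair; identical positions are permitted) and their
#' absolute distance recorded. Chromosomes with fewer than two observed
#' midpoints are skipped with a warning.
#'
#' @param events crossover table from [call_crossovers()] (pooled over the
#'   individuals of one genotype group).
#' @param genome a [genome_map].
#' @param n_pairs pairs per chromosome.
#' @return A data.frame `chrom`, `distance`.
#' @export
expected_distance_sample <- function(events, genome, n_pairs = 200) {
  out <- lapply(genome$chrom, function(ch) {
    mids <- events$midpoint[events$chrom == ch]
    if (length(mids) < 2L) {
      warning("chromosome ", ch, " has < 2 crossover midpoints; skipped")
      return(NULL)
    }
    a <- sample(mids, n_pairs, replace = TRUE)
    b <- sample(mids, n_pairs, replace = TRUE)
    data.frame(chrom = ch, distance = abs(a - b), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Bin observed and expected inter-crossover distances
#'
#' Bins both series into uniform half-open bins `[k*w, (k+1)*w)`, normalizes
#' frequencies within each series, records medians, and (optionally) fits a
#' gamma distribution to each series by maximum likelihood.
#'
#' @param observed numeric vector of observed cis-DCO distances (>= 0).
#' @param expected numeric vector of resampled expected distances.
#' @param bin_width bin width, base pairs.
#' @param fit if `TRUE`, attach [fit_gamma()] results for both series
#'   (`NULL` where a fit is not possible).
#' @return A list of class `"distance_distribution"`: `bin_width`, `breaks`,
#'   `mids`, `observed_counts`, `observed_freq`, `expected_counts`,
#'   `expected_freq`, `observed_median`, `expected_median`, `observed_fit`,
#'   `expected_fit`.
#' @export
bin_distances <- function(observed, expected, bin_width = 3.15e6, fit = TRUE) {
  if (length(observed) == 0L) stop("no observed distances to analyse")
  stopifnot(all(observed >= 0), all(expected >= 0))
  nb <- max(floor(c(observed, expected) / bin_width)) + 1L
  breaks <- (0:nb) * bin_width
  cobs <- tabulate(pmin(floor(observed / bin_width) + 1L, nb), nbins = nb)
  cexp <- tabulate(pmin(floor(expected / bin_width) + 1L, nb), nbins = nb)
  res <- list(bin_width = bin_width, breaks = breaks,
              mids = breaks[-1] - bin_width / 2,
              observed_counts = cobs,
              observed_freq = cobs / sum(cobs),
              expected_counts = cexp,
              expected_freq = if (sum(cexp) > 0) cexp / sum(cexp) else cexp,
              observed_median = stats::median(observed),
              expected_median = if (length(expected)) stats::median(expected) else NA_real_)
  if (fit) {
    res$observed_fit <- try_fit_gamma(observed)
    res$expected_fit <- try_fit_gamma(expected)
  }
  class(res) <- "distance_distribution"
  res
}

try_fit_gamma <- function(x) {
  tryCatch(fit_gamma(x), error = function(e) NULL)
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat("Inter-crossover distance distribution (bin width",
      format(x$bin_width, big.mark = ","), "bp)\n")
  cat(sprintf("  observed: n = %d, median = %.3g bp\n",
              sum(x$observed_counts), x$observed_median))
  cat(sprintf("  expected: n = %d, median = %.3g bp\n",
              sum(x$expected_counts), x$expected_median))
  if (!is.null(x$observed_fit)) {
    cat(sprintf("  gamma fit (observed): shape %.3f, rate %.3g\n",
                x$observed_fit$shape, x$observed_fit$rate))
  }
  if (!is.null(x$expected_fit)) {
    cat(sprintf("  gamma fit (expected): shape %.3f, rate %.3g\n",
                x$expected_fit$shape, x$expected_fit$rate))
  }
  invisible(x)
}

#' Maximum-likelihood gamma fit to a distance sample
#'
#' Fits a gamma distribution by maximum likelihood (via
#' \code{fitdistrplus::fitdist}) with method-of-moments initialization.
#' Zero distances are offset by half the smallest positive distance (the
#' gamma density requires positive support); the number of offset points is
#' recorded. Data are rescaled internally by their mean for numerical
#' stability; the returned rate is on the original base-pair scale.
#'
#' @param x numeric distances, `length(x) >= 5`, not all equal.
#' @return A list of class `"gamma_fit"`: `shape`, `rate`, `loglik`,
#'   `converged`, `n`, `n_zero_offset`.
#' @export
fit_gamma <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 5L) stop("gamma fit requires at least 5 distances")
  if (stats::var(x) == 0) stop("gamma fit requires non-degenerate distances")
  nz <- sum(x == 0)
  if (nz > 0) {
    if (!any(x > 0)) stop("gamma fit requires positive distances")
    x[x == 0] <- min(x[x > 0]) / 2
  }
  s <- mean(x)
  xs <- x / s
  m <- mean(xs); v <- stats::var(xs)
  start <- list(shape = max(m^2 / v, 1e-3), rate = max(m / v, 1e-3))
  fd <- fitdistrplus::fitdist(xs, "gamma", method = "mle", start = start)
  loglik_shift <- -length(x) * log(s)  # Jacobian of the rescaling
  structure(list(shape = unname(fd$estimate["shape"]),
                 rate = unname(fd$estimate["rate"]) / s,
                 loglik = fd$loglik + loglik_shift,
                 converged = is.finite(fd$loglik),
                 n = length(x), n_zero_offset = nz),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("Gamma fit: shape = %.4f, rate = %.4g (n = %d, loglik = %.2f)\n",
              x$shape, x$rate, x$n, x$loglik))
  invisible(x)
}

#' Permutation test for chromosome-end bias of short cis-DCOs
#'
#' Tests whether short cis-double-crossovers sit closer to the chromosome
#' ends than expected by chance. The statistic is the mean, over events with
#' `distance < short_dco_max`, of the event midpoint's normalized distance
#' to the nearest chromosome end. Under the null, each event's midpoint is
#' replaced by a uniform random position on its own chromosome, `n_perm`
#' times. The one-sided empirical p-value (toward the ends, i.e. small
#' means) uses the add-one correction
#' `p = (1 + #\{null mean <= observed mean\}) / (1 + n_perm)`; the two-sided
#' p-value is also reported.
#'
#' @param dcos cis-DCO table from [extract_cis_dcos()].
#' @param genome a [genome_map].
#' @param n_perm permutation iterations.
#' @param short_dco_max distance cutoff (base pairs) selecting short events.
#' @return A list of class `"dco_position_test"`: `observed_mean`,
#'   `p_one_sided`, `p_two_sided`, `n_events`, `n_perm`, `null_means`.
#' @export
short_dco_position_test <- function(dcos, genome, n_perm = 10000,
                                    short_dco_max = 5e6) {
  sel <- dcos[dcos$distance < short_dco_max, , drop = FALSE]
  if (nrow(sel) == 0L) stop("no cis-DCOs below the short-distance cutoff")
  len <- genome$length[genome_row(genome, sel$chrom)]
  obs <- mean(pmin(sel$midpoint, len - sel$midpoint) / len)
  ne <- nrow(sel)
  u <- matrix(stats::runif(n_perm * ne), nrow = n_perm)
  pos <- 1 + u * rep(len - 1, each = n_perm)
  lmat <- rep(len, each = n_perm)
  nd <- pmin(pos, lmat - pos) / lmat
  null_means <- rowMeans(matrix(nd, nrow = n_perm))
  p_low <- (1 + sum(null_means <= obs)) / (1 + n_perm)
  p_high <- (1 + sum(null_means >= obs)) / (1 + n_perm)
  structure(list(observed_mean = obs,
                 p_one_sided = p_low,
                 p_two_sided = min(1, 2 * min(p_low, p_high)),
                 n_events = ne, n_perm = n_perm,
                 null_means = null_means),
            class = "dco_position_test")
}

#' @export
print.dco_position_test <- function(x, ...) {
  cat("Permutation test: chromosome-end bias of short cis-DCOs\n")
  cat(sprintf("  events: %d; observed mean normalized end distance: %.4f\n",
              x$n_events, x$observed_mean))
  cat(sprintf("  one-sided p (toward ends): %.4g; two-sided p: %.4g (%d permutations)\n",
              x$p_one_sided, x$p_two_sided, x$n_perm))
  invisible(x)
}
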