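#' Coefficient-of-coincidence profile
#'
#' The coefficient of coincidence (CoC) compares the observed frequency of
#' double crossovers at a given inter-interval distance to the frequency
#' expected under independent crossover placement: CoC = 1 means no
#' interference, CoC < 1 positive interference, CoC > 1 at short distances
#' crossover clustering. Two estimators are provided and must agree at
#' CoC = 1 under independence:
#'
#' * `"interval_pairs"` (the classical construction): each chromosome is
#'   tiled into `bin_width` intervals; for an interval pair (i, j) the
#'   observed value is the fraction of individuals with at least one
#'   crossover in both, the expected value is the product of the two
#'   marginal interval frequencies; CoC per distance class `|i - j|` is the
#'   ratio of the summed observed to summed expected values, pooled over
#'   chromosomes.
#' * `"distance_histogram"`: the observed cis-DCO distance frequencies are
#'   divided, bin by bin, by the resampled random-placement expected
#'   frequencies (see [expected_distance_sample()]). When `n_individuals`
#'   and per-chromosome mean crossover counts are available, the expected
#'   series is first rescaled so its total matches the double-crossover rate
#'   implied by independent placement (per individual per chromosome,
#'   `E[C(N,2)] = lambda^2 / 2` with `N ~ Poisson(lambda)` at the observed
#'   mean `lambda`); otherwise the plain ratio of relative frequencies is
#'   returned.
#'
#' @param events crossover table from [call_crossovers()].
#' @param genome a [genome_map].
#' @param individuals all individual ids of the group (defines denominators).
#' @param bin_width interval width, base pairs.
#' @param mode `"interval_pairs"` or `"distance_histogram"`.
#' @param segments segment table (required for `"distance_histogram"`, which
#'   extracts cis-DCOs from it).
#' @param n_pairs resampled pairs per chromosome for the expected series
#'   (`"distance_histogram"` only).
#' @param scale_to_co_rate logical: apply the observed-CO-frequency rescaling
#'   of the expected series (`"distance_histogram"` only).
#' @return A data.frame of class `"coc_profile"` with columns
#'   `distance_class`, `distance_bp` (class centre distance), `coc`,
#'   `observed`, `expected`, and `defined` (FALSE where the expected
#'   frequency is zero and the CoC is masked to `NA`).
#' @export
coc_profile <- function(events, genome, individuals,
                        bin_width = 3.15e6,
                        mode = c("interval_pairs", "distance_histogram"),
                        segments = NULL, n_pairs = 200,
                        scale_to_co_rate = TRUE) {
  mode <- match.arg(mode)
  if (mode == "interval_pairs") {
    return(coc_interval_pairs(events, genome, individuals, bin_width))
  }
  if (is.null(segments)) stop("distance_histogram mode requires `segments`")
  dcos <- extract_cis_dcos(segments, genome)
  if (nrow(dcos) == 0L) stop("no cis-DCOs observed; CoC profile undefined")
  expected <- expected_distance_sample(events, genome, n_pairs = n_pairs)
  co_rate <- NULL
  n_ind <- NULL
  if (scale_to_co_rate) {
    n_ind <- length(unique(individuals))
    tab <- table(factor(events$chrom, levels = genome$chrom))
    co_rate <- as.numeric(tab) / n_ind
    names(co_rate) <- genome$chrom
  }
  coc_distance_histogram(dcos, expected, bin_width = bin_width,
                         n_individuals = n_ind, co_rate = co_rate)
}

#' @rdname coc_profile
#' @export
coc_interval_pairs <- function(events, genome, individuals, bin_width = 3.15e6) {
  individuals <- unique(individuals)
  n_ind <- length(individuals)
  if (n_ind == 0L) stop("individuals must be non-empty")
  max_k <- max(ceiling(genome$length / bin_width))
  sum_obs <- numeric(max_k - 1L)
  sum_exp <- numeric(max_k - 1L)
  n_pairs <- integer(max_k - 1L)
  for (ci in seq_len(nrow(genome))) {
    ch <- genome$chrom[ci]
    k <- ceiling(genome$length[ci] / bin_width)
    if (k < 2L) next
    ev <- events[events$chrom == ch, , drop = FALSE]
    w <- window_index(ev$midpoint, bin_width)
    inc <- table(factor(ev$individual, levels = individuals),
                 factor(w, levels = seq_len(k))) > 0
    f <- colMeans(inc)
    joint <- crossprod(inc) / n_ind   # P(>=1 CO in i and in j)
    for (d in seq_len(k - 1L)) {
      i <- seq_len(k - d)
      sum_obs[d] <- sum_obs[d] + sum(joint[cbind(i, i + d)])
      sum_exp[d] <- sum_exp[d] + sum(f[i] * f[i + d])
      n_pairs[d] <- n_pairs[d] + length(i)
    }
  }
  defined <- sum_exp > 0
  out <- data.frame(distance_class = seq_len(max_k - 1L),
                    distance_bp = seq_len(max_k - 1L) * bin_width,
                    coc = ifelse(defined, sum_obs / ifelse(defined, sum_exp, 1), NA_real_),
                    observed = sum_obs, expected = sum_exp,
                    n_interval_pairs = n_pairs,
                    defined = defined, stringsAsFactors = FALSE)
  out <- out[out$n_interval_pairs > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("coc_profile", "data.frame")
  attr(out, "mode") <- "interval_pairs"
  attr(out, "bin_width") <- bin_width
  out
}

#' @rdname coc_profile
#' @param dcos cis-DCO table from [extract_cis_dcos()].
#' @param expected expected-distance table from [expected_distance_sample()].
#' @param n_individuals number of individuals in the group (for rate
#'   scaling; `NULL` for the plain frequency ratio).
#' @param co_rate named numeric: observed mean crossover count per
#'   individual for each chromosome (for rate scaling; `NULL` for the plain
#'   frequency ratio).
#' @export
coc_distance_histogram <- function(dcos, expected, bin_width = 3.15e6,
                                   n_individuals = NULL, co_rate = NULL) {
  if (nrow(dcos) == 0L) stop("no cis-DCOs observed")
  if (is.null(expected) || nrow(expected) == 0L) stop("expected series is empty")
  nb <- max(floor(c(dcos$distance, expected$distance) / bin_width)) + 1L
  scaled <- !is.null(n_individuals) && !is.null(co_rate)
  obs_cnt <- numeric(nb)
  exp_val <- numeric(nb)
  chroms <- union(unique(dcos$chrom), unique(expected$chrom))
  for (ch in chroms) {
    oc <- tabulate(floor(dcos$distance[dcos$chrom == ch] / bin_width) + 1L,
                   nbins = nb)
    ed <- expected$distance[expected$chrom == ch]
    ec <- tabulate(floor(ed / bin_width) + 1L, nbins = nb)
    if (scaled) {
      # rescale this chromosome's expected series so its total equals the
      # independence expectation n_ind * lambda^2 / 2 (Poisson pair count)
      lam <- co_rate[[ch]] %||% 0
      target <- n_individuals * lam^2 / 2
      ef <- if (sum(ec) > 0) ec / sum(ec) * target else ec
      obs_cnt <- obs_cnt + oc
      exp_val <- exp_val + ef
    } else {
      obs_cnt <- obs_cnt + oc
      exp_val <- exp_val + ec
    }
  }
  if (all(exp_val == 0)) stop("expected series has no mass")
  if (scaled) {
    obs <- obs_cnt
    expv <- exp_val
  } else {
    if (sum(exp_val) == 0) stop("expected series has no mass")
    obs <- obs_cnt / sum(obs_cnt)
    expv <- exp_val / sum(exp_val)
  }
  defined <- expv > 0
  out <- data.frame(distance_class = seq_len(nb),
                    distance_bp = (seq_len(nb) - 0.5) * bin_width,
                    coc = ifelse(defined, obs / ifelse(defined, expv, 1), NA_real_),
                    observed = obs, expected = expv,
                    defined = defined, stringsAsFactors = FALSE)
  class(out) <- c("coc_profile", "data.frame")
  attr(out, "mode") <- if (scaled) "distance_histogram_scaled" else "distance_histogram"
  attr(out, "bin_width") <- bin_width
  out
}
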