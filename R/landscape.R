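#' Windowed crossover landscape
#'
#' Assigns each crossover to the physical window containing its midpoint and
#' reports the per-window crossover frequency per F2 individual. Window
#' counts conserve the total: `sum(count) == nrow(events)`.
#'
#' @param events crossover table from [call_crossovers()].
#' @param genome a [genome_map].
#' @param n_individuals number of individuals contributing events.
#' @param window_bp window width, base pairs.
#' @return A data.frame `chrom`, `window`, `start`, `end`, `count`,
#'   `freq_per_individual`.
#' @export
window_co_frequency <- function(events, genome, n_individuals, window_bp = 3e5) {
  stopifnot(n_individuals > 0)
  wins <- partition_windows(genome, window_bp)
  i <- genome_row(genome, events$chrom)
  if (any(events$midpoint < 1 | events$midpoint > genome$length[i])) {
    stop("crossover midpoint outside chromosome bounds")
  }
  key_w <- paste(wins$chrom, wins$window)
  key_e <- paste(events$chrom, window_index(events$midpoint, window_bp))
  cnt <- table(factor(key_e, levels = key_w))
  wins$count <- as.integer(cnt)
  wins$freq_per_individual <- wins$count / n_individuals
  wins
}

#' Arm-scaled crossover landscape (telomere 0 to centromere 1)
#'
#' Maps each physical window's centre to its arm-scaled coordinate
#' ([arm_scaled_coordinate]) and aggregates window frequencies across all
#' chromosome arms into equal-width scaled bins, either averaging (default)
#' or summing per bin.
#'
#' @param landscape output of [window_co_frequency()].
#' @param genome a [genome_map].
#' @param n_bins number of equal scaled bins between telomere and centromere.
#' @param agg `"mean"` or `"sum"` across the windows falling in a bin.
#' @return A data.frame `scaled_bin`, `scaled_center`, `freq`, `n_windows`.
#' @export
scaled_landscape <- function(landscape, genome, n_bins = 100,
                             agg = c("mean", "sum")) {
  agg <- match.arg(agg)
  center <- pmin((landscape$start + landscape$end - 1) / 2,
                 genome$length[genome_row(genome, landscape$chrom)])
  sc <- arm_scaled_coordinate(landscape$chrom, center, genome)
  bin <- pmin(floor(sc$scaled * n_bins) + 1L, n_bins)
  f <- factor(bin, levels = seq_len(n_bins))
  freq <- tapply(landscape$freq_per_individual, f, if (agg == "mean") mean else sum)
  data.frame(scaled_bin = seq_len(n_bins),
             scaled_center = (seq_len(n_bins) - 0.5) / n_bins,
             freq = as.numeric(freq),
             n_windows = as.integer(table(f)))
}

#' Per-individual arm and pericentromere crossover counts
#'
#' Classifies each crossover midpoint as arm or pericentromere
#' ([classify_region]) and tabulates per-individual counts; arm +
#' pericentromere always equals the total.
#'
#' @param events crossover table.
#' @param genome a [genome_map].
#' @param individuals all individual ids (zero rows included).
#' @return A data.frame `individual`, `arm`, `pericentromere`, `total`.
#' @export
region_counts <- function(events, genome, individuals) {
  individuals <- unique(individuals)
  region <- if (nrow(events)) {
    classify_region(events$chrom, events$midpoint, genome)
  } else character(0)
  tab <- table(factor(events$individual, levels = individuals),
               factor(region, levels = c("arm", "pericentromere")))
  data.frame(individual = individuals,
             arm = as.integer(tab[, "arm"]),
             pericentromere = as.integer(tab[, "pericentromere"]),
             total = as.integer(rowSums(tab)),
             stringsAsFactors = FALSE)
}

#' Compare crossover counts between genotype groups
#'
#' Omnibus Kruskal-Wallis on per-individual totals followed by Dunn's
#' pairwise z-tests with Bonferroni correction, plus pairwise two-sided
#' Wilcoxon rank-sum tests (Bonferroni-corrected) on arm, pericentromere and
#' total counts.
#'
#' @param counts a data.frame with columns `group`, `arm`, `pericentromere`,
#'   `total` (one row per individual), e.g. [region_counts()] output with a
#'   `group` column added.
#' @return A list of class `"co_group_tests"`: `kruskal` (statistic, df, p),
#'   `dunn` (pairwise table), `wilcoxon` (per-region pairwise tables).
#' @export
compare_groups <- function(counts) {
  need <- c("group", "arm", "pericentromere", "total")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("counts table is missing columns: ",
                         paste(miss, collapse = ", "))
  g <- factor(counts$group)
  if (nlevels(g) < 2L) stop("need at least two groups")
  if (any(table(g) < 2L)) stop("every group needs at least 2 individuals")
  kw <- stats::kruskal.test(counts$total, g)
  dunn <- dunn_test(counts$total, g)
  wil <- lapply(c(arm = "arm", pericentromere = "pericentromere",
                  total = "total"), function(col) {
    pairwise_wilcoxon(counts[[col]], g)
  })
  structure(list(kruskal = list(statistic = unname(kw$statistic),
                                df = unname(kw$parameter),
                                p = kw$p.value),
                 dunn = dunn, wilcoxon = wil),
            class = "co_group_tests")
}

# Dunn's post-hoc z tests on ranks with tie correction; Bonferroni-adjusted.
dunn_test <- function(x, g) {
  g <- factor(g)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- table(g)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(g)
  combs <- utils::combn(lev, 2)
  k <- ncol(combs)
  z <- p <- numeric(k)
  for (j in seq_len(k)) {
    a <- combs[1, j]; b <- combs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[a]] + 1 / n[[b]]))
    z[j] <- (rbar[[a]] - rbar[[b]]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  data.frame(group1 = combs[1, ], group2 = combs[2, ], z = z,
             p = p, p_adj = pmin(1, p * k), stringsAsFactors = FALSE)
}

pairwise_wilcoxon <- function(x, g) {
  lev <- levels(g)
  combs <- utils::combn(lev, 2)
  k <- ncol(combs)
  p <- W <- numeric(k)
  for (j in seq_len(k)) {
    wt <- suppressWarnings(stats::wilcox.test(x[g == combs[1, j]],
                                              x[g == combs[2, j]],
                                              alternative = "two.sided"))
    p[j] <- wt$p.value
    W[j] <- unname(wt$statistic)
  }
  data.frame(group1 = combs[1, ], group2 = combs[2, ], W = W, p = p,
             p_adj = pmin(1, p * k), stringsAsFactors = FALSE)
}

#' @export
print.co_group_tests <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis on totals: chi-sq = %.3f, df = %d, p = %.3g\n",
              x$kruskal$statistic, x$kruskal$df, x$kruskal$p))
  cat("Dunn pairwise (Bonferroni):\n")
  print(x$dunn, row.names = FALSE)
  cat("Wilcoxon pairwise on totals (Bonferroni):\n")
  print(x$wilcoxon$total, row.names = FALSE)
  invisible(x)
}

#' Percent-change summaries against a reference mean
#'
#' Reports, for each group mean, the percent change relative to a reference
#' mean, the percent change of the pooled group mean, and (for quantities
#' already expressed in percent) the signed percentage-point differences.
#'
#' @param reference reference mean (> 0).
#' @param groups numeric vector of group means.
#' @return A list: `percent_change` (per group), `mean_percent_change`
#'   (pooled group mean vs reference), `point_change` (per-group
#'   `group - reference`), `mean_point_change`.
#' @examples
#' percent_change_summary(52, c(32, 39, 25))
#' @export
percent_change_summary <- function(reference, groups) {
  if (!is.numeric(reference) || length(reference) != 1L || reference <= 0) {
    stop("reference must be a single positive number")
  }
  list(percent_change = 100 * (groups - reference) / reference,
       mean_percent_change = 100 * (mean(groups) - reference) / reference,
       point_change = groups - reference,
       mean_point_change = mean(groups - reference))
}
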