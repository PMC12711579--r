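#' Crossover interference analysis of an F2 population
#'
#' The package's main entry point. From a marker-level F2 genotype table it
#' (1) segments each individual's genotype track and calls crossovers from
#' parental/heterozygous genotype transitions, (2) extracts cis-double-
#' crossovers (parental-heterozygous-parental triples), (3) builds the
#' resampled random-placement expected distance distribution, bins both
#' series and fits gamma distributions, (4) runs the permutation test for
#' chromosome-end bias of short cis-DCOs, (5) computes coefficient-of-
#' coincidence profiles in both the classical interval-pair construction and
#' the distance-histogram construction, and (6) produces windowed and
#' arm-scaled crossover landscapes plus arm/pericentromere counts. With a
#' `group` assignment the analysis is run per genotype group and the groups
#' are compared with Kruskal-Wallis/Dunn and Wilcoxon rank tests.
#'
#' @param genotypes a genotype data.frame (`individual`, `chrom`,
#'   `position`, `genotype`) or an `"f2_population"` from
#'   [simulate_f2_population()].
#' @param genome a [genome_map]; taken from the population when `genotypes`
#'   is an `"f2_population"`.
#' @param group optional named vector or two-column data.frame
#'   (`individual`, `group`) assigning individuals to genotype groups;
#'   default: one group `"all"`.
#' @param params an [analysis_params] list.
#' @return An object of class `"co_interference"`: a list with `groups`
#'   (per-group result lists), `comparison` (group tests or `NULL`),
#'   `genome`, `params`, `call`. Each group result holds `individuals`,
#'   `segments`, `events`, `counts`, `cis_dcos`, `distances`
#'   (a `"distance_distribution"`), `position_test`, `coc_interval_pairs`,
#'   `coc_distance_histogram`, `landscape`, `landscape_scaled`, `regions`,
#'   `n_individuals`, `mean_co`.
#' @seealso [simulate_f2_population()], [coc_profile()], [fit_gamma()]
#' @examples
#' gm <- synthetic_genome(2, 20e6)
#' pop <- simulate_f2_population(sim_config(gm, model = "poisson",
#'   co_intensity = 1, n_individuals = 60, marker_spacing = 2e5, seed = 7))
#' fit <- co_interference(pop, params = analysis_params(n_perm = 100, seed = 1))
#' print(fit)
#' @export
co_interference <- function(genotypes, genome = NULL, group = NULL,
                            params = analysis_params()) {
  cl <- match.call()
  if (inherits(genotypes, "f2_population")) {
    if (is.null(genome)) genome <- genotypes$genome
    genotypes <- genotypes$genotypes
  }
  if (is.null(genome)) stop("a genome map is required")
  genome <- validate_genome_map(genome)
  stopifnot(inherits(params, "analysis_params"))
  if (!is.null(params$seed)) set.seed(params$seed)

  individuals <- unique(genotypes$individual)
  grp <- normalise_group(group, individuals)
  res <- lapply(split(individuals, grp[match(individuals, names(grp))]),
                function(ids) {
    analyse_group(genotypes[genotypes$individual %in% ids, , drop = FALSE],
                  ids, genome, params)
  })

  comparison <- NULL
  if (length(res) >= 2L) {
    counts <- do.call(rbind, lapply(names(res), function(gname) {
      rc <- res[[gname]]$regions
      rc$group <- gname
      rc
    }))
    comparison <- compare_groups(counts)
  }
  structure(list(groups = res, comparison = comparison, genome = genome,
                 params = params, call = cl),
            class = "co_interference")
}

normalise_group <- function(group, individuals) {
  if (is.null(group)) {
    grp <- rep("all", length(individuals))
    names(grp) <- individuals
    return(grp)
  }
  if (is.data.frame(group)) {
    grp <- as.character(group$group)
    names(grp) <- group$individual
  } else {
    grp <- as.character(group)
    names(grp) <- names(group)
  }
  miss <- setdiff(as.character(individuals), names(grp))
  if (length(miss)) stop("no group assignment for individuals: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  grp
}

analyse_group <- function(genotypes, ids, genome, params) {
  segments <- segment_population(genotypes, min_support = params$min_support)
  events <- call_crossovers(segments)
  counts <- per_individual_counts(events, ids, genome)
  cis_dcos <- extract_cis_dcos(segments, genome)
  expected <- expected_distance_sample(events, genome, n_pairs = params$n_pairs)
  distances <- if (nrow(cis_dcos) > 0L) {
    bin_distances(cis_dcos$distance,
                  if (is.null(expected)) numeric(0) else expected$distance,
                  bin_width = params$bin_width)
  } else NULL
  position_test <- tryCatch(
    short_dco_position_test(cis_dcos, genome, n_perm = params$n_perm,
                            short_dco_max = params$short_dco_max),
    error = function(e) NULL)
  coc_ip <- coc_interval_pairs(events, genome, ids,
                               bin_width = params$bin_width)
  coc_dh <- tryCatch(
    coc_profile(events, genome, ids, bin_width = params$bin_width,
                mode = "distance_histogram", segments = segments,
                n_pairs = params$n_pairs),
    error = function(e) NULL)
  landscape <- window_co_frequency(events, genome, length(ids),
                                   window_bp = params$window_bp)
  list(individuals = ids,
       segments = segments, events = events, counts = counts,
       cis_dcos = cis_dcos, distances = distances,
       position_test = position_test,
       coc_interval_pairs = coc_ip,
       coc_distance_histogram = coc_dh,
       landscape = landscape,
       landscape_scaled = scaled_landscape(landscape, genome,
                                           n_bins = params$scaled_bins),
       regions = region_counts(events, genome, ids),
       n_individuals = length(ids),
       mean_co = nrow(events) / length(ids))
}

#' @export
print.co_interference <- function(x, digits = 3, ...) {
  cat("Crossover interference analysis\n")
  cat("  chromosomes:", nrow(x$genome), " groups:",
      paste(names(x$groups), collapse = ", "), "\n")
  for (gname in names(x$groups)) {
    g <- x$groups[[gname]]
    cat(sprintf("  [%s] %d individuals, %d COs (%.2f per individual), %d cis-DCOs\n",
                gname, g$n_individuals, nrow(g$events), g$mean_co,
                nrow(g$cis_dcos)))
    short <- g$coc_interval_pairs$coc[1]
    if (length(short)) {
      cat(sprintf("        CoC (interval pairs), shortest class: %.*f\n",
                  digits, short))
    }
  }
  if (!is.null(x$comparison)) {
    cat(sprintf("  Kruskal-Wallis on totals: p = %.3g\n", x$comparison$kruskal$p))
  }
  invisible(x)
}

#' @export
summary.co_interference <- function(object, ...) {
  rows <- lapply(names(object$groups), function(gname) {
    g <- object$groups[[gname]]
    of <- g$distances$observed_fit
    data.frame(group = gname,
               n_individuals = g$n_individuals,
               n_co = nrow(g$events),
               mean_co = g$mean_co,
               n_cis_dco = nrow(g$cis_dcos),
               median_dco_distance = if (!is.null(g$distances))
                 g$distances$observed_median else NA_real_,
               gamma_shape = if (!is.null(of)) of$shape else NA_real_,
               coc_shortest = g$coc_interval_pairs$coc[1],
               coc_mean = mean(g$coc_interval_pairs$coc, na.rm = TRUE),
               p_end_bias = if (!is.null(g$position_test))
                 g$position_test$p_one_sided else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- list(table = do.call(rbind, rows), comparison = object$comparison)
  class(out) <- "summary.co_interference"
  out
}

#' @export
print.summary.co_interference <- function(x, ...) {
  cat("Crossover interference analysis: group summary\n")
  print(x$table, row.names = FALSE, digits = 4)
  if (!is.null(x$comparison)) {
    cat("\n")
    print(x$comparison)
  }
  invisible(x)
}

#' Gamma-fit coefficients of a crossover interference analysis
#'
#' Returns the maximum-likelihood gamma parameters fitted to the observed
#' cis-DCO distances and to the resampled expected distances, per group.
#'
#' @param object a `"co_interference"` object.
#' @param ... unused.
#' @return A data.frame with columns `group`, `series`, `shape`, `rate`.
#' @export
coef.co_interference <- function(object, ...) {
  rows <- list()
  for (gname in names(object$groups)) {
    d <- object$groups[[gname]]$distances
    if (is.null(d)) next
    for (series in c("observed", "expected")) {
      f <- d[[paste0(series, "_fit")]]
      if (is.null(f)) next
      rows[[length(rows) + 1L]] <- data.frame(group = gname, series = series,
                                              shape = f$shape, rate = f$rate,
                                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Plot a crossover interference analysis
#'
#' Base-graphics panels: (1) observed vs expected cis-DCO distance
#' histograms with gamma-fit curves, (2) the CoC profile by inter-interval
#' distance with the independence level at 1, (3) the physical crossover
#' landscape per chromosome.
#'
#' @param x a `"co_interference"` object.
#' @param which subset of panels, any of `1:3`.
#' @param group group name (default: first group).
#' @param ... passed to the underlying plot calls.
#' @export
plot.co_interference <- function(x, which = 1:3, group = NULL, ...) {
  gname <- group %||% names(x$groups)[1]
  g <- x$groups[[gname]]
  if (is.null(g)) stop("unknown group: ", gname)
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  mb <- 1e6
  if (1 %in% which && !is.null(g$distances)) {
    d <- g$distances
    ylim <- range(0, d$observed_freq, d$expected_freq)
    graphics::plot(d$mids / mb, d$observed_freq, type = "h", lwd = 6,
                   col = "steelblue", ylim = ylim,
                   xlab = "cis-DCO distance (Mb)", ylab = "frequency",
                   main = paste0(gname, ": inter-CO distances"), ...)
    graphics::points(d$mids / mb + 0.35, d$expected_freq, type = "h",
                     lwd = 6, col = "grey60")
    xx <- seq(min(d$breaks), max(d$breaks), length.out = 200)
    for (series in c("observed", "expected")) {
      f <- d[[paste0(series, "_fit")]]
      if (is.null(f)) next
      graphics::lines(xx / mb,
                      stats::dgamma(xx, f$shape, f$rate) * d$bin_width,
                      col = if (series == "observed") "steelblue4" else "grey40",
                      lwd = 2)
    }
  }
  if (2 %in% which) {
    cc <- g$coc_interval_pairs
    graphics::plot(cc$distance_bp / mb, cc$coc, type = "b", pch = 16,
                   xlab = "distance between intervals (Mb)", ylab = "CoC",
                   main = paste0(gname, ": coefficient of coincidence"), ...)
    graphics::abline(h = 1, lty = 2, col = "grey50")
  }
  if (3 %in% which) {
    ls <- g$landscape
    chroms <- unique(ls$chrom)
    graphics::plot(NA, xlim = c(0, max(ls$end) / mb),
                   ylim = range(0, ls$freq_per_individual),
                   xlab = "position (Mb)", ylab = "COs per individual",
                   main = paste0(gname, ": crossover landscape"), ...)
    for (k in seq_along(chroms)) {
      sub <- ls[ls$chrom == chroms[k], ]
      graphics::lines((sub$start + sub$end - 1) / 2 / mb,
                      sub$freq_per_individual, col = k)
    }
    graphics::legend("topright", legend = chroms, col = seq_along(chroms),
                     lty = 1, cex = 0.7, bty = "n")
  }
  invisible(x)
}
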