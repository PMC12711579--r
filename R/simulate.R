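#' Simulation configuration for synthetic F2 meiosis
#'
#' Bundles the parameters of the synthetic meiosis generator. Crossovers are
#' placed per gamete per chromosome by one of three generative models:
#'
#' * `"poisson"` — no interference: the gamete's crossover count is
#'   Poisson(`co_intensity`) and positions are i.i.d. uniform (optionally
#'   end-biased).
#' * `"gamma_renewal"` — positive interference: chiasma positions on the
#'   bivalent follow a stationary renewal process with gamma inter-event
#'   distances (shape `nu`, rate `2 * co_intensity * nu / length`, so the
#'   bivalent carries `2 * co_intensity` chiasmata on average); each chiasma
#'   is retained on the transmitted chromatid with probability 1/2, giving a
#'   gamete mean of `co_intensity`. `nu = 1` reduces to Poisson placement;
#'   larger `nu` spaces crossovers more evenly.
#' * `"clustered"` — negative interference: a Neyman–Scott cluster process.
#'   Cluster seeds are Poisson(`cluster_rate`) and uniform; each seed spawns
#'   `1 + Poisson(cluster_size_mean - 1)` crossovers at Laplace(`cluster_scale`)
#'   offsets around the seed, clipped to the chromosome.
#'
#' @param genome a [genome_map].
#' @param co_intensity expected crossovers per gamete per chromosome (> 0).
#' @param model `"gamma_renewal"`, `"poisson"` or `"clustered"`.
#' @param nu gamma interference shape (>= 1; `gamma_renewal` only).
#' @param cluster_rate expected cluster seeds per gamete per chromosome
#'   (`clustered` only; defaults to `co_intensity / cluster_size_mean` so the
#'   mean crossover count matches `co_intensity`).
#' @param cluster_size_mean mean crossovers per cluster (>= 1).
#' @param cluster_scale Laplace scale of within-cluster offsets, base pairs.
#' @param obligate_co if `TRUE`, enforce at least one chiasma per bivalent
#'   (gamma mode) or at least one crossover per gamete (other modes) by
#'   rejection sampling (capped at 1000 redraws).
#' @param end_bias optional exponent in `[0, 1)`; when positive, uniform
#'   placement is replaced by a density proportional to
#'   `(distance to nearest chromosome end / length)^(-end_bias)`, skewing
#'   crossovers toward the telomeres (poisson mode and cluster seeds).
#' @param n_individuals number of F2 individuals to simulate.
#' @param marker_spacing mean inter-marker distance in base pairs; markers
#'   are laid down once per population by a Poisson process.
#' @param missing_rate fraction of marker genotype calls replaced by `NA`.
#' @param seed RNG seed for [simulate_f2_population()].
#' @return A list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(synthetic_genome(2, 10e6), co_intensity = 1,
#'                   model = "poisson", n_individuals = 10, seed = 1)
#' @export
sim_config <- function(genome,
                       co_intensity = 0.84,
                       model = c("gamma_renewal", "poisson", "clustered"),
                       nu = 5,
                       cluster_rate = NULL,
                       cluster_size_mean = 2,
                       cluster_scale = 1e6,
                       obligate_co = FALSE,
                       end_bias = 0,
                       n_individuals = 100,
                       marker_spacing = 5e4,
                       missing_rate = 0,
                       seed = NULL) {
  model <- match.arg(model)
  genome <- validate_genome_map(genome)
  stopifnot(co_intensity > 0, nu >= 1, cluster_size_mean >= 1,
            cluster_scale > 0, missing_rate >= 0, missing_rate < 1,
            marker_spacing > 0, n_individuals >= 1,
            end_bias >= 0, end_bias < 1)
  if (is.null(cluster_rate)) cluster_rate <- co_intensity / cluster_size_mean
  stopifnot(cluster_rate > 0)
  structure(list(genome = genome, co_intensity = co_intensity, model = model,
                 nu = nu, cluster_rate = cluster_rate,
                 cluster_size_mean = cluster_size_mean,
                 cluster_scale = cluster_scale, obligate_co = obligate_co,
                 end_bias = end_bias, n_individuals = n_individuals,
                 marker_spacing = marker_spacing, missing_rate = missing_rate,
                 seed = seed),
            class = "sim_config")
}

# Equilibrium (forward-recurrence) CDF of a stationary renewal process with
# gamma(shape, rate) inter-event distances:
#   F_e(x) = (rate/shape) * x * (1 - pgamma(x, shape, rate))
#            + pgamma(x, shape + 1, rate)
gamma_equilibrium_cdf <- function(x, shape, rate) {
  (rate / shape) * x * stats::pgamma(x, shape, rate, lower.tail = FALSE) +
    stats::pgamma(x, shape + 1, rate)
}

# One draw from the equilibrium distribution, truncated knowledge: values
# beyond `cap` are reported as Inf (they imply no event on the chromosome).
requilibrium_gamma <- function(shape, rate, cap) {
  u <- stats::runif(1)
  if (u >= gamma_equilibrium_cdf(cap, shape, rate)) return(Inf)
  stats::uniroot(function(x) gamma_equilibrium_cdf(x, shape, rate) - u,
                 lower = 0, upper = cap, tol = 1e-9 * cap)$root
}

rlaplace <- function(n, scale) {
  u <- stats::runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

# Positions with density ~ (min(x, L - x)/L)^(-beta), beta in [0,1):
# exact inverse-CDF on each half.
r_end_biased <- function(n, len, beta) {
  if (beta <= 0) return(stats::runif(n, 0, len))
  side <- stats::runif(n) < 0.5
  x <- (len / 2) * stats::runif(n)^(1 / (1 - beta))
  ifelse(side, x, len - x)
}

#' Chiasma positions on one bivalent (stationary gamma renewal)
#'
#' Draws the chiasma positions of a single bivalent under the stationary
#' gamma renewal model: first event from the closed-form equilibrium
#' (forward-recurrence) distribution, subsequent inter-event distances i.i.d.
#' gamma(`nu`, `2 * co_intensity * nu / length`).
#'
#' @param length chromosome length, base pairs.
#' @param co_intensity expected crossovers per gamete (bivalent mean is twice this).
#' @param nu gamma shape (>= 1).
#' @return Numeric vector of strictly increasing chiasma positions in
#'   `(1, length)` (possibly empty).
#' @export
simulate_bivalent <- function(length, co_intensity, nu) {
  rate <- 2 * co_intensity * nu / length
  x <- requilibrium_gamma(nu, rate, cap = length)
  if (!is.finite(x)) return(numeric(0))
  pos <- x
  repeat {
    gaps <- stats::rgamma(8L, shape = nu, rate = rate)
    nxt <- pos[base::length(pos)] + cumsum(gaps)
    pos <- c(pos, nxt[nxt < length])
    if (any(nxt >= length)) break
  }
  pos[pos > 1 & pos < length]
}

sim_chrom_positions <- function(config, len) {
  switch(config$model,
    poisson = {
      n <- stats::rpois(1, config$co_intensity)
      sort(r_end_biased(n, len, config$end_bias))
    },
    clustered = {
      n_seed <- stats::rpois(1, config$cluster_rate)
      if (n_seed == 0) return(numeric(0))
      seeds <- r_end_biased(n_seed, len, config$end_bias)
      sizes <- 1L + stats::rpois(n_seed, config$cluster_size_mean - 1)
      pos <- rep(seeds, sizes) + rlaplace(sum(sizes), config$cluster_scale)
      pos <- pmin(pmax(pos, 1 + 1e-9), len - 1e-9)
      sort(unique(pos))
    },
    stop("gamma_renewal positions handled by caller")
  )
}

#' Simulate one gamete for one chromosome
#'
#' Applies the generative crossover model of `config` to a single chromosome
#' and returns the transmitted gamete's crossover positions plus its founder
#' haplotype at position 1. In `gamma_renewal` mode the bivalent chiasma
#' positions are drawn first and each chiasma is kept on the gamete with
#' probability 1/2 (chromatid thinning).
#'
#' @param config a [sim_config].
#' @param chrom chromosome name (must exist in `config$genome`).
#' @return A list with elements `founder` (`"P1"` or `"P2"`), `co` (sorted
#'   crossover positions), and, in gamma mode, `chiasmata` (pre-thinning
#'   bivalent positions).
#' @export
simulate_gamete <- function(config, chrom) {
  len <- config$genome$length[genome_row(config$genome, chrom)]
  founder <- if (stats::runif(1) < 0.5) "P1" else "P2"
  if (config$model == "gamma_renewal") {
    for (try in seq_len(1000L)) {
      chi <- simulate_bivalent(len, config$co_intensity, config$nu)
      if (!config$obligate_co || length(chi) >= 1L) break
      if (try == 1000L) stop("obligate crossover: 1000 bivalent redraws exhausted")
    }
    keep <- stats::runif(length(chi)) < 0.5
    return(list(founder = founder, co = chi[keep], chiasmata = chi))
  }
  for (try in seq_len(1000L)) {
    co <- sim_chrom_positions(config, len)
    if (!config$obligate_co || length(co) >= 1L) break
    if (try == 1000L) stop("obligate crossover: 1000 redraws exhausted")
  }
  list(founder = founder, co = co)
}

#' Simulate one F2 individual (two independent meioses)
#'
#' An F2 individual inherits one recombinant gamete from each F1 parent;
#' the two meioses are independent and share the same configuration.
#'
#' @param config a [sim_config].
#' @return A list with one element per chromosome, each holding `maternal`
#'   and `paternal` gamete truths (see [simulate_gamete()]).
#' @export
simulate_f2_individual <- function(config) {
  out <- lapply(config$genome$chrom, function(ch) {
    list(maternal = simulate_gamete(config, ch),
         paternal = simulate_gamete(config, ch))
  })
  names(out) <- config$genome$chrom
  out
}

#' Emit marker genotypes for one individual on one chromosome
#'
#' The genotype at a marker is the unordered pair of gamete alleles there:
#' `AA` = both P1, `BB` = both P2, `AB` = heterozygous. A gamete's allele at
#' position x is its founder haplotype flipped once per crossover left of x.
#' Calls are independently replaced by `NA` with probability `missing_rate`.
#'
#' @param maternal,paternal gamete truths (lists with `founder`, `co`).
#' @param positions sorted marker positions, base pairs.
#' @param missing_rate per-call dropout probability.
#' @return Character vector of `"AA"`, `"AB"`, `"BB"` or `NA`.
#' @export
genotype_markers <- function(maternal, paternal, positions, missing_rate = 0) {
  if (is.unsorted(positions)) stop("marker positions must be sorted")
  a1 <- gamete_allele(maternal, positions)
  a2 <- gamete_allele(paternal, positions)
  g <- c("AA", "AB", "BB")[a1 + a2 + 1L]
  if (missing_rate > 0) g[stats::runif(length(g)) < missing_rate] <- NA_character_
  g
}

# 0 = P1 allele, 1 = P2 allele at each position
gamete_allele <- function(gamete, positions) {
  base <- if (gamete$founder == "P1") 0L else 1L
  (base + findInterval(positions, gamete$co)) %% 2L
}

#' Simulate a full F2 population with crossover truth
#'
#' Lays down a shared Poisson marker grid (mean spacing
#' `config$marker_spacing`), simulates `config$n_individuals` F2 individuals
#' and emits their marker genotypes. The generating crossover positions are
#' retained as a truth archive so caller accuracy can be audited.
#'
#' @param config a [sim_config]. If `config$seed` is set the population is
#'   reproducible: the same config yields byte-identical output.
#' @return A list of class `"f2_population"`:
#'   \describe{
#'     \item{genotypes}{data.frame `individual`, `chrom`, `position`, `genotype`.}
#'     \item{truth}{list with `tracks` (individual, parent, chrom, founder,
#'       n_co) and `crossovers` (individual, parent, chrom, position).}
#'     \item{markers}{named list of marker positions per chromosome.}
#'     \item{genome, config}{inputs echoed.}
#'   }
#' @export
simulate_f2_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  genome <- config$genome
  markers <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    n_guess <- stats::qpois(1 - 1e-9, len / config$marker_spacing) + 10L
    pos <- cumsum(stats::rexp(n_guess, rate = 1 / config$marker_spacing))
    pos <- round(pos[pos <= len])
    sort(unique(pos[pos >= 1]))
  })
  names(markers) <- genome$chrom
  n <- config$n_individuals
  n_mark <- vapply(markers, length, integer(1))
  m_total <- sum(n_mark)

  geno <- character(n * m_total)
  n_tracks <- n * 2L * nrow(genome)
  tr_ind <- integer(n_tracks); tr_par <- character(n_tracks)
  tr_chr <- character(n_tracks); tr_fdr <- character(n_tracks)
  tr_nco <- integer(n_tracks)
  co_list <- vector("list", n_tracks)
  k <- 0L
  for (ind in seq_len(n)) {
    off <- (ind - 1L) * m_total
    pos0 <- 0L
    for (ci in seq_len(nrow(genome))) {
      ch <- genome$chrom[ci]
      gm <- simulate_gamete(config, ch)
      gp <- simulate_gamete(config, ch)
      g <- genotype_markers(gm, gp, markers[[ci]], config$missing_rate)
      geno[(off + pos0 + 1L):(off + pos0 + n_mark[ci])] <- g
      pos0 <- pos0 + n_mark[ci]
      for (tag in c("maternal", "paternal")) {
        gam <- if (tag == "maternal") gm else gp
        k <- k + 1L
        tr_ind[k] <- ind; tr_par[k] <- tag; tr_chr[k] <- ch
        tr_fdr[k] <- gam$founder; tr_nco[k] <- length(gam$co)
        co_list[[k]] <- gam$co
      }
    }
  }
  tracks <- data.frame(individual = tr_ind, parent = tr_par, chrom = tr_chr,
                       founder = tr_fdr, n_co = tr_nco, stringsAsFactors = FALSE)
  lens <- lengths(co_list)
  crossovers <- data.frame(
    individual = rep(tr_ind, lens),
    parent = rep(tr_par, lens),
    chrom = rep(tr_chr, lens),
    position = unlist(co_list, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  genotypes <- data.frame(
    individual = rep(seq_len(n), each = m_total),
    chrom = rep(rep(genome$chrom, n_mark), n),
    position = rep(unlist(markers, use.names = FALSE), n),
    genotype = geno,
    stringsAsFactors = FALSE
  )
  structure(list(genotypes = genotypes,
                 truth = list(tracks = tracks, crossovers = crossovers),
                 markers = markers, genome = genome, config = config),
            class = "f2_population")
}

#' @export
print.f2_population <- function(x, ...) {
  cat("Synthetic F2 population:", x$config$n_individuals, "individuals,",
      nrow(x$genome), "chromosomes,", sum(lengths(x$markers)), "markers\n")
  cat("  model:", x$config$model,
      if (x$config$model == "gamma_renewal") paste0("(nu = ", x$config$nu, ")") else "",
      "\n")
  cat("  true crossovers:", nrow(x$truth$crossovers),
      sprintf("(%.2f per individual)",
              nrow(x$truth$crossovers) / x$config$n_individuals), "\n")
  invisible(x)
}
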