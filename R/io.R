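#' Read and write marker genotype tables
#'
#' The interchange format is a UTF-8 TSV with header
#' `individual chrom position genotype`; genotypes are `AA`, `AB`, `BB` or
#' the missing token `NA`. Rows are validated and sorted by
#' (individual, chrom, position); duplicate marker rows or unknown genotype
#' tokens are errors (reported with their line number).
#'
#' @param path file path.
#' @return `read_genotype_table()`: a validated, sorted data.frame with
#'   columns `individual`, `chrom`, `position`, `genotype`.
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) stop("genotype table not found: ", path)
  g <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = "NA", colClasses = NA)
  need <- c("individual", "chrom", "position", "genotype")
  miss <- setdiff(need, names(g))
  if (length(miss)) stop("genotype table is missing columns: ",
                         paste(miss, collapse = ", "))
  g$chrom <- as.character(g$chrom)
  g$genotype <- as.character(g$genotype)
  bad <- !is.na(g$genotype) & !g$genotype %in% c("AA", "AB", "BB")
  if (any(bad)) {
    stop("invalid genotype token '", g$genotype[which(bad)[1]],
         "' at line ", which(bad)[1] + 1L)  # +1 for the header line
  }
  key <- paste(g$individual, g$chrom, g$position)
  if (anyDuplicated(key)) {
    stop("duplicate (individual, chrom, position) row at line ",
         which(duplicated(key))[1] + 1L)
  }
  g <- g[order(g$individual, g$chrom, g$position), need, drop = FALSE]
  rownames(g) <- NULL
  g
}

#' @rdname read_genotype_table
#' @param genotypes data.frame with columns `individual`, `chrom`,
#'   `position`, `genotype`.
#' @export
write_genotype_table <- function(genotypes, path) {
  utils::write.table(genotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read and write crossover truth archives
#'
#' The truth archive records each simulated gamete track as
#' `individual parent chrom founder co_positions`, with `co_positions` a
#' comma-joined list of base-pair crossover positions (empty for
#' crossover-free tracks).
#'
#' @param truth a truth list (`tracks` + `crossovers`) from
#'   [simulate_f2_population()].
#' @param path file path.
#' @export
write_truth_archive <- function(truth, path) {
  tr <- truth$tracks
  key <- paste(tr$individual, tr$parent, tr$chrom)
  co_key <- paste(truth$crossovers$individual, truth$crossovers$parent,
                  truth$crossovers$chrom)
  pos <- split(truth$crossovers$position, factor(co_key, levels = unique(key)))
  joined <- vapply(pos, function(p) paste(format(p, trim = TRUE, digits = 15),
                                          collapse = ","), character(1))
  joined[is.na(joined) | joined == "NA"] <- ""
  out <- data.frame(individual = tr$individual, parent = tr$parent,
                    chrom = tr$chrom, founder = tr$founder,
                    co_positions = joined[key], stringsAsFactors = FALSE)
  out$co_positions[is.na(out$co_positions)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_archive
#' @return `read_truth_archive()`: a list with `tracks` and `crossovers`
#'   data.frames matching the in-memory truth format.
#' @export
read_truth_archive <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(co_positions = "character"))
  x$co_positions[is.na(x$co_positions)] <- ""
  pos <- lapply(strsplit(x$co_positions, ","), function(p) as.numeric(p[p != ""]))
  lens <- lengths(pos)
  list(tracks = data.frame(individual = x$individual, parent = x$parent,
                           chrom = x$chrom, founder = x$founder,
                           n_co = lens, stringsAsFactors = FALSE),
       crossovers = data.frame(individual = rep(x$individual, lens),
                               parent = rep(x$parent, lens),
                               chrom = rep(x$chrom, lens),
                               position = unlist(pos, use.names = FALSE),
                               stringsAsFactors = FALSE))
}

#' Run the full crossover-interference pipeline and write its outputs
#'
#' Thin orchestration over the package's analysis functions: obtain
#' genotypes (from a TSV or by simulation), run [co_interference()], and
#' write the result tables (`co_events.tsv`, `cis_dco.tsv`,
#' `distance_distribution.tsv`, `coc_*.tsv`, `landscape.tsv`,
#' `landscape_scaled.tsv`, `region_counts.tsv`) plus a `stats.json` report
#' carrying the parameter echo, seed and headline statistics. Outputs are
#' deterministic: rerunning with the same configuration and seed reproduces
#' them byte for byte.
#'
#' @param config a named list (or path to a YAML/JSON file encoding one)
#'   with elements: `genome` (a [genome_map] or path), exactly one of
#'   `input` (genotype TSV path) or `simulate` (argument list for
#'   [sim_config()], `genome` added automatically), optional `params`
#'   (argument list for [analysis_params()]), optional `seed`.
#' @param out_dir output directory (created if needed).
#' @return The [co_interference] object, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$input) == is.null(config$simulate)) {
    stop("config must set exactly one of `input` (genotype TSV) or `simulate`")
  }
  genome <- config$genome
  if (is.character(genome)) genome <- read_genome_map(genome)
  params <- do.call(analysis_params, config$params %||% list())
  if (!is.null(config$seed)) params$seed <- config$seed

  if (!is.null(config$input)) {
    if (is.null(genome)) stop("config$genome is required with a genotype input")
    genotypes <- read_genotype_table(config$input)
    pop <- NULL
  } else {
    sim_args <- config$simulate
    if (is.null(sim_args$genome)) sim_args$genome <- genome
    if (is.null(sim_args$genome)) stop("config$genome is required")
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    scfg <- do.call(sim_config, sim_args)
    pop <- simulate_f2_population(scfg)
    genome <- scfg$genome
    genotypes <- pop$genotypes
  }

  fit <- co_interference(genotypes, genome, params = params)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.table(x, file.path(out_dir, f), sep = "\t",
                                         quote = FALSE, row.names = FALSE,
                                         na = "NA")
  if (!is.null(pop)) {
    write_genotype_table(pop$genotypes, file.path(out_dir, "genotypes.tsv"))
    write_truth_archive(pop$truth, file.path(out_dir, "truth.tsv"))
  }
  res <- fit$groups[[1]]
  w(res$events, "co_events.tsv")
  w(res$cis_dcos, "cis_dco.tsv")
  dd <- res$distances
  w(data.frame(bin_start = dd$breaks[-length(dd$breaks)],
               bin_end = dd$breaks[-1],
               observed_count = dd$observed_counts,
               observed_freq = dd$observed_freq,
               expected_count = dd$expected_counts,
               expected_freq = dd$expected_freq),
    "distance_distribution.tsv")
  w(as.data.frame(res$coc_interval_pairs), "coc_interval_pairs.tsv")
  if (!is.null(res$coc_distance_histogram)) {
    w(as.data.frame(res$coc_distance_histogram), "coc_distance_histogram.tsv")
  }
  w(res$landscape, "landscape.tsv")
  w(res$landscape_scaled, "landscape_scaled.tsv")
  w(res$regions, "region_counts.tsv")

  stats <- list(
    params = unclass(params),
    seed = params$seed,
    package_version = as.character(utils::packageVersion("meioco")),
    n_individuals = res$n_individuals,
    n_crossovers = nrow(res$events),
    mean_co_per_individual = res$mean_co,
    n_cis_dco = nrow(res$cis_dcos),
    observed_median_distance = dd$observed_median,
    expected_median_distance = dd$expected_median,
    gamma_observed = if (!is.null(dd$observed_fit))
      dd$observed_fit[c("shape", "rate", "loglik")] else NULL,
    gamma_expected = if (!is.null(dd$expected_fit))
      dd$expected_fit[c("shape", "rate", "loglik")] else NULL,
    short_dco_test = if (!is.null(res$position_test))
      res$position_test[c("observed_mean", "p_one_sided", "p_two_sided",
                          "n_events", "n_perm")] else NULL
  )
  jsonlite::write_json(stats, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(fit)
}

read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}
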