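#' Genome map: chromosome geometry for crossover analysis
#'
#' A genome map records, per chromosome, its length, the centromere midpoint
#' and a pericentromere interval. It is the coordinate authority for region
#' classification, arm scaling and window partitioning. Pericentromere
#' intervals are supplied by the user (in real data they are typically
#' delimited by above-average DNA methylation); they are never inferred here.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer-ish vector of chromosome lengths in base pairs.
#' @param centromere centromere midpoint per chromosome, in base pairs.
#' @param peri_start,peri_end closed pericentromere interval per chromosome,
#'   in base pairs, with `1 <= peri_start < peri_end <= length` and
#'   `peri_start <= centromere <= peri_end`.
#' @return A `data.frame` of class `"genome_map"` with columns
#'   `chrom`, `length`, `centromere`, `peri_start`, `peri_end`.
#' @examples
#' gm <- genome_map("Chr1", 30e6, 15e6, 12e6, 18e6)
#' classify_region("Chr1", 1e6, gm)
#' @export
genome_map <- function(chrom, length, centromere, peri_start, peri_end) {
  chrom <- as.character(chrom)
  gm <- data.frame(
    chrom = chrom,
    length = as.numeric(length),
    centromere = as.numeric(centromere),
    peri_start = as.numeric(peri_start),
    peri_end = as.numeric(peri_end),
    stringsAsFactors = FALSE
  )
  validate_genome_map(gm)
}

validate_genome_map <- function(gm) {
  stopifnot(is.data.frame(gm))
  need <- c("chrom", "length", "centromere", "peri_start", "peri_end")
  miss <- setdiff(need, names(gm))
  if (length(miss) > 0L) {
    stop("genome map is missing columns: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(gm$chrom)) stop("chromosome names must be unique")
  if (any(gm$length <= 0)) stop("chromosome lengths must be positive")
  bad <- gm$peri_start < 1 | gm$peri_start >= gm$peri_end | gm$peri_end > gm$length
  if (any(bad)) {
    stop("pericentromere intervals must satisfy 1 <= start < end <= length (chrom: ",
         paste(gm$chrom[bad], collapse = ", "), ")")
  }
  bad <- gm$centromere < gm$peri_start | gm$centromere > gm$peri_end
  if (any(bad)) {
    stop("centromere midpoint must lie inside the pericentromere interval (chrom: ",
         paste(gm$chrom[bad], collapse = ", "), ")")
  }
  if (any(gm$centromere <= 1 | gm$centromere >= gm$length)) {
    message("note: centromere at a chromosome end degenerates to a single arm")
  }
  class(gm) <- c("genome_map", "data.frame")
  gm
}

#' Read or write a genome map
#'
#' The on-disk format is a TSV with header
#' `chrom length centromere peri_start peri_end` (base pairs). A JSON file
#' holding an array of per-chromosome objects with the same field names is
#' also accepted by `read_genome_map()`.
#'
#' @param path file path.
#' @return `read_genome_map()` returns a [genome_map]; `write_genome_map()`
#'   returns `path` invisibly.
#' @export
read_genome_map <- function(path) {
  if (!file.exists(path)) stop("genome map file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(path)
    gm <- as.data.frame(x, stringsAsFactors = FALSE)
  } else {
    gm <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  gm$chrom <- as.character(gm$chrom)
  validate_genome_map(gm)
}

#' @rdname read_genome_map
#' @param gm a [genome_map].
#' @export
write_genome_map <- function(gm, path) {
  gm <- validate_genome_map(gm)
  utils::write.table(gm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a synthetic genome map
#'
#' Convenience constructor for simulation studies: `n_chrom` chromosomes of
#' equal length, metacentric centromeres, and pericentromeres occupying a
#' central fraction of each chromosome (default the central 20%).
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in base pairs.
#' @param peri_fraction fraction of each chromosome classed as
#'   pericentromeric, centred on the centromere midpoint.
#' @return A [genome_map].
#' @examples
#' synthetic_genome(5, 30e6)
#' @export
synthetic_genome <- function(n_chrom = 5, chrom_length = 30e6, peri_fraction = 0.2) {
  stopifnot(n_chrom >= 1, chrom_length > 0, peri_fraction > 0, peri_fraction < 1)
  cen <- round(chrom_length / 2)
  half <- round(chrom_length * peri_fraction / 2)
  genome_map(
    chrom = paste0("Chr", seq_len(n_chrom)),
    length = rep(chrom_length, n_chrom),
    centromere = rep(cen, n_chrom),
    peri_start = rep(cen - half, n_chrom),
    peri_end = rep(cen + half, n_chrom)
  )
}

genome_row <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) {
    stop("unknown chromosome: ", paste(unique(chrom[is.na(i)]), collapse = ", "))
  }
  i
}

#' Classify positions as arm or pericentromere
#'
#' A position is pericentromeric iff it lies within the closed pericentromere
#' interval of its chromosome; otherwise it is on an arm.
#'
#' @param chrom chromosome name(s).
#' @param position 1-based position(s) in base pairs (recycled with `chrom`).
#' @param genome a [genome_map].
#' @return Character vector, `"arm"` or `"pericentromere"`.
#' @export
classify_region <- function(chrom, position, genome) {
  i <- genome_row(genome, chrom)
  if (any(position < 1 | position > genome$length[i])) {
    stop("position outside chromosome bounds")
  }
  ifelse(position >= genome$peri_start[i] & position <= genome$peri_end[i],
         "pericentromere", "arm")
}

#' Arm-scaled coordinate: telomere 0, centromere 1
#'
#' Each chromosome arm (left: positions 1..centromere; right:
#' centromere..length) is mapped linearly so 0 is the telomeric end of the
#' arm and 1 is the centromere midpoint. Used to average crossover landscapes
#' across arms of unequal physical length.
#'
#' @inheritParams classify_region
#' @return A `data.frame` with columns `arm` (`"left"`/`"right"`) and
#'   `scaled` in `[0, 1]`.
#' @export
arm_scaled_coordinate <- function(chrom, position, genome) {
  i <- genome_row(genome, chrom)
  len <- genome$length[i]
  cen <- genome$centromere[i]
  if (any(position < 1 | position > len)) stop("position outside chromosome bounds")
  left <- position <= cen
  # degenerate arms (centromere at an end) have zero width; assign the other arm
  left[left & cen <= 1] <- FALSE
  scaled <- ifelse(left,
                   (position - 1) / pmax(cen - 1, 1),
                   (len - position) / pmax(len - cen, 1))
  # exact centromere position maps to 1 on either arm
  scaled[position == cen] <- 1
  data.frame(arm = ifelse(left, "left", "right"), scaled = pmin(pmax(scaled, 0), 1),
             stringsAsFactors = FALSE)
}

#' Partition chromosomes into half-open windows
#'
#' Tiles each chromosome with contiguous half-open windows
#' `[start, start + window_bp)`; the last window is truncated at the
#' chromosome end. Every base `1..length` belongs to exactly one window.
#'
#' @param genome a [genome_map].
#' @param window_bp window width in base pairs (> 0).
#' @return A `data.frame` with columns `chrom`, `window` (1-based index),
#'   `start` (inclusive), `end` (exclusive, capped at `length + 1`).
#' @export
partition_windows <- function(genome, window_bp) {
  if (!is.numeric(window_bp) || length(window_bp) != 1L || window_bp <= 0) {
    stop("window_bp must be a single positive number")
  }
  out <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    starts <- seq(1, len, by = window_bp)
    data.frame(chrom = genome$chrom[i],
               window = seq_along(starts),
               start = starts,
               end = pmin(starts + window_bp, len + 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# window index of a position under width w: positions 1..w -> 1, etc.
window_index <- function(position, window_bp) {
  floor((position - 1) / window_bp) + 1L
}
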