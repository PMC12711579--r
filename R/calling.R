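#' Segment marker genotype tracks
#'
#' Collapses per-marker genotypes into maximal runs of identical genotype
#' (segments), dissolving runs supported by fewer than `min_support` markers.
#' Dissolved markers are ignored and flanking same-genotype segments merge;
#' dissolution repeats until every remaining segment meets the support
#' threshold. This support-threshold caller is a transparent genotype-level
#' stand-in for read-level HMM callers: the threshold absorbs isolated
#' genotyping flicker that would otherwise masquerade as a double crossover.
#'
#' `segment_genotypes()` operates on one track (one individual, one
#' chromosome); `segment_population()` applies the identical algorithm to a
#' whole genotype table at once.
#'
#' @param positions sorted marker positions (base pairs) of one track.
#' @param genotypes character vector (`"AA"`, `"AB"`, `"BB"` or `NA`)
#'   parallel to `positions`; `NA` calls are dropped before segmentation.
#' @param min_support minimum markers per retained segment (>= 1).
#' @return A data.frame with columns `genotype`, `first`, `last` (first/last
#'   supporting marker positions) and `support`; consecutive rows always
#'   differ in genotype. Zero rows if the track is empty or fully dissolved.
#' @examples
#' segment_genotypes(1:5 * 1e5, c("AA", "AA", "AB", "AA", "AA"), min_support = 2)
#' @export
segment_genotypes <- function(positions, genotypes, min_support = 3) {
  stopifnot(length(positions) == length(genotypes))
  if (is.unsorted(positions)) stop("marker positions must be sorted")
  if (length(positions) == 0L) {
    return(data.frame(genotype = character(0), first = numeric(0),
                      last = numeric(0), support = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- data.frame(individual = 1L, chrom = "chr",
                    position = positions, genotype = as.character(genotypes),
                    stringsAsFactors = FALSE)
  seg <- segment_population(tab, min_support = min_support)
  seg[, c("genotype", "first", "last", "support")]
}

#' @rdname segment_genotypes
#' @param genotype_table data.frame with columns `individual`, `chrom`,
#'   `position`, `genotype`, sorted by (individual, chrom, position).
#' @export
segment_population <- function(genotype_table, min_support = 3) {
  stopifnot(min_support >= 1)
  need <- c("individual", "chrom", "position", "genotype")
  miss <- setdiff(need, names(genotype_table))
  if (length(miss)) stop("genotype table is missing columns: ",
                         paste(miss, collapse = ", "))
  g <- genotype_table[!is.na(genotype_table$genotype), need]
  bad <- !g$genotype %in% c("AA", "AB", "BB")
  if (any(bad)) stop("invalid genotype token(s): ",
                     paste(unique(g$genotype[bad]), collapse = ", "))
  empty <- data.frame(individual = g$individual[0], chrom = character(0),
                      genotype = character(0), first = numeric(0),
                      last = numeric(0), support = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(g) == 0L) return(empty)

  n <- nrow(g)
  new_track <- c(TRUE, g$individual[-1] != g$individual[-n] |
                         g$chrom[-1] != g$chrom[-n])
  track_id <- cumsum(new_track)
  boundary <- new_track | c(TRUE, g$genotype[-1] != g$genotype[-n])
  run_id <- cumsum(boundary)
  starts <- which(boundary)
  ends <- c(starts[-1] - 1L, n)
  runs <- data.frame(track = track_id[starts],
                     individual = g$individual[starts],
                     chrom = g$chrom[starts],
                     genotype = g$genotype[starts],
                     first = g$position[starts],
                     last = g$position[ends],
                     support = as.integer(ends - starts + 1L),
                     stringsAsFactors = FALSE)

  # iterative dissolution: drop weak runs, merge same-genotype neighbours
  repeat {
    low <- runs$support < min_support
    if (!any(low)) break
    runs <- runs[!low, , drop = FALSE]
    if (nrow(runs) == 0L) break
    m <- nrow(runs)
    joined <- c(FALSE, runs$track[-1] == runs$track[-m] &
                         runs$genotype[-1] == runs$genotype[-m])
    if (!any(joined)) next
    grp <- cumsum(!joined)
    gstart <- which(!joined)
    gend <- c(gstart[-1] - 1L, m)
    runs <- data.frame(track = runs$track[gstart],
                       individual = runs$individual[gstart],
                       chrom = runs$chrom[gstart],
                       genotype = runs$genotype[gstart],
                       first = runs$first[gstart],
                       last = runs$last[gend],
                       support = as.integer(rowsum(runs$support, grp)[, 1]),
                       stringsAsFactors = FALSE)
  }
  if (nrow(runs) == 0L) return(empty)
  rownames(runs) <- NULL
  runs[, c("individual", "chrom", "genotype", "first", "last", "support")]
}

#' Call crossovers from genotype segments
#'
#' Every adjacent pair of segments on a track yields one crossover event,
#' bounded by the last marker of the preceding segment and the first marker
#' of the following one; the event midpoint is the centre of that interval.
#' A direct `AA`/`BB` adjacency (possible after weak-segment dissolution)
#' implies two allele changes and is emitted as two stacked events sharing
#' the same bounds, flagged `"stacked"`.
#'
#' @param segments output of [segment_population()] (or
#'   [segment_genotypes()] augmented with `individual`/`chrom` columns).
#' @return A data.frame with columns `individual`, `chrom`, `left`, `right`,
#'   `midpoint`, `transition`, `flag`.
#' @export
call_crossovers <- function(segments) {
  if (!all(c("individual", "chrom") %in% names(segments))) {
    segments$individual <- segments$individual %||% 1L
    segments$chrom <- segments$chrom %||% "chr"
  }
  n <- nrow(segments)
  empty <- data.frame(individual = segments$individual[0], chrom = character(0),
                      left = numeric(0), right = numeric(0),
                      midpoint = numeric(0), transition = character(0),
                      flag = character(0), stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  adj <- segments$individual[-n] == segments$individual[-1] &
         segments$chrom[-n] == segments$chrom[-1]
  i <- which(adj)
  if (length(i) == 0L) return(empty)
  from <- segments$genotype[i]
  to <- segments$genotype[i + 1L]
  ev <- data.frame(individual = segments$individual[i],
                   chrom = segments$chrom[i],
                   left = segments$last[i],
                   right = segments$first[i + 1L],
                   midpoint = (segments$last[i] + segments$first[i + 1L]) / 2,
                   transition = paste0(from, "->", to),
                   flag = "", stringsAsFactors = FALSE)
  stopifnot(all(ev$left < ev$right))
  # AA<->BB adjacency: two allele changes => two stacked events
  dbl <- (from == "AA" & to == "BB") | (from == "BB" & to == "AA")
  if (any(dbl)) {
    d <- which(dbl)
    e1 <- ev[d, ]; e2 <- ev[d, ]
    e1$transition <- paste0(from[d], "->AB")
    e2$transition <- paste0("AB->", to[d])
    e1$flag <- e2$flag <- "stacked"
    ev <- rbind(ev[-d, ], e1, e2)
    o <- order(ev$individual, ev$chrom, ev$midpoint)
    ev <- ev[o, ]
  }
  rownames(ev) <- NULL
  ev
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-individual crossover counts
#'
#' Tabulates called crossover events per individual, total and per
#' chromosome, including explicit zero rows for individuals without events.
#'
#' @param events crossover table from [call_crossovers()].
#' @param individuals vector of all individual identifiers in the
#'   population (so non-recombinant individuals appear with count 0).
#' @param genome a [genome_map] (defines chromosome columns).
#' @return A data.frame with one row per individual: `individual`, one count
#'   column per chromosome, and `total`.
#' @export
per_individual_counts <- function(events, individuals, genome) {
  if (length(individuals) == 0L) stop("individuals must be non-empty")
  individuals <- unique(individuals)
  tab <- table(factor(events$individual, levels = individuals),
               factor(events$chrom, levels = genome$chrom))
  out <- data.frame(individual = individuals, stringsAsFactors = FALSE)
  for (ch in genome$chrom) out[[ch]] <- as.integer(tab[, ch])
  out$total <- as.integer(rowSums(tab))
  out
}
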