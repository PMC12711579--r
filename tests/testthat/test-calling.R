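test_that("segmentation collapses runs and dissolves weak segments", {
  seg <- segment_genotypes(c(1, 2, 3, 4) * 1e5, rep("AA", 4), min_support = 1)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$support, 4)
  expect_equal(c(seg$first, seg$last), c(1e5, 4e5))

  # lone AB flicker dissolves, flanking AA segments merge
  seg <- segment_genotypes(c(1, 2, 3, 4, 5) * 1e5,
                           c("AA", "AA", "AB", "AA", "AA"), min_support = 2)
  expect_equal(seg$genotype, "AA")
  expect_equal(seg$support, 4)

  # alternating output, missing dropped
  seg <- segment_genotypes(1:6 * 1e5, c("AA", NA, "AA", "AB", "AB", "BB"),
                           min_support = 1)
  expect_equal(seg$genotype, c("AA", "AB", "BB"))
  expect_true(all(seg$first <= seg$last))

  expect_equal(nrow(segment_genotypes(numeric(0), character(0))), 0)
  expect_error(segment_genotypes(c(2, 1), c("AA", "AA")), "sorted")
  expect_error(segment_genotypes(1:2, c("AC", "AA")), "invalid genotype")
})

test_that("crossover calls bound transitions by flanking markers", {
  segs <- seg_table(c("AA", "AB"), first = c(1e6, 4e6), last = c(3e6, 8e6))
  ev <- call_crossovers(segs)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$left, 3e6)
  expect_equal(ev$right, 4e6)
  expect_equal(ev$midpoint, 3.5e6)
  expect_equal(ev$transition, "AA->AB")

  expect_equal(nrow(call_crossovers(seg_table("AA", 1e6, 9e6))), 0)
})

test_that("AA-BB adjacencies are emitted as two stacked flagged events", {
  segs <- seg_table(c("AA", "BB"), first = c(1e6, 6e6), last = c(5e6, 9e6))
  ev <- call_crossovers(segs)
  expect_equal(nrow(ev), 2)
  expect_true(all(ev$flag == "stacked"))
  expect_equal(sort(ev$transition), c("AA->AB", "AB->BB"))
  expect_equal(unique(ev$midpoint), 5.5e6)
})

test_that("caller equals brute-force adjacent-difference scan at min_support 1", {
  set.seed(41)
  gm <- tiny_genome()
  cfg <- sim_config(gm, co_intensity = 2, model = "poisson", n_individuals = 1)
  for (rep in 1:20) {
    ind <- simulate_f2_individual(cfg)
    pos <- sort(sample(1:10e6, 200))
    g <- genotype_markers(ind$Chr1$maternal, ind$Chr1$paternal, pos)
    seg <- segment_genotypes(pos, g, min_support = 1)
    ev <- call_crossovers(cbind(individual = 1L, chrom = "Chr1", seg))
    bf <- brute_force_events(pos, g)
    # brute force counts AA<->BB steps once; the caller stacks them
    n_bf <- nrow(bf) + sum(abs(match(g[-1], c("AA", "AB", "BB")) -
                               match(g[-length(g)], c("AA", "AB", "BB"))) == 2)
    expect_equal(nrow(ev), n_bf)
    expect_true(all(sort(unique(ev$left)) == sort(unique(bf$left))))
  }
})

test_that("events per track equal segments minus one plus stacked extras", {
  set.seed(42)
  gm <- study_genome(2)
  pop <- simulate_f2_population(sim_config(gm, co_intensity = 1.5,
    model = "poisson", n_individuals = 30, marker_spacing = 1e5, seed = 42))
  seg <- segment_population(pop$genotypes, min_support = 3)
  ev <- call_crossovers(seg)
  n_tracks <- nrow(unique(seg[, c("individual", "chrom")]))
  n_stacked <- sum(ev$flag == "stacked")
  expect_equal(nrow(ev), (nrow(seg) - n_tracks) + n_stacked / 2)
})

test_that("adding markers inside segments never changes the call count", {
  set.seed(43)
  gm <- tiny_genome()
  cfg <- sim_config(gm, co_intensity = 2, model = "poisson", n_individuals = 1)
  for (rep in 1:10) {
    ind <- simulate_f2_individual(cfg)
    pos <- sort(sample(1:10e6, 100))
    g <- genotype_markers(ind$Chr1$maternal, ind$Chr1$paternal, pos)
    seg1 <- segment_genotypes(pos, g, min_support = 1)
    ev1 <- call_crossovers(cbind(individual = 1L, chrom = "Chr1", seg1))
    # super-sample: add markers strictly inside existing segments
    extra <- unlist(lapply(seq_len(nrow(seg1)), function(i) {
      if (seg1$last[i] - seg1$first[i] < 2) return(numeric(0))
      floor(seq(seg1$first[i], seg1$last[i], length.out = 5))
    }))
    pos2 <- sort(unique(c(pos, extra)))
    g2 <- genotype_markers(ind$Chr1$maternal, ind$Chr1$paternal, pos2)
    seg2 <- segment_genotypes(pos2, g2, min_support = 1)
    ev2 <- call_crossovers(cbind(individual = 1L, chrom = "Chr1", seg2))
    expect_equal(nrow(ev2), nrow(ev1))
    # bounds only tighten
    if (nrow(ev1) > 0 && nrow(ev1) == nrow(ev2)) {
      expect_true(all(ev2$right - ev2$left <= ev1$right - ev1$left + 1e-9))
    }
  }
})

test_that("per-individual counts include zeros and conserve totals", {
  gm <- study_genome(2)
  ev <- data.frame(individual = c(1L, 1L, 3L), chrom = c("Chr1", "Chr2", "Chr1"),
                   midpoint = c(1e6, 2e6, 3e6))
  cnt <- per_individual_counts(ev, individuals = 1:4, genome = gm)
  expect_equal(cnt$total, c(2L, 0L, 1L, 0L))
  expect_equal(rowSums(cnt[, gm$chrom]), cnt$total, ignore_attr = TRUE)
  expect_equal(sum(cnt$total), nrow(ev))
  expect_error(per_individual_counts(ev, integer(0), gm), "non-empty")
  empty <- per_individual_counts(ev[0, ], 1:3, gm)
  expect_true(all(empty$total == 0))
})
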