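test_that("cis-DCO extraction follows the parental-het-parental pattern", {
  gm <- tiny_genome()
  # AA [1..2.5]  AB [3.5..7.5]  AA [8.5..10] Mb: transitions at 3 and 8 Mb
  segs <- seg_table(c("AA", "AB", "AA"),
                    first = c(1e6, 3.5e6, 8.5e6),
                    last = c(2.5e6, 7.5e6, 10e6))
  d <- extract_cis_dcos(segs, gm)
  expect_equal(nrow(d), 1)
  expect_equal(d$mid1, 3e6)
  expect_equal(d$mid2, 8e6)
  expect_equal(d$distance, 5e6)
  expect_equal(d$flank, "AA")
  expect_equal(d$midpoint, 5.5e6)
  expect_equal(d$norm_end_dist, min(5.5e6, 10e6 - 5.5e6) / 10e6)

  # trans configuration is excluded
  trans <- seg_table(c("AA", "AB", "BB"),
                     first = c(1e6, 3.5e6, 8.5e6),
                     last = c(2.5e6, 7.5e6, 10e6))
  expect_equal(nrow(extract_cis_dcos(trans, gm)), 0)

  # overlapping triples both reported and flagged
  five <- seg_table(c("AA", "AB", "AA", "AB", "AA"),
                    first = c(1, 2, 4, 6, 8) * 1e6,
                    last = c(1.5, 3.5, 5.5, 7.5, 10) * 1e6)
  d5 <- extract_cis_dcos(five, gm)
  expect_equal(nrow(d5), 2)
  expect_true(all(d5$overlaps))
})

test_that("expected distances are resampled from the pooled midpoints", {
  gm <- tiny_genome()
  ev2 <- data.frame(chrom = "Chr1", midpoint = c(2e6, 7e6))
  set.seed(51)
  s <- expected_distance_sample(ev2, gm, n_pairs = 500)
  expect_true(all(s$distance %in% c(0, 5e6)))

  ev1 <- data.frame(chrom = "Chr1", midpoint = rep(4e6, 10))
  s1 <- expected_distance_sample(ev1, gm, n_pairs = 100)
  expect_true(all(s1$distance == 0))

  expect_warning(expected_distance_sample(
    data.frame(chrom = "Chr1", midpoint = 1e6), gm, n_pairs = 10),
    "skipped")

  # uniform pool: |U1 - U2| is triangular with mean L/3
  set.seed(52)
  L <- 10e6
  pool <- data.frame(chrom = "Chr1", midpoint = runif(5000, 0, L))
  s <- expected_distance_sample(pool, gm, n_pairs = 10000)
  expect_lt(abs(mean(s$distance) - L / 3), 0.01 * L)
})

test_that("distance binning normalizes within each series", {
  d <- bin_distances(c(1e6, 2e6, 4e6), c(1e6, 2e6, 4e6),
                     bin_width = 3.15e6, fit = FALSE)
  expect_equal(d$observed_freq, d$expected_freq)
  expect_equal(sum(d$observed_freq), 1)
  expect_equal(sum(d$expected_freq), 1)

  one <- bin_distances(1e6, numeric(0), bin_width = 3.15e6, fit = FALSE)
  expect_equal(one$observed_counts, 1)
  expect_equal(one$observed_freq, 1)

  set.seed(53)
  x <- rexp(200, 1e-6); y <- rexp(300, 2e-6)
  d <- bin_distances(x, y, bin_width = 1e6, fit = FALSE)
  expect_equal(sum(d$observed_freq), 1, tolerance = 1e-9)
  expect_equal(sum(d$expected_freq), 1, tolerance = 1e-9)
  expect_equal(d$observed_median, median(x))
  expect_error(bin_distances(numeric(0), y), "no observed")
})

test_that("gamma fitting recovers parameters and beats method of moments", {
  set.seed(54)
  x <- rgamma(1000, shape = 2, rate = 4e-7)
  f <- fit_gamma(x)
  expect_lt(abs(f$shape - 2) / 2, 0.1)
  expect_lt(abs(f$rate - 4e-7) / 4e-7, 0.15)
  expect_true(f$converged)

  # exponential data: shape ~ 1
  e <- fit_gamma(rexp(1000, 1e-6))
  expect_lt(abs(e$shape - 1), 0.1)

  # MLE log-likelihood >= method-of-moments log-likelihood
  for (rep in 1:5) {
    x <- rgamma(300, shape = runif(1, 0.8, 6), rate = 10^runif(1, -7, -5))
    f <- fit_gamma(x)
    mom_shape <- mean(x)^2 / var(x)
    mom_rate <- mean(x) / var(x)
    ll_mom <- sum(dgamma(x, mom_shape, mom_rate, log = TRUE))
    expect_gte(f$loglik, ll_mom - 1e-6)
  }

  # zeros are offset by half the minimum positive distance
  fz <- fit_gamma(c(0, 0, rgamma(100, 2, 1e-6)))
  expect_equal(fz$n_zero_offset, 2)

  expect_error(fit_gamma(c(1, 2, 3)), "at least 5")
  expect_error(fit_gamma(rep(5, 10)), "non-degenerate")
})

test_that("positional permutation test behaves at the extremes", {
  gm <- tiny_genome()
  near_end <- data.frame(individual = 1:5, chrom = "Chr1",
                         distance = rep(1e6, 5), midpoint = rep(1, 5))
  set.seed(55)
  t1 <- short_dco_position_test(near_end, gm, n_perm = 499)
  expect_lt(t1$observed_mean, 1e-6)
  expect_lte(t1$p_one_sided, 2 / (1 + 499))

  centre <- data.frame(individual = 1, chrom = "Chr1",
                       distance = 1e6, midpoint = 5e6)
  t2 <- short_dco_position_test(centre, gm, n_perm = 499)
  expect_equal(t2$observed_mean, 0.5)
  expect_gt(t2$p_one_sided, 0.98)
  expect_error(short_dco_position_test(near_end[0, ], gm), "no cis-DCOs")
  # distance filter applies
  far <- data.frame(individual = 1, chrom = "Chr1",
                    distance = 9e6, midpoint = 5e6)
  expect_error(short_dco_position_test(far, gm, short_dco_max = 5e6),
               "no cis-DCOs")
})

test_that("every extracted cis-DCO arises from two same-gamete crossovers", {
  gm <- study_genome(3)
  cfg <- sim_config(gm, co_intensity = 1.2, model = "poisson",
                    n_individuals = 150, marker_spacing = 5e4, seed = 56)
  pop <- simulate_f2_population(cfg)
  seg <- segment_population(pop$genotypes, min_support = 1)
  ev <- call_crossovers(seg)
  dcos <- extract_cis_dcos(seg, gm)
  expect_gt(nrow(dcos), 20)
  tc <- pop$truth$crossovers
  for (i in seq_len(nrow(dcos))) {
    d <- dcos[i, ]
    evs <- ev[ev$individual == d$individual & ev$chrom == d$chrom, ]
    e1 <- evs[abs(evs$midpoint - d$mid1) < 1e-6, ][1, ]
    e2 <- evs[abs(evs$midpoint - d$mid2) < 1e-6, ][1, ]
    parent_of <- function(e) {
      sub <- tc[tc$individual == d$individual & tc$chrom == d$chrom &
                tc$position > e$left & tc$position <= e$right, ]
      odd <- tapply(rep(1, nrow(sub)), factor(sub$parent,
                    levels = c("maternal", "paternal")), sum)
      odd[is.na(odd)] <- 0
      names(odd)[odd %% 2 == 1]
    }
    p1 <- parent_of(e1); p2 <- parent_of(e2)
    expect_length(p1, 1)
    expect_length(p2, 1)
    expect_identical(p1, p2)
  }
})
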