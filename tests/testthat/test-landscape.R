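test_that("window landscapes conserve crossover totals", {
  gm <- study_genome(2)
  expect_true(all(window_co_frequency(data.frame(individual = integer(0),
    chrom = character(0), midpoint = numeric(0)), gm, 10)$count == 0))

  set.seed(71)
  ev <- data.frame(individual = sample(1:50, 400, TRUE),
                   chrom = sample(gm$chrom, 400, TRUE),
                   midpoint = runif(400, 1, 30e6))
  ls <- window_co_frequency(ev, gm, n_individuals = 50)
  expect_equal(sum(ls$count), 400)
  expect_equal(sum(ls$freq_per_individual * 50), 400)
  bad <- ev; bad$midpoint[1] <- 40e6
  expect_error(window_co_frequency(bad, gm, 50), "outside")
})

test_that("end-biased placement enriches the telomeric quartile", {
  gm <- study_genome(3)
  cfg <- sim_config(gm, co_intensity = 1.5, model = "poisson", end_bias = 0.7,
                    n_individuals = 400, marker_spacing = 1e5, seed = 72)
  pop <- simulate_f2_population(cfg)
  ev <- call_crossovers(segment_population(pop$genotypes, min_support = 1))
  ls <- window_co_frequency(ev, gm, 400)
  sc <- scaled_landscape(ls, gm, n_bins = 20)
  tel <- mean(sc$freq[sc$scaled_center < 0.25], na.rm = TRUE)
  cen <- mean(sc$freq[sc$scaled_center > 0.75], na.rm = TRUE)
  expect_gt(tel, cen)
})

test_that("scaled aggregation is invariant to chromosome relabelling", {
  gm <- study_genome(3)
  set.seed(73)
  ev <- data.frame(individual = sample(1:30, 300, TRUE),
                   chrom = sample(gm$chrom, 300, TRUE),
                   midpoint = runif(300, 1, 30e6))
  sc1 <- scaled_landscape(window_co_frequency(ev, gm, 30), gm, n_bins = 25)
  perm <- c(Chr1 = "Chr3", Chr2 = "Chr1", Chr3 = "Chr2")
  ev2 <- ev; ev2$chrom <- unname(perm[ev$chrom])
  sc2 <- scaled_landscape(window_co_frequency(ev2, gm, 30), gm, n_bins = 25)
  expect_equal(sc1$freq, sc2$freq)
})

test_that("region counts split arm and pericentromere conservatively", {
  gm <- tiny_genome()  # peri 4-6 Mb of 10 Mb => 20% of length
  ev_arm <- data.frame(individual = c(1, 2), chrom = "Chr1",
                       midpoint = c(1e6, 9e6))
  rc <- region_counts(ev_arm, gm, individuals = 1:3)
  expect_true(all(rc$pericentromere == 0))
  expect_equal(rc$arm + rc$pericentromere, rc$total)

  set.seed(74)
  ev <- data.frame(individual = sample(1:100, 4000, TRUE), chrom = "Chr1",
                   midpoint = runif(4000, 1, 10e6))
  rc <- region_counts(ev, gm, 1:100)
  expect_equal(rc$arm + rc$pericentromere, rc$total)
  frac <- sum(rc$pericentromere) / sum(rc$total)
  se <- sqrt(0.2 * 0.8 / 4000)
  expect_lt(abs(frac - 0.2), 3 * se)
})

test_that("group comparisons: identical groups are non-significant", {
  base <- data.frame(arm = rep(c(3, 4, 5, 6), 5),
                     pericentromere = rep(1, 20),
                     total = rep(c(4, 5, 6, 7), 5))
  counts <- rbind(cbind(base, group = "a"), cbind(base, group = "b"))
  res <- compare_groups(counts)
  expect_gt(res$dunn$p_adj, 0.99)
  expect_gt(res$wilcoxon$total$p_adj, 0.99)
  expect_error(compare_groups(counts[counts$group == "a", ]), "two groups")
})

test_that("Bonferroni adjustment is min(1, p * n_comparisons)", {
  set.seed(75)
  counts <- data.frame(group = rep(c("a", "b", "c"), each = 30),
                       arm = rpois(90, 6), pericentromere = rpois(90, 1))
  counts$total <- counts$arm + counts$pericentromere
  res <- compare_groups(counts)
  expect_equal(res$dunn$p_adj, pmin(1, res$dunn$p * 3))
  expect_equal(res$wilcoxon$arm$p_adj, pmin(1, res$wilcoxon$arm$p * 3))
})

test_that("wilcoxon p matches brute-force rank enumeration on 3 vs 3", {
  x <- c(1.3, 2.7, 3.1); y <- c(4.2, 5.9, 8.8)
  counts <- data.frame(group = rep(c("a", "b"), each = 3),
                       arm = c(x, y), pericentromere = 0, total = c(x, y))
  res <- compare_groups(counts)
  # enumerate all 20 assignments of ranks to group a
  vals <- c(x, y); combs <- combn(6, 3)
  W_obs <- sum(rank(vals)[1:3]) - 3 * 4 / 2
  W_all <- apply(combs, 2, function(i) sum(rank(vals)[i]) - 6)
  p_exact <- mean(abs(W_all - 4.5) >= abs(W_obs - 4.5))
  expect_equal(res$wilcoxon$total$p, p_exact)
})

test_that("Dunn z agrees with Kruskal-Wallis in the two-group case", {
  set.seed(76)
  counts <- data.frame(group = rep(c("a", "b"), each = 25),
                       arm = 0, pericentromere = 0,
                       total = c(rpois(25, 8), rpois(25, 11)))
  res <- compare_groups(counts)
  expect_equal(res$dunn$z^2, res$kruskal$statistic, tolerance = 1e-9)
})

test_that("groups at the wild-type vs mutant intensity ratio separate decisively", {
  set.seed(77)
  counts <- data.frame(group = rep(c("wt", "mut"), each = 260),
                       arm = 0, pericentromere = 0,
                       total = c(rpois(260, 8.4), rpois(260, 14)))
  res <- compare_groups(counts)
  expect_lt(res$dunn$p_adj, 0.001)
})

test_that("percent-change summaries match direct arithmetic", {
  fert <- percent_change_summary(52, c(32, 39, 25))
  expect_equal(round(-fert$mean_percent_change), 38)
  pollen <- percent_change_summary(98, c(91, 96, 89))
  expect_equal(-pollen$mean_point_change, 6)
  expect_equal(percent_change_summary(10, 10)$percent_change, 0)
  expect_error(percent_change_summary(0, 5), "positive")
})
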