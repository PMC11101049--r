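test_that("Andrassy mass formula and its guards", {
  expect_equal(andrassy_mass(1.6e6, 1), 1)
  expect_equal(andrassy_mass(1000, 40), 1)
  expect_equal(andrassy_mass(2000, 40), 2)
  expect_error(andrassy_mass(-1, 40), "positive")
  expect_error(andrassy_mass(1000, 0), "positive")
})

test_that("average and overall female proportions", {
  one <- female_proportions(3, 4)
  expect_equal(one$afp, 0.75)
  expect_equal(one$ofp, 0.75)

  two <- female_proportions(c(2, 1), c(3, 1))
  expect_equal(two$afp, (2 / 3 + 1) / 2)
  expect_equal(two$ofp, 3 / 4)

  sat <- female_proportions(c(5, 2), c(5, 2))
  expect_equal(sat$afp, 1)
  expect_equal(sat$ofp, 1)

  expect_warning(none <- female_proportions(c(0, 0), c(0, 0)), "no lake")
  expect_true(is.na(none$afp) && is.na(none$ofp))
  expect_error(female_proportions(3, 2), "females <= adults")
})

test_that("OFP and AFP lie between the extreme per-lake proportions", {
  set.seed(21)
  for (rep in 1:20) {
    ad <- rpois(6, 5) + 1
    fe <- rbinom(6, ad, runif(1))
    fp <- female_proportions(fe, ad)
    pr <- fe / ad
    expect_gte(fp$ofp, min(pr)); expect_lte(fp$ofp, max(pr))
    expect_gte(fp$afp, min(pr)); expect_lte(fp$afp, max(pr))
  }
})

test_that("species filters implement both eligibility rules", {
  tr <- data.frame(taxon = c("a", "b", "c"),
                   freq = c(4, 3, 5), adults = c(1, 100, 10))
  tr <- species_filters(tr)
  # few adults despite enough lakes; enough adults in too few lakes
  expect_equal(tr$eligible_distribution, c(FALSE, FALSE, TRUE))
  expect_equal(tr$eligible_femprop, c(FALSE, TRUE, TRUE))
})

test_that("species_traits aggregates counts and joins morphometry", {
  counts <- data.frame(
    lake_id = c("l1", "l2", "l1"),
    taxon = c("a", "a", "b"),
    abundance = c(5, 3, 2), adults = c(3, 1, 2), females = c(2, 1, 2))
  morpho <- data.frame(taxon = c("a", "b"), L_um = c(1000, 2000), a_um = c(40, 40))
  tr <- species_traits(counts, morpho)
  expect_equal(tr$freq, c(2, 1))
  expect_equal(tr$abundance, c(8, 2))
  expect_equal(tr$afp, c((2 / 3 + 1) / 2, 1))
  expect_equal(tr$ofp, c(3 / 4, 1))
  expect_equal(tr$mass_ug, c(1, 2))
  expect_error(species_traits(transform(counts, females = adults + 1)),
               "females <= adults")
})

test_that("per-lake summaries honour the per-species six-adult rule", {
  counts <- data.frame(
    lake_id = c("l1", "l1", "l1", "l2"),
    taxon = c("a", "b", "c", "a"),
    abundance = c(10, 8, 3, 4),
    adults = c(8, 6, 3, 4),
    females = c(4, 6, 1, 4))
  traits <- data.frame(taxon = c("a", "b", "c"), mass_ug = c(2, 4, 1))
  ls <- lake_trait_summary(counts, traits)
  l1 <- ls[ls$lake_id == "l1", ]
  # only a and b qualify within l1 (c has 3 adults): mean(0.5, 1)
  expect_equal(l1$afp_mean, 0.75)
  expect_equal(l1$fp_weighted, 11 / 17)
  l2 <- ls[ls$lake_id == "l2", ]
  expect_true(is.na(l2$afp_mean))        # 4 adults only
  expect_true(is.na(l2$fp_weighted))     # 4 adults in total < 6
  expect_equal(l2$size_mean, 2)
  # relativised sizes attain 1 at the argmax lake
  expect_equal(max(ls$size_mean_rel, na.rm = TRUE), 1)
  expect_equal(ls$size_mean_rel[which.max(ls$size_mean)], 1)
})

test_that("lake summary eligibility matches a brute-force row filter on synthetic data", {
  sim <- synth_metacommunity(synth_config(n_lakes = 40, n_species = 12, seed = 5))
  traits <- species_traits(sim$counts, sim$morphometry)
  ls <- lake_trait_summary(sim$counts, traits)
  for (i in seq_len(nrow(ls))) {
    rows <- sim$counts[sim$counts$lake_id == ls$lake_id[i], ]
    expect_equal(!is.na(ls$afp_mean[i]), any(rows$adults >= 6))
    expect_equal(!is.na(ls$fp_weighted[i]), sum(rows$adults) >= 6)
  }
})

test_that("bundled survey table loads with its documented shape", {
  tab <- survey_species_table()
  expect_equal(nrow(tab), 33)
  expect_equal(sum(!tab$exclude), 31)
  part <- survey_partition_table()
  expect_equal(nrow(part), 20)
  expect_true(all(part$species %in% tab$taxon))
})
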