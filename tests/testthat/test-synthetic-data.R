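test_that("founder pools are fully inbred and seed-reproducible", {
  pools <- simulate_founders(2, 2, 10, maf_low = 0.5, maf_high = 0.5, seed = 1)
  g <- rbind(pools$B$genotypes$geno, pools$R$genotypes$geno)
  expect_equal(nrow(g), 4)
  expect_equal(ncol(g), 10)
  expect_true(all(g %in% c(0, 2)))

  again <- simulate_founders(2, 2, 10, maf_low = 0.5, maf_high = 0.5, seed = 1)
  expect_identical(pools$B$genotypes$geno, again$B$genotypes$geno)
  expect_identical(pools$R$genotypes$geno, again$R$genotypes$geno)

  other <- simulate_founders(2, 2, 10, maf_low = 0.5, maf_high = 0.5, seed = 2)
  expect_false(identical(pools$B$genotypes$geno, other$B$genotypes$geno))

  expect_error(simulate_founders(2, 2, 10, maf_low = 0.3, maf_high = 0.2),
               "maf_low")
  expect_error(simulate_founders(2, 2, 10, maf_low = 0, maf_high = 0.6),
               "maf_low")
})

test_that("realised founder MAF spans the sampling design", {
  pools <- simulate_founders(50, 50, 2000, maf_low = 0.05, maf_high = 0.5,
                             seed = 7)
  g <- pools$B$genotypes$geno
  maf <- pmin(colMeans(g) / 2, 1 - colMeans(g) / 2)
  # frequencies were drawn U[0.05, 0.5]; binomial sampling with 50 lines
  # spreads each marker around its frequency, so the empirical MAF
  # distribution must cover the design range and average near its middle
  expect_lt(min(maf), 0.10)
  expect_gt(max(maf), 0.45)
  expect_equal(mean(maf), 0.26, tolerance = 0.05)
})

test_that("trait values follow the additive + dominance architecture", {
  # single QTL, a = 0, d = 1: heterozygote scores 1, homozygotes 0
  g <- gm_from(matrix(c(0, 1, 2), nrow = 3,
                      dimnames = list(c("p1", "h", "p2"), "m1")))
  arch <- trait_architecture(qtl_indices = 1, additive_effects = 0,
                             dominance_effects = 1)
  v <- simulate_trait(arch, g)
  expect_equal(unname(v), c(0, 1, 0))
  # mid-parent of p1 (dosage 0) and p2 (dosage 2) is 0, hybrid scores 1

  # purely additive trait: every hybrid sits exactly at its mid-parent
  pop <- tiny_population(6, 6, 100, seed = 11)
  arch_add <- random_architecture(100, 20, additive_sd = 1,
                                  dominance_mean = 0, dominance_sd = 0,
                                  seed = 12)
  tv <- simulate_trait(arch_add, gm_rbind(pop$inbreds, pop$hybrids))
  mp <- (tv[pop$plan$female_id] + tv[pop$plan$male_id]) / 2
  expect_equal(unname(tv[pop$plan$hybrid_id]), unname(mp), tolerance = 1e-12)

  # directional dominance: median mid-parent heterosis strictly positive
  arch_dom <- random_architecture(100, 100, additive_sd = 0.5,
                                  dominance_mean = 1, dominance_sd = 0.2,
                                  seed = 13)
  tvd <- simulate_trait(arch_dom, gm_rbind(pop$inbreds, pop$hybrids))
  tvd <- tvd - min(tvd) + 1  # positive scale so the ratio is defined
  mpd <- (tvd[pop$plan$female_id] + tvd[pop$plan$male_id]) / 2
  mph <- (tvd[pop$plan$hybrid_id] - mpd) / mpd
  expect_gt(median(mph), 0)

  # missing QTL genotype is a data error
  gm_na <- g; gm_na$geno[2, 1] <- NA
  expect_error(simulate_trait(arch, gm_na), "missing")
})

test_that("zero-dominance architectures show no heterosis", {
  pop <- tiny_population(15, 15, 300, seed = 21)  # 225 hybrids
  arch <- random_architecture(300, 50, additive_sd = 1,
                              dominance_mean = 0, dominance_sd = 0, seed = 22)
  tv <- simulate_trait(arch, gm_rbind(pop$inbreds, pop$hybrids))
  tv <- tv + 100  # positive scale
  mp <- (tv[pop$plan$female_id] + tv[pop$plan$male_id]) / 2
  mph <- (tv[pop$plan$hybrid_id] - mp) / mp
  expect_gte(length(mph), 200)
  expect_lt(abs(median(mph)), 0.01)
})

test_that("field book layout honours blocks, controls and replication", {
  pop <- tiny_population(5, 5, 50, seed = 31)
  keep <- pop$plan$hybrid_id[1:16]
  g <- gm_rbind(pop$inbreds, gm_subset(pop$hybrids, entries = keep))
  arch <- random_architecture(50, 10, seed = 32, resid_sd = 1, gxe_sd = 0.5,
                              rep_sd = 0.5, block_sd = 0.5, loc_sd = 1)
  tv <- simulate_trait(arch, g)  # 26 entries
  controls <- c("B001", keep[1])
  et <- setNames(g$entries$type, g$entries$id)
  book <- simulate_field_book(tv, arch, n_locations = 4, n_reps = 2,
                              block_size = 14, controls = controls,
                              entry_types = et, seed = 33)
  # 24 experimental entries in 2 blocks of 12 + 2 controls per block
  expect_equal(nrow(book), 4 * 2 * 2 * 14)
  blocks <- split(book$entry_id, book$block)
  expect_true(all(vapply(blocks, function(b) all(controls %in% b), TRUE)))
  # each non-control entry appears once per replicate per location
  noncon <- book[!book$entry_id %in% controls, ]
  tab <- table(noncon$entry_id, noncon$replicate)
  expect_true(all(tab == 1))

  # impossible layouts fail loudly
  expect_error(simulate_field_book(tv, arch, block_size = 15,
                                   controls = controls, seed = 1),
               "blocks")
})

test_that("noise-free plots reproduce the true genotypic values", {
  tv <- setNames(rnorm(30), paste0("e", 1:30))
  arch <- trait_architecture(1, 0, 0, loc_sd = 0, gxe_sd = 0, rep_sd = 0,
                             block_sd = 0, resid_sd = 0)
  book <- simulate_field_book(tv, arch, n_locations = 2, n_reps = 2,
                              block_size = 10, seed = 5)
  expect_equal(book$trait, unname(tv[book$entry_id]), tolerance = 1e-12)
})

test_that("plot residual variance matches the requested component", {
  # 320 entries x 4 locations x 2 reps = 2560 noise-only plots... use a
  # bigger grid to pass 5000 plots
  tv <- setNames(rep(0, 320), paste0("e", 1:320))
  arch <- trait_architecture(1, 0, 0, resid_sd = 2)
  book <- simulate_field_book(tv, arch, n_locations = 8, n_reps = 2,
                              block_size = 16, seed = 6)
  expect_gte(nrow(book), 5000)
  expect_equal(var(book$trait), 4, tolerance = 0.4)
})

test_that("field books and cross plans are bit-identical under a fixed seed", {
  tv <- setNames(rnorm(30), paste0("e", 1:30))
  arch <- trait_architecture(1, 0, 0, resid_sd = 1, gxe_sd = 1)
  b1 <- simulate_field_book(tv, arch, n_locations = 2, n_reps = 2,
                            block_size = 10, seed = 9)
  b2 <- simulate_field_book(tv, arch, n_locations = 2, n_reps = 2,
                            block_size = 10, seed = 9)
  expect_identical(b1, b2)
  p1 <- make_cross_plan(paste0("B", 1:8), paste0("R", 1:8), n_hybrids = 20,
                        seed = 3)
  p2 <- make_cross_plan(paste0("B", 1:8), paste0("R", 1:8), n_hybrids = 20,
                        seed = 3)
  expect_identical(p1, p2)
})

test_that("derived residual SD hits the heritability target in expectation", {
  tv <- setNames(rnorm(300, sd = 2), paste0("e", 1:300))
  arch <- trait_architecture(1, 0, 0, target_h2 = 0.75, gxe_sd = 0.5)
  book <- simulate_field_book(tv, arch, n_locations = 4, n_reps = 2,
                              block_size = 15, seed = 10)
  vg <- var(tv)
  ve <- attr(book, "resid_sd")^2
  h2_implied <- vg / (vg + 0.25 / 4 + ve / 8)
  expect_equal(h2_implied, 0.75, tolerance = 1e-10)
})
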