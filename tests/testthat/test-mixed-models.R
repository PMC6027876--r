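test_that("heritability follows the entry-mean formula", {
  vc <- function(g, gl, e) c(v_g = g, v_l = 0, v_gxl = gl, v_rep = 0,
                             v_block = 0, v_resid = e)
  expect_equal(heritability(vc(1, 0, 0), 4, 2), 1)
  expect_equal(heritability(vc(0, 3, 1), 4, 2), 0)
  # VG = 1, VGxL/NL = 4/4 = 1, Ve/(NR*NL) = 8/8 = 1
  expect_equal(heritability(vc(1, 4, 8), 4, 2), 1 / 3)
  # undefined when no variance enters
  expect_true(is.na(heritability(vc(0, 0, 0), 4, 2)))
  expect_error(heritability(vc(-1, 0, 1), 4, 2), "nonnegative")
})

test_that("heritability is monotone in each component", {
  grid <- expand.grid(g = c(0.5, 1, 2, 4), gl = c(0, 1, 3), e = c(0.5, 2, 8))
  h <- mapply(function(g, gl, e)
    heritability(c(v_g = g, v_gxl = gl, v_resid = e), 4, 2),
    grid$g, grid$gl, grid$e)
  expect_true(all(h >= 0 & h <= 1))
  for (i in seq_len(nrow(grid))) {
    up_g <- heritability(c(v_g = grid$g[i] + 1, v_gxl = grid$gl[i],
                           v_resid = grid$e[i]), 4, 2)
    up_gl <- heritability(c(v_g = grid$g[i], v_gxl = grid$gl[i] + 1,
                            v_resid = grid$e[i]), 4, 2)
    up_e <- heritability(c(v_g = grid$g[i], v_gxl = grid$gl[i],
                           v_resid = grid$e[i] + 1), 4, 2)
    expect_gt(up_g, h[i])
    expect_lt(up_gl, h[i])
    expect_lt(up_e, h[i])
  }
})

test_that("REML matches the balanced-ANOVA oracle on a toy design", {
  # 3 entries x 2 locations x 2 replicates, one block per replicate (the
  # block term is aliased away); generous true variances keep every
  # method-of-moments estimate interior, where REML and ANOVA coincide
  set.seed(1402)
  entries <- paste0("e", 1:3)
  locs <- c("L1", "L2")
  df <- expand.grid(entry_id = entries, location = locs, rep = 1:2,
                    stringsAsFactors = FALSE)
  g_eff <- setNames(rnorm(3, 0, 3), entries)
  l_eff <- setNames(rnorm(2, 0, 3), locs)
  gl_eff <- matrix(rnorm(6, 0, 2), 3, dimnames = list(entries, locs))
  r_eff <- matrix(rnorm(4, 0, 2), 2, dimnames = list(c("1", "2"), locs))
  df$y <- g_eff[df$entry_id] + l_eff[df$location] +
    gl_eff[cbind(df$entry_id, df$location)] +
    r_eff[cbind(as.character(df$rep), df$location)] + rnorm(nrow(df), 0, 1)
  book <- data.frame(location = df$location, replicate = df$rep,
                     block = 1, entry_id = df$entry_id,
                     entry_type = "inbred_B", y = df$y)

  # oracle: expected-mean-square equations from a balanced aov fit
  av <- summary(stats::aov(y ~ entry_id + location + location:factor(rep) +
                             entry_id:location, data = df))[[1]]
  ms <- setNames(av[["Mean Sq"]], trimws(rownames(av)))
  a <- 3; b <- 2; r <- 2
  s_e <- ms[["Residuals"]]
  s_gl <- (ms[["entry_id:location"]] - s_e) / r
  s_rep <- (ms[["location:factor(rep)"]] - s_e) / a
  s_g <- (ms[["entry_id"]] - ms[["entry_id:location"]]) / (b * r)
  expect_true(all(c(s_e, s_gl, s_rep, s_g) > 0))  # interior solution

  fit <- fit_random_model(book, "y")
  expect_lt(abs(fit$vc[["v_resid"]] - s_e), 1e-6)
  expect_lt(abs(fit$vc[["v_gxl"]] - s_gl), 1e-6)
  expect_lt(abs(fit$vc[["v_rep"]] - s_rep), 1e-6)
  expect_lt(abs(fit$vc[["v_g"]] - s_g), 1e-6)
  expect_equal(unname(fit$vc["v_block"]), 0)  # aliased, dropped
  expect_equal(fit$grand_mean, mean(df$y), tolerance = 1e-6)
})

test_that("degenerate designs are refused with a diagnostic", {
  book <- data.frame(location = "L1", replicate = rep(1:2, each = 3),
                     block = 1, entry_id = rep(paste0("e", 1:3), 2),
                     entry_type = "inbred_B", y = rnorm(6))
  expect_error(fit_random_model(book, "y"), "location")
  two_loc <- data.frame(location = rep(c("L1", "L2"), each = 3),
                        replicate = 1, block = 1,
                        entry_id = paste0("e", 1:6),
                        entry_type = "inbred_B", y = rnorm(6))
  expect_error(fit_random_model(two_loc, "y"), "replicated")
})

test_that("a pure-noise trait yields near-zero genetic variance and shrunken BLUPs", {
  tv <- setNames(rep(0, 60), paste0("e", 1:60))
  arch <- trait_architecture(1, 0, 0, resid_sd = 1)
  book <- simulate_field_book(tv, arch, n_locations = 2, n_reps = 2,
                              block_size = 15, seed = 44)
  fit <- fit_random_model(book, "trait")
  expect_lt(unname(fit$vc["v_g"]), 0.15)
  expect_lt(var(fit$blups$blup), 0.1 * unname(fit$vc["v_resid"]))
})

test_that("variance components are recovered from a simulated trial", {
  # true components: v_g ~ var(tv), v_gxl = 1, v_resid = 2
  set.seed(90)
  tv <- setNames(rnorm(300, 50, 2), paste0("e", 1:300))
  arch <- trait_architecture(1, 0, 0, gxe_sd = 1, rep_sd = 0.5,
                             block_sd = 0.5, resid_sd = sqrt(2))
  book <- simulate_field_book(tv, arch, n_locations = 4, n_reps = 2,
                              block_size = 15, seed = 91)
  fit <- fit_random_model(book, "trait")
  expect_equal(unname(fit$vc["v_g"]), var(tv), tolerance = 0.25)
  expect_equal(unname(fit$vc["v_gxl"]), 1, tolerance = 0.3)
  expect_equal(unname(fit$vc["v_resid"]), 2, tolerance = 0.3)
  # genotype BLUPs track the simulated true merit closely at this h2
  expect_gt(cor(fit$blups$blup, tv[fit$blups$entry_id]), 0.9)
  # random-effect centring: BLUPs average out to ~0
  expect_lt(abs(mean(fit$blups$blup)), 0.05 * sd(tv))
})

test_that("BLUPs shrink toward zero as noise swamps the genetic signal", {
  tv <- setNames(rnorm(60, 0, 1), paste0("e", 1:60))
  arch_lo <- trait_architecture(1, 0, 0, resid_sd = 0.5)
  arch_hi <- trait_architecture(1, 0, 0, resid_sd = 20)
  b_lo <- simulate_field_book(tv, arch_lo, n_locations = 2, n_reps = 2,
                              block_size = 15, seed = 7)
  b_hi <- simulate_field_book(tv, arch_hi, n_locations = 2, n_reps = 2,
                              block_size = 15, seed = 7)
  v_lo <- var(fit_random_model(b_lo, "trait")$blups$blup)
  v_hi <- var(fit_random_model(b_hi, "trait")$blups$blup)
  expect_lt(v_hi, v_lo)
})

test_that("mid-parent heterosis matches hand computation on a fixture", {
  blups <- data.frame(
    entry_id = c("f1", "f2", "m1", "m2", "h1", "h2", "h3", "h4", "h5"),
    population = c(rep("inbred", 4), rep("hybrid", 5)),
    blup = 0,
    value = c(10, 20, 30, 40, 30, 33, 20, 50, 28))
  plan <- data.frame(hybrid_id = paste0("h", 1:5),
                     female_id = c("f1", "f1", "f2", "f2", "f1"),
                     male_id = c("m1", "m2", "m1", "m2", "m1"))
  mph <- midparent_heterosis(blups, plan)
  # mid-parents: 20, 25, 25, 30, 20 -> heterosis 0.5, 0.32, -0.2, 2/3, 0.4
  expect_equal(mph$heterosis, c(0.5, 0.32, -0.2, 2 / 3, 0.4))
  expect_equal(attr(mph, "median"), 0.4)
  expect_equal(attr(mph, "n_flagged"), 0)

  # hybrid equal to its mid-parent scores zero
  blups$value[blups$entry_id == "h1"] <- 20
  expect_equal(midparent_heterosis(blups, plan)$heterosis[1], 0)

  # non-positive mid-parent is flagged and excluded from the median
  blups$value[blups$entry_id %in% c("f1", "m1")] <- c(-5, 5)
  mph2 <- midparent_heterosis(blups, plan)
  expect_equal(attr(mph2, "n_flagged"), 2)
  expect_true(all(is.na(mph2$heterosis[c(1, 5)])))
})

test_that("population centring zeroes both population means", {
  blups <- data.frame(entry_id = paste0("e", 1:4),
                      population = c("inbred", "inbred", "hybrid", "hybrid"),
                      blup = c(1, 3, 10, 14) - 7,
                      value = c(1, 3, 10, 14))
  cc <- center_by_population(blups)
  expect_equal(cc$value, c(-1, 1, -2, 2))
  expect_lt(abs(mean(cc$value[cc$population == "inbred"])), 1e-10)
  expect_lt(abs(mean(cc$value[cc$population == "hybrid"])), 1e-10)
  # centring is idempotent
  expect_equal(center_by_population(cc)$value, cc$value)
  # a single-entry population maps to zero
  one <- blups[2:4, ]
  expect_equal(center_by_population(one)$value[1], 0)
  # both populations must be present
  expect_error(center_by_population(blups[3:4, ]), "population")
})
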