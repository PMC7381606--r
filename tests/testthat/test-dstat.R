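test_that("observed change sum matches the hand calculation on 4 tips", {
  tr <- balanced_four_tip()
  # (1,1,0,0) split along the root: cherries contribute 0, root |1-0| = 1
  expect_equal(observed_change_sum(tr, c(A = 1, B = 1, C = 0, D = 0)), 1)
  # maximally interleaved trait: cherries contribute 1 each, root 0
  expect_equal(observed_change_sum(tr, c(A = 1, B = 0, C = 1, D = 0)), 2)
  # complement symmetry
  withr::with_seed(2, {
    rl <- random_labelled_tree(64, seed = 9)
    trait <- sample(c(rep(1, 16), rep(0, 48)))
  })
  expect_equal(observed_change_sum(rl$tree, trait),
               observed_change_sum(rl$tree, 1 - trait))
})

test_that("degenerate traits error", {
  tr <- balanced_four_tip()
  expect_error(observed_change_sum(tr, c(1, 1, 1, 1)), "constant")
  expect_error(observed_change_sum(tr, c(1, 0, NA, 0)), "binary")
  expect_error(observed_change_sum(tr, c(A = 1, B = 0, C = 1)), "missing")
})

test_that("polytomy nodes average daughter-pairwise differences", {
  phy <- ape::read.tree(text = "(A:1,B:1,C:1);")
  tr <- suppressWarnings(as_dated_tree(phy))
  # pairs (1,0),(1,0),(0,0): mean |diff| = 2/3
  expect_equal(observed_change_sum(tr, c(A = 1, B = 0, C = 0)), 2 / 3)
})

test_that("D satisfies its definitional identities", {
  rl <- random_labelled_tree(64, seed = 4)
  withr::with_seed(3, trait <- sample(c(rep(1, 16), rep(0, 48))))
  res <- d_statistic(rl$tree, trait, n_perm = 100, seed = 5)
  # substitute the null means for d_obs: D must be exactly 0 / exactly 1
  denom <- mean(res$d_random) - mean(res$d_brownian)
  expect_equal((mean(res$d_brownian) - mean(res$d_brownian)) / denom, 0)
  expect_equal((mean(res$d_random) - mean(res$d_brownian)) / denom, 1)
  # and the reported D is the same scaling of the observed change sum
  expect_equal(res$D, (res$d_obs - mean(res$d_brownian)) / denom)
  expect_true(res$p_random >= 0 && res$p_random <= 1)
  expect_true(res$p_brownian >= 0 && res$p_brownian <= 1)
  expect_length(res$d_random, 100)
  expect_length(res$d_brownian, 100)
})

test_that("results are bitwise reproducible under a fixed seed", {
  rl <- random_labelled_tree(32, seed = 6)
  trait <- as.numeric(rl$species$biome == "savanna")
  names(trait) <- rl$species$species
  a <- d_statistic(rl$tree, trait, n_perm = 50, seed = 77)
  b <- d_statistic(rl$tree, trait, n_perm = 50, seed = 77)
  expect_identical(a$d_random, b$d_random)
  expect_identical(a$d_brownian, b$d_brownian)
  expect_identical(a$D, b$D)
})

test_that("shuffled traits give D near 1, Brownian-threshold near 0", {
  n_trees <- 25
  Ds_rand <- Ds_bm <- numeric(n_trees)
  for (i in seq_len(n_trees)) {
    sc <- synthetic_scenario(seed = 100 + i, n_tips = 128, prevalence = 0.25)
    tr <- simulate_tree(sc)
    trait <- withr::with_seed(200 + i, sample(c(rep(1, 32), rep(0, 96))))
    Ds_rand[i] <- d_statistic(tr, trait, n_perm = 100, seed = i)$D
    lab <- simulate_biome_labels(tr, sc)
    Ds_bm[i] <- d_statistic(tr, as.numeric(lab$biome == "savanna"),
                            n_perm = 100, seed = 1000 + i)$D
  }
  expect_lt(abs(mean(Ds_rand) - 1), 0.15)
  expect_lt(abs(mean(Ds_bm) - 0), 0.15)
})

test_that("more clustered traits have weakly smaller expected D", {
  # lowering the white-noise scale increases conservatism
  mean_D_at_noise <- function(noise) {
    Ds <- numeric(12)
    for (i in seq_len(12)) {
      sc <- synthetic_scenario(seed = 400 + i, n_tips = 96,
                               prevalence = 0.25, noise_scale = noise)
      tr <- simulate_tree(sc)
      lab <- simulate_biome_labels(tr, sc)
      Ds[i] <- d_statistic(tr, as.numeric(lab$biome == "savanna"),
                           n_perm = 80, seed = i)$D
    }
    mean(Ds)
  }
  d_low <- mean_D_at_noise(0)
  d_high <- mean_D_at_noise(10)
  expect_lt(d_low, d_high)
  expect_lt(abs(d_high - 1), 0.35)  # huge noise behaves like shuffling
})

test_that("biome membership wrapper codes the trait from the species table", {
  rl <- random_labelled_tree(48, seed = 12)
  res <- biome_dstat(rl$tree, rl$species, "savanna", n_perm = 50, seed = 3)
  trait <- as.numeric(
    rl$species$biome[match(rl$tree$tip.label, rl$species$species)] == "savanna")
  expect_equal(res$d_obs, observed_change_sum(rl$tree, trait))
  expect_equal(res$prevalence, mean(trait))
})
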