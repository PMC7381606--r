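test_that("only same-biome cherries are returned", {
  tr <- balanced_four_tip()
  sp <- data.frame(species = c("A", "B", "C", "D"),
                   biome = c("savanna", "savanna", "forest", "savanna"))
  pairs <- find_biome_sister_pairs(tr, sp, "savanna")
  expect_equal(nrow(pairs), 1)
  expect_equal(sort(c(pairs$species_a, pairs$species_b)), c("A", "B"))
  expect_equal(pairs$age_ma, 1.0)

  # mixed cherries are excluded outright: no ancestral-state inference
  sp$biome <- c("savanna", "forest", "forest", "forest")
  expect_warning(none <- find_biome_sister_pairs(tr, sp, "savanna"),
                 "no savanna")
  expect_equal(nrow(none), 0)
})

test_that("pair extraction matches brute-force cherry enumeration", {
  for (seed in 1:40) {
    rl <- random_labelled_tree(sample(10:200, 1), seed = seed)
    tip_biome <- rl$species$biome[match(rl$tree$tip.label, rl$species$species)]
    oracle <- brute_force_cherries(rl$tree, tip_biome, "savanna")
    got <- find_biome_sister_pairs(rl$tree, rl$species, "savanna") |>
      suppressWarnings()
    got_pairs <- lapply(seq_len(nrow(got)),
                        function(i) sort(c(got$species_a[i], got$species_b[i])))
    expect_setequal(
      vapply(got_pairs, paste, character(1), collapse = "|"),
      vapply(oracle, paste, character(1), collapse = "|")
    )
  }
})

test_that("pair extraction is invariant to child rotation", {
  rl <- random_labelled_tree(80, seed = 123)
  rotated <- ape::rotateConstr(rl$tree, sample(rl$tree$tip.label))
  key <- function(p) sort(paste(pmin(p$species_a, p$species_b),
                                pmax(p$species_a, p$species_b)))
  p1 <- find_biome_sister_pairs(rl$tree, rl$species, "savanna")
  p2 <- find_biome_sister_pairs(as_dated_tree(rotated), rl$species, "savanna")
  expect_equal(key(p1), key(p2))
})

test_that("same-biome tips under polytomies are excluded and reported", {
  phy <- ape::read.tree(text = "((A:1,B:1,C:1):1,(D:2,E:2):0);")
  tr <- as_dated_tree(phy)
  sp <- data.frame(species = LETTERS[1:5], biome = "savanna")
  pairs <- find_biome_sister_pairs(tr, sp, "savanna")
  expect_equal(nrow(pairs), 1)  # only the true cherry (D, E)
  expect_equal(sort(c(pairs$species_a, pairs$species_b)), c("D", "E"))
  rep <- attr(pairs, "polytomy_report")
  expect_equal(rep$n_excluded_same_biome, 1)
})

test_that("age cap and named exclusions filter with exact counts", {
  pairs <- tibble::tibble(
    species_a = c("a1", "b1", "c1", "Bolusanthus_speciosus"),
    species_b = c("a2", "b2", "c2", "Pericopsis_angolensis"),
    biome = "savanna",
    age_ma = c(3, 12, 26, 14)
  )
  out <- filter_pairs(pairs, max_age = 25)
  expect_equal(sort(out$age_ma), c(3, 12, 14))

  # order-insensitive named exclusion
  out2 <- filter_pairs(pairs, max_age = 25,
                       exclude = c("Pericopsis angolensis",
                                   "Bolusanthus speciosus"))
  expect_equal(sort(out2$age_ma), c(3, 12))
  log <- attr(out2, "filter_log")
  expect_equal(nrow(log), 2)
  expect_setequal(log$reason, c("age > 25 Ma", "named exclusion"))

  expect_warning(filter_pairs(pairs, exclude = c("x", "y")),
                 "matches no pair")
})

test_that("filtering counts satisfy the bookkeeping identity", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- sample(5:50, 1)
      pairs <- tibble::tibble(
        species_a = sprintf("s%da", 1:n), species_b = sprintf("s%db", 1:n),
        biome = "savanna", age_ma = runif(n, 0, 40)
      )
      cap <- runif(1, 5, 35)
      n_excl <- sample(0:min(3, n), 1)
      excl <- if (n_excl > 0) {
        lapply(sample(which(pairs$age_ma <= cap), min(n_excl, sum(pairs$age_ma <= cap))),
               function(i) c(pairs$species_a[i], pairs$species_b[i]))
      } else NULL
      out <- filter_pairs(pairs, max_age = cap, exclude = excl)
      expect_equal(nrow(out),
                   n - sum(pairs$age_ma > cap) -
                     (if (is.null(excl)) 0 else length(excl)))
    }
  })
})

test_that("pair tables serialize with exclusion flags", {
  pairs <- tibble::tibble(
    species_a = c("a1", "b1"), species_b = c("a2", "b2"),
    biome = "savanna", age_ma = c(3, 30),
    hpd_lower = c(2, 25), hpd_upper = c(4, 35),
    mean_latitude = c(-10, -5), latitude_source = "both_species"
  )
  out <- filter_pairs(pairs, max_age = 25)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pair_table(out, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 2)
  expect_equal(sum(back$excluded_flag), 1)
  expect_match(back$exclusion_reason[back$excluded_flag], "age > 25")
})
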