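# Independent oracles used across tests. These deliberately reimplement the
# quantities they check by the most literal brute-force route.

# minimum check loss over all lines through two data points (the LP optimum
# passes through at least two points, so this enumeration is exhaustive)
brute_force_check_loss <- function(x, y, tau) {
  n <- length(x)
  best <- Inf
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (x[i] == x[j]) next
      b <- (y[j] - y[i]) / (x[j] - x[i])
      a <- y[i] - b * x[i]
      r <- y - a - b * x
      l <- sum(r * (tau - (r < 0)))
      if (l < best) best <- l
    }
  }
  best
}

# literal cherry enumeration: test every internal node for "exactly two
# descendants, both tips, equal labels"
brute_force_cherries <- function(phy, tip_biome, biome) {
  n_tip <- ape::Ntip(phy)
  out <- list()
  for (nd in (n_tip + 1):(n_tip + phy$Nnode)) {
    ch <- phy$edge[phy$edge[, 1] == nd, 2]
    if (length(ch) == 2 && all(ch <= n_tip) &&
        all(tip_biome[ch] == biome)) {
      tips <- sort(phy$tip.label[ch])
      out[[length(out) + 1]] <- tips
    }
  }
  out
}

# a random bifurcating dated tree with random biome labels
random_labelled_tree <- function(n_tips, seed, biomes = c("savanna", "forest")) {
  withr::with_seed(seed, {
    phy <- ape::rphylo(n_tips, birth = 0.3, death = 0)
    phy$tip.label <- sprintf("sp%03d", seq_len(n_tips))
    lab <- sample(biomes, n_tips, replace = TRUE)
  })
  list(tree = as_dated_tree(phy),
       species = data.frame(species = phy$tip.label, biome = lab))
}

# per-cell recomputation of the age grid, looping over pairs and cells
brute_force_grid <- function(pairs, cells, res) {
  key <- function(lat, lon) paste(floor(lon / res), floor(lat / res))
  cell_species <- split(key(cells$lat, cells$lon), cells$species)
  acc <- list()
  for (i in seq_len(nrow(pairs))) {
    ck <- unique(c(cell_species[[pairs$species_a[i]]],
                   cell_species[[pairs$species_b[i]]]))
    for (k in ck) {
      acc[[k]] <- c(acc[[k]], pairs$age_ma[i])
    }
  }
  data.frame(
    key = names(acc),
    mean_age = vapply(acc, mean, numeric(1)),
    n_pairs = vapply(acc, length, numeric(1)),
    row.names = NULL
  )
}

# small fixed 4-tip tree used in several hand calculations
balanced_four_tip <- function() {
  as_dated_tree(ape::read.tree(text = "((A:1,B:1):1,(C:2,D:2):0);"))
}
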