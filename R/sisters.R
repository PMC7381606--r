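#' Enumerate same-biome sister pairs (cherries) on a dated tree
#'
#' A sister pair is a strictly bifurcating cherry: an internal node whose
#' descendants are exactly two tips. Only cherries where both tips carry the
#' requested biome label are returned, so the divergence can be attributed to
#' that biome without reconstructing ancestral states; mixed-biome cherries
#' are dropped, and same-biome tips hanging from polytomies are excluded and
#' counted in `attr(pairs, "polytomy_report")`. Each tip appears in at most
#' one pair by construction.
#'
#' @param tree A `dated_tree` (see [read_dated_tree()]).
#' @param species Species table as returned by [read_species_table()] (or any
#'   data frame with `species` and `biome`).
#' @param biome Biome of interest, from the closed vocabulary.
#' @return Tibble with one row per pair: `species_a`, `species_b`, `biome`,
#'   `node` (MRCA node number), `age_ma`, `hpd_lower`, `hpd_upper`,
#'   `mean_latitude` (`NA`, filled by [attach_pair_latitudes()]), and
#'   `latitude_source` (`"missing"` until latitudes are attached).
#' @export
#' @examples
#' phy <- ape::read.tree(text = "((A:1,B:1):1,(C:2,D:2):0);")
#' tr <- as_dated_tree(phy)
#' sp <- data.frame(species = c("A", "B", "C", "D"),
#'                  biome = c("savanna", "savanna", "forest", "savanna"))
#' find_biome_sister_pairs(tr, sp, "savanna")
find_biome_sister_pairs <- function(tree, species, biome) {
  stopifnot(inherits(tree, "dated_tree"))
  biome <- check_biome(biome)
  stopifnot(length(biome) == 1)
  species <- validate_species_table(species)
  n_tip <- ape::Ntip(tree)
  tip_biome <- species$biome[match(tree$tip.label, species$species)]
  tip_biome[is.na(tip_biome)] <- "unknown"

  edge <- tree$edge
  is_tip_child <- edge[, 2] <= n_tip
  n_children <- tabulate(edge[, 1], nbins = n_tip + tree$Nnode)
  n_tip_children <- tabulate(edge[is_tip_child, 1], nbins = n_tip + tree$Nnode)

  cherry_nodes <- which(n_children == 2 & n_tip_children == 2)
  # >= 2 same-biome tips under a multifurcation (or beside a subtree): these
  # are not strict cherries and are excluded, but reported
  poly_candidates <- which(n_tip_children >= 2 & n_children > 2)
  poly_excluded <- 0L
  for (nd in poly_candidates) {
    tips <- edge[edge[, 1] == nd & is_tip_child, 2]
    if (sum(tip_biome[tips] == biome) >= 2) poly_excluded <- poly_excluded + 1L
  }

  rows <- list()
  for (nd in cherry_nodes) {
    tips <- sort(edge[edge[, 1] == nd, 2])
    if (tip_biome[tips[1]] == biome && tip_biome[tips[2]] == biome) {
      rows[[length(rows) + 1L]] <- tibble(
        species_a = tree$tip.label[tips[1]],
        species_b = tree$tip.label[tips[2]],
        biome = biome,
        node = nd,
        age_ma = tree$node_age[nd]
      )
    }
  }
  if (length(rows) == 0) {
    warning("no ", biome, " sister pairs found", call. = FALSE)
    out <- tibble(
      species_a = character(0), species_b = character(0),
      biome = character(0), node = integer(0), age_ma = numeric(0)
    )
  } else {
    out <- bind_rows(rows) |> arrange(dplyr::desc(.data$age_ma), .data$species_a)
  }
  ages <- node_ages(tree)
  out <- out |>
    left_join(select(ages, "node", "hpd_lower", "hpd_upper"), by = "node") |>
    mutate(mean_latitude = NA_real_, latitude_source = "missing")
  attr(out, "polytomy_report") <- tibble(
    n_polytomy_nodes = length(tree$polytomies),
    n_excluded_same_biome = poly_excluded
  )
  out
}

#' Filter sister pairs by maximum age and named exclusions
#'
#' Applies the age cap (pairs strictly older than `max_age` are removed) and
#' removes named pairs order-insensitively. Every removal and its reason is
#' recorded in `attr(result, "filter_log")`.
#'
#' @param pairs Pair table from [find_biome_sister_pairs()].
#' @param max_age Optional age cap in Ma (e.g. 25); `NULL` keeps all ages.
#' @param exclude Optional named exclusions: a character vector of length
#'   two, a list of such vectors, or a two-column matrix/data frame of
#'   species names (either order).
#' @return Filtered pair tibble with a `filter_log` attribute (tibble of
#'   `species_a`, `species_b`, `age_ma`, `reason`).
#' @export
filter_pairs <- function(pairs, max_age = NULL, exclude = NULL) {
  pairs <- as_tibble(pairs)
  log <- list()
  keep <- rep(TRUE, nrow(pairs))

  if (!is.null(max_age)) {
    over <- pairs$age_ma > max_age
    if (any(over)) {
      log[[length(log) + 1L]] <- pairs[over, c("species_a", "species_b", "age_ma")] |>
        mutate(reason = sprintf("age > %g Ma", max_age))
    }
    keep <- keep & !over
  }

  if (!is.null(exclude)) {
    excl <- normalize_exclusions(exclude)
    pair_key <- pair_keys(pairs$species_a, pairs$species_b)
    for (key in excl) {
      hit <- keep & pair_key == key
      if (!any(pair_key == key)) {
        warning("exclusion '", sub("\r", " / ", key, fixed = TRUE),
                "' matches no pair", call. = FALSE)
      }
      if (any(hit)) {
        log[[length(log) + 1L]] <- pairs[hit, c("species_a", "species_b", "age_ma")] |>
          mutate(reason = "named exclusion")
      }
      keep <- keep & pair_key != key
    }
  }

  out <- pairs[keep, , drop = FALSE]
  attr(out, "filter_log") <- if (length(log) > 0) {
    bind_rows(log)
  } else {
    tibble(species_a = character(0), species_b = character(0),
           age_ma = numeric(0), reason = character(0))
  }
  attr(out, "polytomy_report") <- attr(pairs, "polytomy_report")
  out
}

normalize_exclusions <- function(exclude) {
  if (is.character(exclude) && length(exclude) == 2 && is.null(dim(exclude))) {
    exclude <- list(exclude)
  }
  if (is.matrix(exclude) || is.data.frame(exclude)) {
    exclude <- lapply(seq_len(nrow(exclude)),
                      function(i) as.character(unlist(exclude[i, 1:2])))
  }
  vapply(exclude, function(p) {
    stopifnot(length(p) == 2)
    pair_keys(p[1], p[2])
  }, character(1))
}

pair_keys <- function(a, b) {
  a <- normalize_species_names(a)
  b <- normalize_species_names(b)
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Write a sister-pair table to CSV, including filtered-out pairs
#'
#' Emits the retained pairs plus any rows recorded in the `filter_log`
#' attribute, with `excluded_flag` and `exclusion_reason` columns.
#'
#' @param pairs Pair tibble (typically from [filter_pairs()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  keep <- as_tibble(pairs) |>
    mutate(excluded_flag = FALSE, exclusion_reason = NA_character_)
  log <- attr(pairs, "filter_log")
  if (!is.null(log) && nrow(log) > 0) {
    dropped <- log |>
      rename(exclusion_reason = "reason") |>
      mutate(excluded_flag = TRUE)
    keep <- bind_rows(keep, dropped)
  }
  cols <- c("species_a", "species_b", "biome", "age_ma", "hpd_lower",
            "hpd_upper", "mean_latitude", "latitude_source",
            "excluded_flag", "exclusion_reason")
  for (cl in setdiff(cols, names(keep))) keep[[cl]] <- NA
  readr::write_csv(keep[, cols], path, progress = FALSE)
  invisible(path)
}
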