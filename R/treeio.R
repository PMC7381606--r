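#' Read a dated ultrametric phylogeny from a Newick file
#'
#' Reads a time-calibrated tree whose branch lengths are in millions of years
#' (Ma), computes node ages (distance from a node down to its descendant
#' tips), and optionally extracts per-node HPD age intervals from bracketed
#' metadata comments of the form `[&<key>={lower,upper}]` attached to internal
#' nodes (the style exported by Bayesian dating software). Tip labels are
#' normalized with [normalize_species_names()].
#'
#' Non-ultrametric trees (tip ages deviating from zero by more than `tol`
#' relative to tree height) produce a warning and a per-tip deviation report
#' in `attr(tree, "tip_age_deviations")`. Duplicate tip labels after
#' normalization are an error. Polytomies are retained but recorded in
#' `tree$polytomies` so downstream pair extraction can exclude them
#' explicitly.
#'
#' @param path Path to a Newick file. Bracketed comments are tolerated and
#'   stripped; they are only interpreted when `hpd_key` is given.
#' @param hpd_key Name of the metadata field holding the HPD interval, e.g.
#'   `"height_95%_HPD"`. `NULL` (default) ignores annotations.
#' @param tol Relative ultrametricity tolerance (fraction of tree height).
#' @return A `dated_tree` object: an [ape::phylo] tree with additional
#'   elements `node_age` (numeric, tips then internal nodes, Ma), `hpd`
#'   (tibble with columns `node`, `lower`, `upper`, or `NULL`), `annot_key`,
#'   and `polytomies` (internal node numbers with more than two children).
#' @export
read_dated_tree <- function(path, hpd_key = NULL, tol = 1e-6) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parts <- split_newick_comments(txt)
  phy <- ape::read.tree(text = parts$newick)
  if (is.null(phy)) stop("could not parse Newick in ", path, call. = FALSE)
  hpd <- NULL
  if (!is.null(hpd_key) && length(parts$comments) > 0) {
    loc <- locate_comment_sentinels(phy)
    hpd <- parse_hpd_comments(parts$comments, loc, hpd_key, n_tip = ape::Ntip(phy))
  }
  phy$tip.label <- strip_sentinels(phy$tip.label)
  if (!is.null(phy$node.label)) {
    phy$node.label <- strip_sentinels(phy$node.label)
  }
  as_dated_tree(phy, hpd = hpd, hpd_key = hpd_key, tol = tol)
}

#' Construct a dated tree from an ape phylogeny
#'
#' @param phy An [ape::phylo] object with branch lengths in Ma.
#' @param hpd Optional tibble/data frame with columns `node`, `lower`,
#'   `upper` giving HPD age bounds for internal nodes.
#' @param hpd_key Metadata key under which HPDs are (re)serialized.
#' @param tol Relative ultrametricity tolerance.
#' @return A `dated_tree` object (see [read_dated_tree()]).
#' @export
as_dated_tree <- function(phy, hpd = NULL, hpd_key = NULL, tol = 1e-6) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) {
    stop("tree has no branch lengths; a dated tree requires lengths in Ma",
         call. = FALSE)
  }
  phy$tip.label <- normalize_species_names(phy$tip.label)
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup) > 0) {
    stop("duplicate tip labels after normalization: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  n_tip <- ape::Ntip(phy)
  depth <- ape::node.depth.edgelength(phy)
  height <- max(depth[seq_len(n_tip)])
  age <- height - depth
  dev <- abs(age[seq_len(n_tip)])
  tip_dev <- NULL
  if (height > 0 && any(dev > tol * height)) {
    tip_dev <- tibble(species = phy$tip.label, age_deviation = dev) |>
      filter(.data$age_deviation > tol * height) |>
      arrange(dplyr::desc(.data$age_deviation))
    warning(sprintf(
      "tree is not ultrametric within tolerance: %d tip(s) deviate, max %.6g Ma; see attr(, 'tip_age_deviations')",
      nrow(tip_dev), max(tip_dev$age_deviation)), call. = FALSE)
  }
  # clamp tip ages that are pure floating-point noise
  age[seq_len(n_tip)][dev <= tol * max(height, 1)] <- 0
  kids <- tabulate(phy$edge[, 1], nbins = n_tip + phy$Nnode)
  poly <- which(kids > 2)

  if (!is.null(hpd) && nrow(hpd) > 0) {
    hpd <- as_tibble(hpd)
    stopifnot(all(c("node", "lower", "upper") %in% names(hpd)))
    slack <- 1e-8 * max(height, 1)
    bad <- hpd$lower > age[hpd$node] + slack | hpd$upper < age[hpd$node] - slack
    if (any(bad)) {
      warning(sum(bad), " HPD interval(s) do not bracket the point age; ",
              "they are kept as read", call. = FALSE)
    }
  } else {
    hpd <- NULL
  }

  phy$node_age <- age
  phy$hpd <- hpd
  phy$annot_key <- hpd_key
  phy$polytomies <- poly
  class(phy) <- unique(c("dated_tree", class(phy)))
  attr(phy, "tip_age_deviations") <- tip_dev
  phy
}

#' Write a dated tree to Newick, preserving HPD annotations
#'
#' Inverse of [read_dated_tree()]: topology, branch lengths and any HPD
#' intervals round-trip exactly (to floating-point printing precision).
#'
#' @param tree A `dated_tree`.
#' @param path Output file path.
#' @param digits Significant digits for branch lengths.
#' @return `path`, invisibly.
#' @export
write_dated_tree <- function(tree, path, digits = 15) {
  stopifnot(inherits(tree, "dated_tree"))
  phy <- tree
  class(phy) <- "phylo"
  n_tip <- ape::Ntip(phy)
  hpd <- tree$hpd
  if (!is.null(hpd) && nrow(hpd) > 0) {
    key <- tree$annot_key %||% "age_hpd"
    labs <- phy$node.label %||% rep("", phy$Nnode)
    idx <- hpd$node - n_tip
    labs[idx] <- sprintf("%s@CMT%d@", labs[idx], seq_len(nrow(hpd)))
    phy$node.label <- labs
    txt <- ape::write.tree(phy, digits = digits)
    for (k in seq_len(nrow(hpd))) {
      txt <- sub(sprintf("@CMT%d@", k),
                 sprintf("[&%s={%.15g,%.15g}]", key, hpd$lower[k], hpd$upper[k]),
                 txt, fixed = TRUE)
    }
  } else {
    txt <- ape::write.tree(phy, digits = digits)
  }
  writeLines(txt, path)
  invisible(path)
}

#' Node ages of a dated tree as a tibble
#'
#' @param tree A `dated_tree`.
#' @return Tibble with columns `node`, `label` (tips only), `age_ma`, and
#'   `hpd_lower`/`hpd_upper` (degenerate `[0, 0]` at tips, `NA` where no HPD
#'   was annotated).
#' @export
node_ages <- function(tree) {
  stopifnot(inherits(tree, "dated_tree"))
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  out <- tibble(
    node = seq_len(n_all),
    label = c(tree$tip.label, rep(NA_character_, tree$Nnode)),
    age_ma = tree$node_age,
    hpd_lower = c(rep(0, n_tip), rep(NA_real_, tree$Nnode)),
    hpd_upper = c(rep(0, n_tip), rep(NA_real_, tree$Nnode))
  )
  if (!is.null(tree$hpd)) {
    out$hpd_lower[tree$hpd$node] <- tree$hpd$lower
    out$hpd_upper[tree$hpd$node] <- tree$hpd$upper
  }
  out
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf("Dated tree: %d tips, %d internal nodes, height %.4g Ma\n",
              ape::Ntip(x), x$Nnode, max(x$node_age)))
  if (!is.null(x$hpd)) {
    cat(sprintf("  HPD intervals on %d node(s) [key: %s]\n",
                nrow(x$hpd), x$annot_key %||% "?"))
  }
  if (length(x$polytomies) > 0) {
    cat(sprintf("  %d polytomy node(s) recorded\n", length(x$polytomies)))
  }
  invisible(x)
}

# --- internal: comment tokenizer ---------------------------------------------

# Replace each bracketed Newick comment with a sentinel token spliced into the
# label of the node the comment annotates, so ape can parse the tree and the
# comment can be re-attached to a node number afterwards. Handles comments
# after a tip label, after ')' (before or after an internal-node label), and
# after a branch length.
split_newick_comments <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  out <- character(0)
  comments <- character(0)
  colon_pos <- NA_integer_  # index in `out` of the ':' opening a length token
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated '[' comment in Newick input", call. = FALSE)
      comments <- c(comments, paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      sent <- strsplit(sprintf("@CMT%d@", length(comments)), "")[[1]]
      if (is.na(colon_pos)) {
        out <- c(out, sent)
      } else {
        out <- append(out, sent, after = colon_pos - 1L)
        colon_pos <- colon_pos + length(sent)
      }
      i <- j + 1L
      next
    }
    if (ch %in% c("(", ",", ")")) colon_pos <- NA_integer_
    if (ch == ":" && is.na(colon_pos)) colon_pos <- length(out) + 1L
    out <- c(out, ch)
    i <- i + 1L
  }
  list(newick = paste(out, collapse = ""), comments = comments)
}

# map sentinel tokens in parsed labels to node numbers
locate_comment_sentinels <- function(phy) {
  labs <- c(phy$tip.label, phy$node.label %||% rep("", phy$Nnode))
  m <- regmatches(labs, gregexpr("@CMT([0-9]+)@", labs))
  loc <- integer(0)
  for (node in seq_along(m)) {
    if (length(m[[node]]) > 0) {
      ks <- as.integer(sub("@CMT([0-9]+)@", "\\1", m[[node]]))
      loc[ks] <- node
    }
  }
  loc
}

strip_sentinels <- function(x) gsub("@CMT[0-9]+@", "", x)

parse_hpd_comments <- function(comments, loc, hpd_key, n_tip) {
  key_re <- gsub("([][{}()+*^$|\\\\?.%])", "\\\\\\1", hpd_key)
  pat <- paste0(key_re, "=\\{\\s*([-+0-9.eE]+)\\s*,\\s*([-+0-9.eE]+)\\s*\\}")
  rows <- list()
  any_comment_on_internal <- FALSE
  for (k in seq_along(comments)) {
    node <- if (k <= length(loc)) loc[k] else NA_integer_
    if (is.na(node) || node <= n_tip) next  # HPDs attach to internal nodes only
    any_comment_on_internal <- TRUE
    m <- regmatches(comments[k], regexec(pat, comments[k]))[[1]]
    if (length(m) == 3) {
      lo <- as.numeric(m[2]); hi <- as.numeric(m[3])
      rows[[length(rows) + 1L]] <-
        tibble(node = node, lower = min(lo, hi), upper = max(lo, hi))
    }
  }
  if (length(rows) == 0) {
    if (any_comment_on_internal) {
      warning("no readable '", hpd_key,
              "' annotation found in node comments; HPDs absent",
              call. = FALSE)
    }
    return(NULL)
  }
  bind_rows(rows) |> arrange(.data$node)
}
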