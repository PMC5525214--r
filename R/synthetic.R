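# Synthetic fixtures: random phylogenies, clade-cut taxonomy, copy
# numbers, and ecosystem-structured sparse abundance profiles. These
# emulate the statistical shape the search assumes — high-dimensional,
# sparse abundance vectors clustered by environment — so the whole
# pipeline is exercisable without any external database.

#' Random coalescent phylogeny
#'
#' Binary random merge order with coalescent branch lengths, rescaled to
#' the requested root-to-tip height (default 1 tree unit, which puts
#' leaf-to-leaf path lengths in `[0, 2]` and pairwise community
#' distances on the scale the search radii 0.1-0.4 address).
#' Deterministic per seed.
#'
#' @param n_leaves Number of leaves (labels `otu0001`, ...).
#' @param seed Integer seed.
#' @param height Root-to-deepest-tip height after rescaling.
#' @return An `ms_tree`.
#' @export
random_tree <- function(n_leaves, seed = 1L, height = 1) {
  stopifnot(n_leaves >= 1L)
  labels <- sprintf("otu%04d", seq_len(n_leaves))
  if (n_leaves == 1L) {
    return(parse_newick(sprintf("(%s:%.10g);", labels, height)))
  }
  ph <- withr::with_seed(seed, ape::rcoal(n_leaves, tip.label = labels))
  depth <- max(ape::node.depth.edgelength(ph))
  ph$edge.length <- ph$edge.length * height / depth
  phylo_to_tree(ph)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Ecosystem-structured random profiles
#'
#' Each ecosystem owns a random leaf subset of expected size
#' `sparsity * n_leaves` and a Dirichlet center over it; samples draw
#' sample-specific proportions around the center (concentration
#' `separability * |support|`; larger = tighter within-ecosystem
#' clusters) and then multinomial read counts at Poisson-distributed
#' depth. Metadata records the true ecosystem label. Taxonomy is derived
#' by clade cuts of the tree (ancestor identity at rank-specific depth
#' levels) and copy numbers are uniform on 1..10.
#'
#' @param tree An `ms_tree`.
#' @param n_samples Number of samples.
#' @param n_ecosystems Number of ecosystems (samples split evenly).
#' @param mean_depth Mean sequencing depth per sample (Poisson).
#' @param sparsity Expected fraction of leaves with non-zero abundance
#'   per sample, in (0, 1].
#' @param separability Dirichlet concentration multiplier controlling
#'   how tightly samples cluster around their ecosystem center.
#' @param seed Integer seed; the fixture is a pure function of it.
#' @return A list: `db` (an `ms_database`), `taxonomy` (tibble),
#'   `copy_numbers` (named vector).
#' @export
random_profiles <- function(tree, n_samples, n_ecosystems = 3L,
                            mean_depth = 2000, sparsity = 0.05,
                            separability = 5, seed = 1L) {
  stopifnot(inherits(tree, "ms_tree"), n_samples >= 1L, n_ecosystems >= 1L,
            sparsity > 0, sparsity <= 1, mean_depth > 0)
  withr::with_seed(seed, {
    support_n <- max(2L, min(tree$n_leaves,
                             round(sparsity * tree$n_leaves)))
    ecosystems <- lapply(seq_len(n_ecosystems), function(e) {
      leaves <- sort(sample(names(tree$leaf_index), support_n))
      list(leaves = leaves, center = rdirichlet1(rep(1, support_n)))
    })
    eco_of <- rep(seq_len(n_ecosystems), length.out = n_samples)
    profiles <- lapply(seq_len(n_samples), function(i) {
      eco <- ecosystems[[eco_of[i]]]
      props <- rdirichlet1(eco$center * separability * support_n)
      depth <- max(1L, stats::rpois(1L, mean_depth))
      counts <- stats::rmultinom(1L, depth, props)[, 1L]
      abundance_profile(sprintf("s%04d", i),
                        stats::setNames(counts, eco$leaves))
    })
    metadata <- tibble::tibble(
      sample_id = vapply(profiles, `[[`, character(1), "sample_id"),
      ecosystem = sprintf("eco%d", eco_of),
      annotation = sprintf("synthetic community from ecosystem eco%d",
                           eco_of)
    )
    list(
      db = sample_database(profiles, metadata),
      taxonomy = clade_taxonomy(tree),
      copy_numbers = stats::setNames(
        sample.int(10L, tree$n_leaves, replace = TRUE),
        names(tree$leaf_index))
    )
  })
}

# Taxonomy by clade cuts: the label at rank r is the identity of the
# leaf's ancestor at a rank-specific depth level, so related leaves
# share lineages exactly as clades nest.
clade_taxonomy <- function(tree) {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  cut_levels <- round(seq(0, max(tree$max_level - 1L, 0L), length.out = 7L))
  rows <- lapply(names(tree$leaf_index), function(leaf) {
    path <- rev(ancestor_path(tree, leaf))  # root ... leaf
    lineage <- vapply(seq_along(ranks), function(r) {
      node <- path[min(cut_levels[r] + 1L, length(path))]
      sprintf("%s_n%d", substr(ranks[r], 1L, 1L), node)
    }, character(1))
    c(otu = leaf, stats::setNames(lineage, ranks))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Precompute the all-versus-all database distance matrix
#'
#' Performs exactly `choose(|M|, 2)` metric evaluations, optionally
#' writing the matrix to the plain-text store (which round-trips
#' bit-exactly) and attaching it to the returned database.
#'
#' @param db An `ms_database`.
#' @param metric Metric over profiles (e.g. [emd_metric()] applied to
#'   prepared profiles; count profiles are normalized internally when
#'   `tree` is given instead).
#' @param path Optional output path for the on-disk store.
#' @return The database with `precalc` populated; the number of metric
#'   evaluations is in `attr(db$precalc, "n_evaluations")`.
#' @export
build_precalc <- function(db, metric, path = NULL) {
  stopifnot(inherits(db, "ms_database"))
  ids <- sort(names(db$profiles))
  cm <- counted_metric(metric)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        m[i, j] <- m[j, i] <- cm$f(db$profiles[[ids[i]]],
                                   db$profiles[[ids[j]]])
      }
    }
  }
  attr(m, "n_evaluations") <- cm$env$n
  if (!is.null(path)) write_dist_matrix(m, path)
  db$precalc <- m
  db
}

#' Generate and write a complete fixture directory
#'
#' Writes everything the readers consume: `tree.nwk`, `otu_table.tsv`,
#' `taxonomy.tsv`, `copy_numbers.tsv`, `metadata.tsv` and (optionally)
#' `precalc.tsv` (EMD-UniFrac over relative profiles).
#'
#' @param dir Output directory (created if needed).
#' @param n_leaves,n_samples,n_ecosystems,mean_depth,sparsity,separability,seed
#'   Passed to [random_tree()] / [random_profiles()].
#' @param precalc Also compute and write the distance store.
#' @return The `ms_database` (with tree/taxonomy/copy-number
#'   attributes), invisibly.
#' @export
simulate_fixture <- function(dir, n_leaves = 200L, n_samples = 60L,
                             n_ecosystems = 3L, mean_depth = 2000,
                             sparsity = 0.05, separability = 5,
                             seed = 1L, precalc = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tree <- random_tree(n_leaves, seed = seed)
  fx <- random_profiles(tree, n_samples, n_ecosystems = n_ecosystems,
                        mean_depth = mean_depth, sparsity = sparsity,
                        separability = separability, seed = seed + 1L)
  db <- fx$db
  writeLines(write_newick(tree), file.path(dir, "tree.nwk"))
  write_otu_table(db$profiles, file.path(dir, "otu_table.tsv"))
  write_metadata(db$metadata, file.path(dir, "metadata.tsv"))
  write_taxonomy(fx$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_copy_numbers(fx$copy_numbers, file.path(dir, "copy_numbers.tsv"))
  if (precalc) {
    metric <- emd_metric(tree)
    prep <- prepare_relative(tree, db$profiles)
    db <- build_precalc(sample_database(prep, db$metadata), metric,
                        path = file.path(dir, "precalc.tsv"))
    db <- sample_database(fx$db$profiles, fx$db$metadata, db$precalc)
  }
  attr(db, "tree") <- tree
  attr(db, "taxonomy") <- fx$taxonomy
  attr(db, "copy_numbers") <- fx$copy_numbers
  invisible(db)
}
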