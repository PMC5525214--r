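# Shared fixture builders. Everything is generated in code at test time.

tree_abcd <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1):0;")

prof <- function(id, ...) {
  abundance_profile(id, c(...))
}

rel <- function(id, ...) to_relative(abundance_profile(id, c(...)))

# Random relative profile over a tree's leaves.
random_rel_profile <- function(tree, id, max_support = 10L) {
  leaves <- names(tree$leaf_index)
  s <- sample(leaves, min(length(leaves), sample.int(max_support, 1L)))
  to_relative(abundance_profile(id, stats::setNames(runif(length(s)), s)))
}

# A small ecosystem-structured database with tree/taxonomy attributes,
# plus prepared relative profiles and the UniFrac metric.
search_fixture <- function(n_leaves = 128L, n_samples = 60L,
                           n_queries = 3L, seed = 42L,
                           separability = 5, precalc = TRUE) {
  tree <- random_tree(n_leaves, seed = seed)
  fx <- random_profiles(tree, n_samples + n_queries,
                        separability = separability, seed = seed + 1L)
  all_ids <- names(fx$db$profiles)
  qids <- all_ids[seq_len(n_queries) * floor(n_samples / n_queries)]
  dbids <- setdiff(all_ids, qids)
  meta <- fx$db$metadata[fx$db$metadata$sample_id %in% dbids, ]
  db <- sample_database(fx$db$profiles[dbids], meta)
  metric <- emd_metric(tree)
  prep <- prepare_relative(tree, db$profiles)
  if (precalc) {
    pdb <- build_precalc(sample_database(prep, meta), metric)
    db <- sample_database(db$profiles, meta, pdb$precalc)
  }
  attr(db, "tree") <- tree
  list(tree = tree, db = db, metric = metric, prep = prep,
       queries = fx$db$profiles[qids],
       qprep = prepare_relative(tree, fx$db$profiles[qids]),
       query_eco = stats::setNames(
         fx$db$metadata$ecosystem[match(qids, fx$db$metadata$sample_id)],
         qids),
       taxonomy = fx$taxonomy, copy_numbers = fx$copy_numbers)
}
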