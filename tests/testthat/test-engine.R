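make_record <- function(qid, d) {
  new_search_record(qid, d, radius = Inf)
}

test_that("context selection intersects records then takes per-query top k", {
  r1 <- make_record("n1", c(s1 = 0.1, s2 = 0.2, s3 = 0.5))
  r2 <- make_record("n2", c(s2 = 0.15, s3 = 0.4))
  expect_equal(select_context(list(r1, r2), k = 20), c("s2", "s3"))
  # with k = 1 the ranking is restricted to the intersection {s2, s3}
  expect_equal(select_context(list(r1, r2), k = 1), "s2")
  r <- make_record("n1", c(a = 0.3, b = 0.1))
  expect_equal(select_context(list(r), k = 10), c("a", "b"))
  r3 <- make_record("n3", c(zz = 0.2))
  expect_error(select_context(list(r1, r3)), class = "ms_empty_context")
})

test_that("matrix composition fills every block from its stated source", {
  tr <- tree_abcd()
  metric <- emd_metric(tr)
  dbp <- prepare_relative(tr, list(abundance_profile("m1", c(A = 1)),
                                   abundance_profile("m2", c(B = 1))))
  q <- prepare_relative(tr, list(abundance_profile("n1", c(C = 1))))
  precalc <- matrix(c(0, 2, 2, 0), 2, 2,
                    dimnames = list(c("m1", "m2"), c("m1", "m2")))
  rec <- make_record("n1", c(m1 = 4, m2 = 4))
  full <- assemble_matrix(c("m1", "m2"), q, precalc, list(rec), metric)
  expect_equal(dim(full), c(3L, 3L))
  expect_equal(diag(full), stats::setNames(rep(0, 3), c("m1", "m2", "n1")))
  expect_equal(full["m1", "m2"], 2)
  expect_equal(full["m1", "n1"], 4)
  # every cell agrees with recomputing the metric directly
  profs <- c(dbp, q)
  for (a in rownames(full)) for (b in colnames(full)) {
    expect_equal(full[a, b], metric(profs[[a]], profs[[b]]),
                 tolerance = 1e-9)
  }
  bad <- precalc
  bad[1, 2] <- 3
  expect_error(assemble_matrix(c("m1", "m2"), q, bad, list(rec), metric),
               "asymmetric")
  expect_error(
    assemble_matrix(c("m1", "m2"), q, precalc,
                    list(make_record("n1", c(m1 = 4))), metric),
    "missing pair")
})

test_that("classical scaling reproduces embeddable distances", {
  m <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  co <- ms_pcoa(m, dims = 1)
  d12 <- abs(co$Axis1[1] - co$Axis1[2])
  d13 <- abs(co$Axis1[1] - co$Axis1[3])
  d23 <- abs(co$Axis1[2] - co$Axis1[3])
  expect_equal(c(d12, d13, d23), c(1, 2, 1), tolerance = 1e-9)

  eq <- matrix(1, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(eq) <- 0
  co2 <- ms_pcoa(eq, dims = 2)
  pts <- as.matrix(co2[, c("Axis1", "Axis2")])
  expect_equal(as.numeric(stats::dist(pts)), rep(1, 3), tolerance = 1e-9)

  # identical points embed at distance zero
  z <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  cz <- ms_pcoa(z, dims = 1)
  expect_equal(cz$Axis1[1], cz$Axis1[2], tolerance = 1e-9)

  # Euclidean-embeddable matrix reproduced at full dimensionality
  set.seed(3)
  x <- matrix(rnorm(5 * 3), 5, 3)
  dm <- as.matrix(stats::dist(x))
  dimnames(dm) <- list(paste0("p", 1:5), paste0("p", 1:5))
  cf <- ms_pcoa(dm, dims = 4)
  rec <- as.matrix(stats::dist(as.matrix(cf[, -1])))
  expect_lt(max(abs(rec - dm)), 1e-6)
})

test_that("UPGMA merges at half the cophenetic distance", {
  m <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.9, 0.9, 0.9, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  dd <- hierarchical_cluster(m)
  expect_equal(dd$heights[1], 0.05)
  expect_match(dd$newick, "a:0.05")
  ident <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(hierarchical_cluster(ident)$heights[1], 0)
  # 4-point fixture against hand-computed UPGMA
  m4 <- matrix(c(0, 2, 6, 10,
                 2, 0, 6, 10,
                 6, 6, 0, 10,
                 10, 10, 10, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  d4 <- hierarchical_cluster(m4)
  # merges: (a,b)@1, (ab,c)@3, (abc,d)@5
  expect_equal(d4$heights, c(1, 3, 5))
})

test_that("binned p-values track exact pair counting", {
  d6 <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  tab <- build_pvalue_table(d6, bins = 10000)
  expect_equal(tab$total_pairs, 6L)
  expect_equal(tab$below_edge[length(tab$below_edge)], 6)
  expect_equal(empirical_pvalue(tab, 0.35), 0.5)
  expect_equal(empirical_pvalue(tab, 0), 0)
  expect_equal(empirical_pvalue(tab, 0.7), 1)
  # within one bin width of exact counting on random distances
  set.seed(12)
  dists <- runif(400, 0, 0.9)
  tab2 <- build_pvalue_table(dists, bins = 10000)
  width <- diff(tab2$bin_edges[1:2])
  for (x in runif(50, 0, 1)) {
    exact <- mean(dists < x)
    approx <- empirical_pvalue(tab2, x)
    expect_lte(abs(approx - exact), mean(dists >= x - width & dists < x) +
                 1e-12)
    expect_gte(approx, 0)
    expect_lte(approx, 1)
  }
  # monotone in d
  xs <- sort(runif(30, 0, 1))
  ps <- empirical_pvalue(tab2, xs)
  expect_false(is.unsorted(ps))
})

test_that("a 4-sample table counts all binomial pairs", {
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m[upper.tri(m)] <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  m <- m + t(m)
  tab <- build_pvalue_table(m)
  expect_equal(tab$total_pairs, 6L)
})

test_that("representative selection respects filter, cap and seed", {
  fx <- search_fixture(n_leaves = 64L, n_samples = 30L, n_queries = 1L,
                       seed = 21L)
  reps_all <- select_representatives(fx$db, "All", max_n = 1000)
  expect_setequal(reps_all, names(fx$db$profiles))
  eco1 <- fx$db$metadata$sample_id[fx$db$metadata$ecosystem == "eco1"]
  reps1 <- select_representatives(fx$db, "eco1", max_n = 1000)
  expect_setequal(reps1, eco1)
  capped <- select_representatives(fx$db, "All", max_n = 10, seed = 4)
  expect_length(capped, 10L)
  expect_identical(capped, select_representatives(fx$db, "All", max_n = 10,
                                                  seed = 4))
  # medoids span the ecosystem structure
  eco_of <- stats::setNames(fx$db$metadata$ecosystem,
                            fx$db$metadata$sample_id)
  expect_setequal(unique(eco_of[capped]), unique(fx$db$metadata$ecosystem))
  expect_error(select_representatives(fx$db, "no-such-eco"), "filter")
})

test_that("type-I search ranks exact matches first with p-value zero", {
  fx <- search_fixture(n_leaves = 96L, n_samples = 45L, n_queries = 2L,
                       seed = 31L)
  q <- fx$db$profiles[[10]]
  qcopy <- abundance_profile("query_copy", named_counts(q))
  res <- run_type1(fx$db, list(qcopy), tree = fx$tree, method = "gnat",
                   seed = 2)
  top <- res$ranking[res$ranking$rank == 1, ]
  expect_equal(top$match_id, q$sample_id)
  expect_equal(top$distance, 0)
  expect_equal(top$p_value, 0)
  # two identical queries get identical per-query rankings
  res2 <- run_type1(fx$db,
                    list(qcopy, abundance_profile("query_copy2",
                                                  named_counts(q))),
                    tree = fx$tree, method = "gnat", seed = 2)
  r1 <- res2$ranking[res2$ranking$query_id == "query_copy", -1]
  r2 <- res2$ranking[res2$ranking$query_id == "query_copy2", -1]
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("type-I ranking equals the linear-oracle ranking on hits", {
  fx <- search_fixture(n_leaves = 96L, n_samples = 45L, n_queries = 2L,
                       seed = 33L)
  for (method in c("gnat", "aesa")) {
    res <- run_type1(fx$db, fx$queries, tree = fx$tree, method = method,
                     radius = 0.3, k = 1000, seed = 3)
    for (qid in names(fx$qprep)) {
      lin <- linear_range_search(fx$prep, fx$qprep[[qid]], 0.3, fx$metric)
      mine <- res$ranking[res$ranking$query_id == qid, ]
      expect_equal(mine$match_id, lin$hits)
      expect_equal(mine$distance, lin$hit_distances, tolerance = 1e-12)
    }
  }
})

test_that("queries from one ecosystem retrieve that ecosystem", {
  # an easy, well-separated instance by construction
  fx <- search_fixture(n_leaves = 200L, n_samples = 45L, n_queries = 3L,
                       seed = 51L, separability = 40)
  eco_of <- stats::setNames(fx$db$metadata$ecosystem,
                            fx$db$metadata$sample_id)
  res <- run_type1(fx$db, fx$queries, tree = fx$tree, method = "aesa",
                   radius = 0.4, k = 5, seed = 6)
  for (qid in unique(res$ranking$query_id)) {
    hits <- res$ranking[res$ranking$query_id == qid, ]
    labs <- eco_of[hits$match_id]
    # majority of top matches carry the query's true ecosystem label
    expect_gte(mean(labs == fx$query_eco[qid]), 0.5)
  }
})

test_that("query limits are enforced per method and overridable", {
  fx <- search_fixture(n_leaves = 64L, n_samples = 20L, n_queries = 1L,
                       seed = 61L)
  many <- lapply(1:11, function(i) {
    abundance_profile(paste0("q", i), named_counts(fx$queries[[1]]))
  })
  expect_error(run_type1(fx$db, many, tree = fx$tree, method = "gnat"),
               class = "ms_validation_error")
  expect_no_error(
    run_type1(fx$db, many[1:2], tree = fx$tree, method = "gnat", seed = 1))
  expect_no_error(
    res <- run_type1(fx$db, many, tree = fx$tree, method = "gnat",
                     enforce_limits = FALSE, seed = 1))
})

test_that("type-II search ranks representatives by Bray-Curtis", {
  fx <- search_fixture(n_leaves = 96L, n_samples = 30L, n_queries = 1L,
                       seed = 71L)
  rep1 <- fx$db$profiles[[4]]
  qcopy <- abundance_profile("qc", named_counts(rep1))
  res <- run_type2(fx$db, list(qcopy), k = 10, seed = 2)
  top <- res$ranking[res$ranking$rank == 1, ]
  expect_equal(top$match_id, rep1$sample_id)
  expect_equal(top$distance, 0)
  expect_true(all(res$ranking$distance >= 0 & res$ranking$distance <= 1))
  expect_true(all(res$full_matrix >= 0 & res$full_matrix <= 1))
  # ecosystem recovery on an easy instance
  fx2 <- search_fixture(n_leaves = 200L, n_samples = 30L, n_queries = 2L,
                        seed = 73L, separability = 40)
  eco_of <- stats::setNames(fx2$db$metadata$ecosystem,
                            fx2$db$metadata$sample_id)
  res2 <- run_type2(fx2$db, fx2$queries, k = 3, seed = 2)
  for (qid in unique(res2$ranking$query_id)) {
    hits <- res2$ranking[res2$ranking$query_id == qid, ]
    labs <- eco_of[hits$match_id]
    expect_gte(mean(labs == fx2$query_eco[qid]), 0.5)
  }
})

test_that("composition comparison orders taxa by the query's fractions", {
  tax <- tibble::tibble(
    otu = c("o1", "o2"), kingdom = "k", phylum = c("X", "Y"),
    class = c("cX", "cY"), order = "o", family = c("fX", "fY"),
    genus = c("gX", "gY"), species = "s")
  q <- prof("q", o1 = 6, o2 = 4)
  m <- prof("m", o1 = 5, o2 = 5)
  cc <- composition_comparison(q, m, tax, ranks = "phylum")
  expect_equal(cc$taxon, c("X", "Y"))
  expect_equal(cc$query_fraction, c(0.6, 0.4))
  expect_equal(cc$match_fraction, c(0.5, 0.5))
  # absent taxon reports zero; fractions sum to 1 per sample per rank
  cc2 <- composition_comparison(prof("q", o1 = 1),
                                prof("m", o1 = 1, o2 = 3), tax,
                                ranks = c("phylum", "genus"))
  for (rk in unique(cc2$rank)) {
    sub <- cc2[cc2$rank == rk, ]
    expect_equal(sum(sub$query_fraction), 1)
    expect_equal(sum(sub$match_fraction), 1)
    expect_equal(sub$query_fraction[sub$taxon %in% c("Y", "gY")], 0)
  }
  ccid <- composition_comparison(q, prof("m2", o1 = 6, o2 = 4), tax,
                                 ranks = "phylum")
  expect_equal(ccid$query_fraction, ccid$match_fraction)
  expect_error(composition_comparison(q, m, tax,
                                      ranks = c("phylum", "class",
                                                "order", "family")),
               "at most three")
})

test_that("phyla-key false negatives are counted per threshold", {
  ids <- paste0("s", 1:4)
  m <- matrix(0, 4, 4, dimnames = list(ids, ids))
  m[upper.tri(m)] <- c(0.05, 0.15, 0.25, 0.35, 0.45, 0.55)
  m <- m + t(m)
  keys <- stats::setNames(c("A|B", "A|B", "A|C", "A|B"), ids)
  tab <- phyla_index_fn_table(m, keys, thresholds = c(0.1, 0.3, 0.6))
  expect_equal(tab$total_pairs, c(1L, 3L, 6L))
  # below 0.3 (column-major fill): (s1,s2)=.05 same, (s1,s3)=.15 diff,
  # (s2,s3)=.25 diff
  expect_equal(tab$differing_pairs, c(0L, 2L, 3L))
  expect_equal(tab$percentage, c(0, 66.67, 50))
  # all samples sharing a key: zero differing everywhere
  same <- phyla_index_fn_table(m, stats::setNames(rep("A|B", 4), ids),
                               thresholds = c(0.1, 0.3, 0.6))
  expect_equal(same$differing_pairs, c(0L, 0L, 0L))
  # empty threshold bucket: undefined percentage, not zero
  none <- phyla_index_fn_table(m, keys, thresholds = 0.01)
  expect_equal(none$total_pairs, 0L)
  expect_true(is.na(none$percentage))
})

test_that("tidiers and plots expose the result types", {
  fx <- search_fixture(n_leaves = 64L, n_samples = 20L, n_queries = 1L,
                       seed = 81L)
  res <- run_type1(fx$db, fx$queries, tree = fx$tree, method = "gnat",
                   seed = 1, taxonomy = fx$taxonomy)
  expect_s3_class(tidy(res$pcoa), "tbl_df")
  expect_s3_class(glance(res$pcoa), "tbl_df")
  expect_s3_class(tidy(res$dendrogram), "tbl_df")
  expect_s3_class(tidy(res$records[[1]]), "tbl_df")
  expect_s3_class(autoplot(res$pcoa), "ggplot")
  expect_s3_class(autoplot(res$dendrogram), "ggplot")
  expect_s3_class(plot_ranking(res$ranking), "ggplot")
  expect_s3_class(plot_composition(res$ranking$composition[[1]]), "ggplot")
})
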