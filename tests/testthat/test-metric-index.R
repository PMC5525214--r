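# One moderate fixture shared across the index tests.
fx <- search_fixture(n_leaves = 100L, n_samples = 80L, n_queries = 4L,
                     seed = 11L, precalc = FALSE)

test_that("linear oracle evaluates everything once and sorts hits", {
  q <- fx$qprep[[1]]
  rec <- linear_range_search(fx$prep, q, 0.3, fx$metric)
  expect_equal(rec$n_evaluations, length(fx$prep))
  expect_equal(length(rec$evaluated), length(fx$prep))
  expect_false(is.unsorted(rec$hit_distances))
  expect_true(all(rec$hit_distances <= 0.3))
  none <- linear_range_search(fx$prep, q, 0, fx$metric)
  expect_true(all(none$evaluated[none$hits] == 0))
})

test_that("GNAT stores every id exactly once and builds subquadratically", {
  single <- build_gnat(fx$prep[1], fx$metric)
  expect_equal(single$root$type, "leaf")
  expect_equal(single$root$ids, names(fx$prep)[1])

  gn <- build_gnat(fx$prep, fx$metric, seed = 2)
  stored <- gnat_stored_ids(gn$root)
  expect_equal(sort(stored), sort(names(fx$prep)))
  expect_equal(length(stored), length(fx$prep))
  n <- length(fx$prep)
  expect_lt(gn$n_build_evaluations, n * (n - 1) / 2)
})

test_that("GNAT range tables hold the true min/max on build", {
  gn <- build_gnat(fx$prep, fx$metric, seed = 2)
  node <- gn$root
  expect_equal(node$type, "internal")
  members <- lapply(seq_along(node$pivots), function(j) {
    child_ids <- gnat_stored_ids(node$children[[j]])
    c(node$pivots[j], child_ids)
  })
  for (i in seq_along(node$pivots)) {
    for (j in seq_along(node$pivots)) {
      d <- vapply(members[[j]], function(x) {
        fx$metric(fx$prep[[node$pivots[i]]], fx$prep[[x]])
      }, numeric(1))
      expect_equal(node$rmin[i, j], min(d), tolerance = 1e-12)
      expect_equal(node$rmax[i, j], max(d), tolerance = 1e-12)
    }
  }
})

test_that("GNAT range search is exact against the linear oracle", {
  gn <- build_gnat(fx$prep, fx$metric, seed = 2)
  for (q in fx$qprep) {
    for (r in c(0.1, 0.2, 0.3, 0.4)) {
      g <- gnat_range_search(gn, q, r, fx$metric)
      l <- linear_range_search(fx$prep, q, r, fx$metric)
      expect_setequal(g$hits, l$hits)
      expect_lte(g$n_evaluations, l$n_evaluations)
      # pruning soundness: everything never evaluated is truly out of range
      skipped <- setdiff(names(fx$prep), names(g$evaluated))
      if (length(skipped)) {
        dskip <- vapply(fx$prep[skipped], fx$metric, numeric(1), q)
        expect_true(all(dskip > r))
      }
    }
  }
  # a database sample queried at radius 0 finds itself
  self <- gnat_range_search(gn, fx$prep[[7]], 0, fx$metric)
  expect_true(names(fx$prep)[7] %in% self$hits)
  # radius beyond the diameter returns the whole database
  all_hits <- gnat_range_search(gn, fx$qprep[[1]], 10, fx$metric)
  expect_setequal(all_hits$hits, names(fx$prep))
})

test_that("asymmetric distances are detected at build time", {
  flip <- local({
    k <- 0
    function(a, b) {
      k <<- k + 1
      k * 0.01  # changes every call: cannot be symmetric
    }
  })
  expect_error(build_gnat(fx$prep[1:10], flip, seed = 1),
               "asymmetry")
  expect_error(build_aesa(fx$prep[1:4], flip, check_metric = TRUE),
               "asymmetry")
})

test_that("AESA precalculation is exactly the binomial pair count", {
  sub <- fx$prep[1:4]
  ae <- build_aesa(sub, fx$metric)
  expect_equal(ae$n_build_evaluations, 6L)
  expect_equal(build_aesa(fx$prep[1], fx$metric)$n_build_evaluations, 0L)
  expect_equal(diag(ae$pairwise), stats::setNames(rep(0, 4), ae$ids))
  expect_equal(ae$pairwise, t(ae$pairwise))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(ae$pairwise[i, j],
                 fx$metric(sub[[ae$ids[i]]], sub[[ae$ids[j]]]),
                 tolerance = 1e-12)
  }
})

test_that("AESA eliminates by lower bound exactly as hand-traced", {
  # two points at distance 1; query sits on x1; x2 must die unevaluated
  tr <- tree_abcd()
  x1 <- rel("x1", A = 1)
  x2 <- rel("x2", C = 1)  # d(x1, x2) = 4 in tree units; rescale radius
  metric <- emd_metric(tr)
  ae <- build_aesa(list(x1 = x1, x2 = x2), metric)
  recq <- aesa_range_search(ae, rel("q", A = 1), 0.3, metric)
  expect_equal(recq$hits, "x1")
  expect_equal(recq$n_evaluations, 1L)  # x2 eliminated by lb = 4 > 0.3
})

test_that("AESA range search is exact and evaluates fewer than linear", {
  ae <- build_aesa(fx$prep, fx$metric)
  evals <- c()
  for (q in fx$qprep) {
    for (r in c(0.1, 0.2, 0.3, 0.4)) {
      a <- aesa_range_search(ae, q, r, fx$metric)
      l <- linear_range_search(fx$prep, q, r, fx$metric)
      expect_setequal(a$hits, l$hits)
      expect_lte(a$n_evaluations, length(fx$prep))
      if (r == 0.3) evals <- c(evals, a$n_evaluations)
      skipped <- setdiff(names(fx$prep), names(a$evaluated))
      if (length(skipped)) {
        dskip <- vapply(fx$prep[skipped], fx$metric, numeric(1), q)
        expect_true(all(dskip > r))
      }
    }
  }
  expect_lt(mean(evals), length(fx$prep))
  big <- aesa_range_search(ae, fx$qprep[[2]], 10, fx$metric)
  expect_setequal(big$hits, names(fx$prep))
})

test_that("hit sets grow monotonically with the radius", {
  gn <- build_gnat(fx$prep, fx$metric, seed = 5)
  ae <- build_aesa(fx$prep, fx$metric)
  q <- fx$qprep[[3]]
  prev_g <- character(0)
  prev_a <- character(0)
  for (r in c(0.05, 0.15, 0.3, 0.6)) {
    g <- gnat_range_search(gn, q, r, fx$metric)$hits
    a <- aesa_range_search(ae, q, r, fx$metric)$hits
    expect_true(all(prev_g %in% g))
    expect_true(all(prev_a %in% a))
    prev_g <- g
    prev_a <- a
  }
})

test_that("indexes survive JSON serialization and search identically", {
  gn <- build_gnat(fx$prep, fx$metric, seed = 2)
  ae <- build_aesa(fx$prep[1:20], fx$metric)
  gpath <- withr::local_tempfile(fileext = ".json")
  apath <- withr::local_tempfile(fileext = ".json")
  write_index(gn, gpath)
  write_index(ae, apath)
  gn2 <- read_index(gpath, fx$prep)
  ae2 <- read_index(apath, fx$prep[1:20])
  q <- fx$qprep[[1]]
  expect_equal(gnat_range_search(gn2, q, 0.3, fx$metric)$hits,
               gnat_range_search(gn, q, 0.3, fx$metric)$hits)
  expect_equal(aesa_range_search(ae2, q, 0.3, fx$metric)$evaluated,
               aesa_range_search(ae, q, 0.3, fx$metric)$evaluated)
})
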