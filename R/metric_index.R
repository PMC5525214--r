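# Exact metric-space range search: GNAT, AESA and a brute-force linear
# oracle. Every search records all true metric evaluations it performs,
# so instrumentation (n_evaluations) and the context-selection step can
# both be driven from the same record.

# Counting wrapper around a metric; keeps a per-build/-search ledger of
# how many true evaluations were made.
counted_metric <- function(metric) {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  f <- function(a, b) {
    env$n <- env$n + 1L
    metric(a, b)
  }
  list(f = f, env = env)
}

db_profiles <- function(db) {
  if (inherits(db, "ms_database")) db$profiles else db
}

new_search_record <- function(query_id, evaluated, radius) {
  evaluated <- evaluated[order(names(evaluated))]
  hit_ids <- names(evaluated)[evaluated <= radius]
  hits <- evaluated[hit_ids]
  hits <- hits[order(hits, names(hits))]
  structure(
    list(query_id = query_id, evaluated = evaluated, hits = names(hits),
         hit_distances = unname(hits), n_evaluations = length(evaluated)),
    class = "ms_search_record"
  )
}

#' @export
print.ms_search_record <- function(x, ...) {
  cat("<ms_search_record> query ", x$query_id, ": ", length(x$hits),
      " hits, ", x$n_evaluations, " distance evaluations\n", sep = "")
  invisible(x)
}

#' Tidy a search record
#'
#' @param x An `ms_search_record`.
#' @param ... Unused.
#' @return A tibble with columns `query_id`, `sample_id`, `distance`,
#'   `hit`, sorted by distance.
#' @export
tidy.ms_search_record <- function(x, ...) {
  tibble::tibble(
    query_id = x$query_id,
    sample_id = names(x$evaluated),
    distance = unname(x$evaluated),
    hit = names(x$evaluated) %in% x$hits
  ) |>
    dplyr::arrange(.data$distance, .data$sample_id)
}

#' Brute-force linear range search (ground-truth oracle)
#'
#' Evaluates the metric against every database sample exactly once.
#'
#' @param db An `ms_database` or named list of profiles.
#' @param q Query profile.
#' @param radius Non-negative search radius.
#' @param metric `function(p, q)` returning a non-negative number.
#' @return An `ms_search_record`; hits are sorted ascending by distance.
#' @export
linear_range_search <- function(db, q, radius, metric) {
  profs <- db_profiles(db)
  d <- vapply(profs, function(s) metric(q, s), numeric(1))
  names(d) <- names(profs)
  new_search_record(q$sample_id, d, radius)
}

#' Build a geometric near-neighbor access tree (GNAT)
#'
#' Recursively selects `branching` pivots greedily (max-min separation
#' from a seeded candidate sample), assigns every remaining point to its
#' nearest pivot (Dirichlet domains), and stores for every pivot pair
#' the exact min/max distance from pivot i to the points of pivot j's
#' domain. Subtrees at or below `leaf_bucket` points are stored flat.
#' Build cost is subquadratic in the database size.
#'
#' @param db An `ms_database` or named list of profiles.
#' @param metric Metric function over profiles.
#' @param branching Pivots per internal node (>= 2).
#' @param leaf_bucket Maximum ids stored in a flat leaf.
#' @param seed Integer seed for candidate sampling.
#' @param check_metric Spot-check symmetry of `metric` on a few pairs and
#'   error if asymmetric beyond 1e-9.
#' @return An `ms_gnat` index; `n_build_evaluations` records the number
#'   of true metric evaluations spent building.
#' @export
build_gnat <- function(db, metric, branching = 8L, leaf_bucket = 16L,
                       seed = 1L, check_metric = TRUE) {
  profs <- db_profiles(db)
  stopifnot(branching >= 2L, length(profs) >= 1L)
  ids <- sort(names(profs))
  cm <- counted_metric(metric)
  dfun <- function(a, b) cm$f(profs[[a]], profs[[b]])
  if (check_metric && length(ids) >= 2L) {
    withr::with_seed(seed, {
      for (k in seq_len(min(3L, length(ids) - 1L))) {
        pr <- sample(ids, 2L)
        if (abs(dfun(pr[1], pr[2]) - dfun(pr[2], pr[1])) > 1e-9) {
          stop("non-metric distance: asymmetry detected between ",
               pr[1], " and ", pr[2], call. = FALSE)
        }
      }
    })
  }
  rng <- withr::with_seed(seed, sample.int(2^30, 1L))
  build_node <- function(ids, depth) {
    if (length(ids) <= leaf_bucket) {
      return(list(type = "leaf", ids = sort(ids)))
    }
    ids <- sort(ids)
    n_cand <- min(length(ids), 3L * branching)
    cand <- withr::with_seed(rng + depth,
                             sort(sample(ids, n_cand)))
    # greedy max-min pivot selection among candidates
    pivots <- cand[1L]
    mind <- vapply(cand, function(x) {
      if (x == cand[1L]) 0 else dfun(x, cand[1L])
    }, numeric(1))
    names(mind) <- cand
    mind[pivots] <- -Inf
    while (length(pivots) < min(branching, length(cand))) {
      nxt <- names(mind)[which.max(mind)]   # ties: first = smallest id
      pivots <- c(pivots, nxt)
      mind[nxt] <- -Inf
      dnew <- vapply(cand, function(x) {
        if (x %in% pivots) -Inf else dfun(x, nxt)
      }, numeric(1))
      mind <- pmin(mind, dnew)
    }
    pivots <- sort(pivots)
    b <- length(pivots)
    rest <- setdiff(ids, pivots)
    # distances pivot x point (points include the pivots themselves)
    dmat <- matrix(0, b, length(ids), dimnames = list(pivots, ids))
    for (i in seq_len(b)) {
      for (x in ids) {
        dmat[i, x] <- if (x == pivots[i]) 0 else dfun(pivots[i], x)
      }
    }
    assign_to <- pivots[apply(dmat[, rest, drop = FALSE], 2L, which.min)]
    names(assign_to) <- rest
    rmin <- matrix(Inf, b, b, dimnames = list(pivots, pivots))
    rmax <- matrix(-Inf, b, b, dimnames = list(pivots, pivots))
    members <- lapply(pivots, function(pj) {
      c(pj, rest[assign_to == pj])  # domain includes its pivot
    })
    for (i in seq_len(b)) {
      for (j in seq_len(b)) {
        dij <- dmat[i, members[[j]]]
        rmin[i, j] <- min(dij)
        rmax[i, j] <- max(dij)
      }
    }
    children <- lapply(members, function(m) {
      build_node(setdiff(m, pivots), depth + 1L)
    })
    list(type = "internal", pivots = pivots, rmin = rmin, rmax = rmax,
         children = children)
  }
  root <- build_node(ids, 1L)
  structure(
    list(root = root, ids = ids, branching = as.integer(branching),
         leaf_bucket = as.integer(leaf_bucket),
         profiles = profs[ids],
         n_build_evaluations = cm$env$n),
    class = "ms_gnat"
  )
}

#' @export
print.ms_gnat <- function(x, ...) {
  cat("<ms_gnat> ", length(x$ids), " samples, branching ", x$branching,
      ", ", x$n_build_evaluations, " build evaluations\n", sep = "")
  invisible(x)
}

gnat_stored_ids <- function(node) {
  if (node$type == "leaf") return(node$ids)
  c(node$pivots, unlist(lapply(node$children, gnat_stored_ids)))
}

#' GNAT range search
#'
#' Exact range search: returns every database sample within `radius` of
#' the query (100% recall and precision against the linear oracle). A
#' child domain j is pruned when, for some evaluated pivot i, the
#' interval `[d(q, p_i) - r, d(q, p_i) + r]` does not intersect the
#' stored `[min_ij, max_ij]` range. All true distance evaluations are
#' recorded.
#'
#' @param index An `ms_gnat`.
#' @param q Query profile.
#' @param radius Non-negative radius.
#' @param metric Metric function (same metric the index was built with).
#' @return An `ms_search_record`.
#' @export
gnat_range_search <- function(index, q, radius, metric) {
  stopifnot(inherits(index, "ms_gnat"), radius >= 0)
  evaluated <- new.env(parent = emptyenv())
  dq <- function(id) {
    if (is.null(evaluated[[id]])) {
      evaluated[[id]] <- metric(q, index$profiles[[id]])
    }
    evaluated[[id]]
  }
  walk <- function(node) {
    if (node$type == "leaf") {
      for (id in node$ids) dq(id)
      return(invisible())
    }
    b <- length(node$pivots)
    dpiv <- vapply(node$pivots, dq, numeric(1))
    alive <- rep(TRUE, b)
    for (i in seq_len(b)) {
      lo <- dpiv[i] - radius
      hi <- dpiv[i] + radius
      alive <- alive & !(node$rmax[i, ] < lo | node$rmin[i, ] > hi)
    }
    for (j in which(alive)) walk(node$children[[j]])
  }
  walk(index$root)
  d <- unlist(as.list(evaluated))
  if (is.null(d)) d <- stats::setNames(numeric(0), character(0))
  new_search_record(q$sample_id, d, radius)
}

#' Build an AESA index (full pairwise distance matrix)
#'
#' Performs exactly `n * (n - 1) / 2` metric evaluations to precompute
#' the symmetric all-versus-all distance matrix that AESA's
#' triangle-inequality lower bounds require.
#'
#' @inheritParams build_gnat
#' @param check_metric If `TRUE`, additionally spot-check symmetry (costs
#'   extra evaluations beyond the exact pair count; off by default).
#' @return An `ms_aesa` index with the pairwise matrix and the profiles.
#' @export
build_aesa <- function(db, metric, check_metric = FALSE) {
  profs <- db_profiles(db)
  stopifnot(length(profs) >= 1L)
  ids <- sort(names(profs))
  n <- length(ids)
  cm <- counted_metric(metric)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        m[i, j] <- m[j, i] <- cm$f(profs[[ids[i]]], profs[[ids[j]]])
      }
    }
  }
  if (check_metric && n >= 2L) {
    d_rev <- metric(profs[[ids[2]]], profs[[ids[1]]])
    if (abs(d_rev - m[1, 2]) > 1e-9) {
      stop("non-metric distance: asymmetry detected between ",
           ids[1], " and ", ids[2], call. = FALSE)
    }
  }
  structure(
    list(ids = ids, pairwise = m, profiles = profs[ids],
         n_build_evaluations = cm$env$n),
    class = "ms_aesa"
  )
}

#' @export
print.ms_aesa <- function(x, ...) {
  cat("<ms_aesa> ", length(x$ids), " samples, ",
      x$n_build_evaluations, " precalculated distances\n", sep = "")
  invisible(x)
}

#' AESA range search
#'
#' Iteratively evaluates the candidate with the smallest
#' triangle-inequality lower bound `lb(s) = max_p |d(q, p) - d(p, s)|`
#' over already-evaluated pivots, reports it when its true distance is
#' within `radius`, and eliminates (unevaluated) every candidate whose
#' lower bound exceeds the radius. Exact: hits equal the linear oracle's,
#' with at most `|db|` true evaluations and typically far fewer.
#'
#' @param index An `ms_aesa`.
#' @param q Query profile.
#' @param radius Non-negative radius.
#' @param metric Metric function.
#' @return An `ms_search_record`.
#' @export
aesa_range_search <- function(index, q, radius, metric) {
  stopifnot(inherits(index, "ms_aesa"), radius >= 0)
  ids <- index$ids
  lb <- stats::setNames(numeric(length(ids)), ids)
  alive <- stats::setNames(rep(TRUE, length(ids)), ids)
  evaluated <- stats::setNames(numeric(0), character(0))
  while (any(alive)) {
    pool <- names(alive)[alive]
    cand <- pool[which.min(lb[pool])]   # which.min ties: smallest id (sorted)
    d <- metric(q, index$profiles[[cand]])
    evaluated[cand] <- d
    alive[cand] <- FALSE
    rest <- names(alive)[alive]
    if (length(rest)) {
      lb[rest] <- pmax(lb[rest], abs(d - index$pairwise[cand, rest]))
      kill <- rest[lb[rest] > radius]
      alive[kill] <- FALSE
    }
  }
  new_search_record(q$sample_id, evaluated, radius)
}
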