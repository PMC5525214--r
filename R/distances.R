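# Distance kernels.
#
# The weighted UniFrac value computed here is the raw (unnormalized) Earth
# Mover Distance on relative abundances with tree path length as ground
# distance; no division by total tree depth. Mass-propagation residuals
# below 1e-12 are treated as balanced and not propagated further.

BALANCE_TOL <- 1e-12
NORM_TOL <- 1e-9

# Resolve a profile's OTUs to tree leaf ids; error on unknown labels and
# unnormalized input. Returns list(idx, val).
profile_leaf_mass <- function(tree, p, check_norm = TRUE) {
  idx <- tree$leaf_index[p$otu]
  if (anyNA(idx)) {
    stop("OTUs not in tree: ",
         paste(utils::head(p$otu[is.na(idx)], 10L), collapse = ", "),
         call. = FALSE)
  }
  if (check_norm && abs(sum(p$count) - 1) > NORM_TOL) {
    stop("profile ", p$sample_id, " is not normalized (sum = ",
         format(sum(p$count)), "); call to_relative() first", call. = FALSE)
  }
  list(idx = as.integer(idx), val = p$count)
}

# Sparse level-wise EMD propagation on pre-resolved leaf masses.
# Touches only ancestors of leaves with a non-zero abundance difference;
# each touched node, once all its touched children are processed, adds
# |accumulated unbalanced mass| * branch length and hands the mass to its
# parent iff it exceeds the balance tolerance.
.emd_sparse <- function(tree, ip, vp, iq, vq) {
  mass <- numeric(tree$n_nodes)
  mass[ip] <- vp
  mass[iq] <- mass[iq] - vq
  seed_nodes <- unique(c(ip, iq))
  seed_nodes <- seed_nodes[mass[seed_nodes] != 0]
  mass[setdiff(c(ip, iq), seed_nodes)] <- 0
  touched <- logical(tree$n_nodes)
  touched[seed_nodes] <- TRUE
  if (!length(seed_nodes)) {
    return(list(value = 0, visited_nodes = 0L))
  }
  pending <- vector("list", tree$max_level + 1L)   # [[lev + 1]]
  for (lv in unique(tree$level[seed_nodes])) {
    pending[[lv + 1L]] <- seed_nodes[tree$level[seed_nodes] == lv]
  }
  visited <- length(seed_nodes)
  dist <- 0
  for (lv in seq(tree$max_level, 1L)) {
    ids <- pending[[lv + 1L]]
    if (is.null(ids)) next
    m <- mass[ids]
    live <- abs(m) >= BALANCE_TOL
    if (any(live)) {
      ids_l <- ids[live]
      m_l <- m[live]
      dist <- dist + sum(tree$bl[ids_l] * abs(m_l))
      par <- tree$parent[ids_l]
      acc <- rowsum(m_l, par)
      pid <- as.integer(rownames(acc))
      mass[pid] <- mass[pid] + acc[, 1L]
      # all of a node's children live at one level, so every parent here
      # receives its full mass in this single batch and is newly touched
      touched[pid] <- TRUE
      visited <- visited + length(pid)
      pending[[lv]] <- c(pending[[lv]], pid)  # parents are at level lv - 1
    }
  }
  list(value = dist, visited_nodes = visited)
}

# Dense level-wise propagation: every node of the phylogeny is processed.
.emd_dense <- function(tree, ip, vp, iq, vq) {
  mass <- numeric(tree$n_nodes)
  mass[ip] <- vp
  mass[iq] <- mass[iq] - vq
  dist <- 0
  for (lv in seq(tree$max_level, 1L)) {
    ids <- tree$levels[[lv + 1L]]
    m <- mass[ids]
    dist <- dist + sum(tree$bl[ids] * abs(m))
    acc <- rowsum(m, tree$parent[ids])
    pid <- as.integer(rownames(acc))
    mass[pid] <- mass[pid] + acc[, 1L]
  }
  list(value = dist, visited_nodes = tree$n_nodes)
}

#' Sparse EMD-UniFrac between two relative-abundance profiles
#'
#' Computes weighted UniFrac as an Earth Mover Distance by propagating
#' abundance differences ("earth") bottom-up through the phylogeny,
#' strictly level-wise, touching only ancestors of leaves where the two
#' profiles differ. Equals the dense traversal and the per-branch sum
#' ([wuf_branch_sum()]) to within 1e-9.
#'
#' @param tree An `ms_tree`.
#' @param p,q Relative-abundance `ms_profile`s (values sum to 1) whose
#'   OTUs are leaves of `tree`.
#' @return An `ms_distance` object: `value` (tree-length units) and
#'   `visited_nodes` (number of tree nodes touched).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1):0;")
#' p <- abundance_profile("p", c(A = 1))
#' q <- abundance_profile("q", c(B = 1))
#' emd_unifrac_sparse(tr, p, q)
#' @export
emd_unifrac_sparse <- function(tree, p, q) {
  stopifnot(inherits(tree, "ms_tree"))
  a <- profile_leaf_mass(tree, p)
  b <- profile_leaf_mass(tree, q)
  structure(.emd_sparse(tree, a$idx, a$val, b$idx, b$val),
            class = "ms_distance")
}

#' Dense EMD-UniFrac (full-tree traversal)
#'
#' Reference formulation that propagates mass through every node of the
#' phylogeny; `visited_nodes` equals the total node count.
#'
#' @inheritParams emd_unifrac_sparse
#' @return An `ms_distance` object.
#' @export
emd_unifrac_dense <- function(tree, p, q) {
  stopifnot(inherits(tree, "ms_tree"))
  a <- profile_leaf_mass(tree, p)
  b <- profile_leaf_mass(tree, q)
  structure(.emd_dense(tree, a$idx, a$val, b$idx, b$val),
            class = "ms_distance")
}

#' @export
print.ms_distance <- function(x, ...) {
  cat("<ms_distance> value ", format(x$value), ", visited ",
      x$visited_nodes, " nodes\n", sep = "")
  invisible(x)
}

#' Weighted UniFrac as a per-branch sum (independent oracle)
#'
#' Evaluates, for every non-root branch, branch length times the absolute
#' difference between the fractions of the two communities found below
#' that branch, accumulating each leaf's mass along its ancestor path.
#' This is an independent route to the same quantity as the EMD
#' propagation.
#'
#' @inheritParams emd_unifrac_sparse
#' @return A single non-negative number.
#' @export
wuf_branch_sum <- function(tree, p, q) {
  stopifnot(inherits(tree, "ms_tree"))
  a <- profile_leaf_mass(tree, p)
  b <- profile_leaf_mass(tree, q)
  under <- function(lm) {
    u <- numeric(tree$n_nodes)
    for (i in seq_along(lm$idx)) {
      node <- lm$idx[i]
      while (!is.na(node)) {
        u[node] <- u[node] + lm$val[i]
        node <- tree$parent[node]
      }
    }
    u
  }
  pu <- under(a)
  qu <- under(b)
  nonroot <- which(!is.na(tree$parent))
  sum(tree$bl[nonroot] * abs(pu[nonroot] - qu[nonroot]))
}

#' Bray-Curtis dissimilarity on count profiles
#'
#' `1 - 2 * sum(min(p_i, q_i)) / (depth(p) + depth(q))`, computed on
#' (optionally rarefied) counts. Bounded in `[0, 1]`; 0 iff the count
#' vectors are identical. Not a metric (fails the triangle inequality),
#' which is why the phylogenetic search route uses UniFrac instead.
#'
#' @param p,q `ms_profile` objects with positive depth.
#' @return A number in `[0, 1]`.
#' @export
bray_curtis <- function(p, q) {
  stopifnot(inherits(p, "ms_profile"), inherits(q, "ms_profile"))
  if (p$depth <= 0 || q$depth <= 0) {
    stop("empty profile in Bray-Curtis", call. = FALSE)
  }
  shared <- intersect(p$otu, q$otu)
  overlap <- if (length(shared)) {
    sum(pmin(p$count[match(shared, p$otu)], q$count[match(shared, q$otu)]))
  } else 0
  1 - 2 * overlap / (p$depth + q$depth)
}
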