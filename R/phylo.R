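#' Parse a newick string into an indexed phylogeny
#'
#' Builds the level-indexed tree structure that the sparse EMD-UniFrac
#' traversal operates on. Node ids follow ape's convention (tips first,
#' then the root, then the remaining internal nodes); every node carries
#' its branch length to its parent and its depth level (root = level 0).
#'
#' @param text A newick string with branch lengths (the root branch is
#'   optional and ignored for distance computation).
#' @return An object of class `ms_tree` with components `parent` (integer,
#'   `NA` at the root), `bl` (branch length to parent), `children`,
#'   `level`, `levels` (list of node-id vectors per depth level),
#'   `leaf_index` (named integer, leaf label to node id), `label`,
#'   `n_leaves`, `n_nodes`, and the underlying ape `phylo` object.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1):0;")
#' tr$n_leaves
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  stripped <- gsub("\\s+$", "", text)
  if (!nzchar(stripped) || substring(stripped, nchar(stripped)) != ";") {
    stop("newick parse error: missing terminal semicolon at position ",
         nchar(stripped) + 1L, call. = FALSE)
  }
  depth <- 0L
  chars <- strsplit(stripped, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("newick parse error: unbalanced parentheses at position ", i,
             call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop("newick parse error: unbalanced parentheses (", depth,
         " unclosed at position ", nchar(stripped), ")", call. = FALSE)
  }
  ph <- tryCatch(
    ape::read.tree(text = stripped),
    error = function(e) stop("newick parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(ph)) stop("newick parse error: unreadable tree", call. = FALSE)
  dup <- unique(ph$tip.label[duplicated(ph$tip.label)])
  if (length(dup)) {
    stop("newick parse error: duplicate leaf labels: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  phylo_to_tree(ph)
}

#' Convert an ape phylo object into the level-indexed representation
#'
#' @param ph An ape `phylo` object with edge lengths.
#' @return An `ms_tree` object; see [parse_newick()].
#' @export
phylo_to_tree <- function(ph) {
  stopifnot(inherits(ph, "phylo"))
  if (is.null(ph$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  n_tips <- length(ph$tip.label)
  n_nodes <- n_tips + ph$Nnode
  parent <- rep(NA_integer_, n_nodes)
  bl <- rep(NA_real_, n_nodes)
  parent[ph$edge[, 2]] <- ph$edge[, 1]
  bl[ph$edge[, 2]] <- ph$edge.length
  root <- setdiff(ph$edge[, 1], ph$edge[, 2])
  if (length(root) != 1L) stop("tree must have exactly one root", call. = FALSE)
  if (any(bl[!is.na(bl)] < 0)) stop("negative branch length", call. = FALSE)
  # ape stores a root edge separately (root.edge); it has no parent node and
  # is ignored in all distance computation.
  children <- vector("list", n_nodes)
  for (i in seq_len(nrow(ph$edge))) {
    children[[ph$edge[i, 1]]] <- c(children[[ph$edge[i, 1]]], ph$edge[i, 2])
  }
  level <- rep(NA_integer_, n_nodes)
  level[root] <- 0L
  frontier <- root
  while (length(frontier)) {
    kids <- unlist(children[frontier], use.names = FALSE)
    if (!length(kids)) break
    level[kids] <- level[rep(frontier, lengths(children[frontier]))] + 1L
    frontier <- kids
  }
  levels <- split(seq_len(n_nodes), level)
  names(levels) <- NULL
  label <- character(n_nodes)
  label[seq_len(n_tips)] <- ph$tip.label
  if (!is.null(ph$node.label)) {
    label[(n_tips + 1L):n_nodes] <- ph$node.label
  }
  leaf_index <- seq_len(n_tips)
  names(leaf_index) <- ph$tip.label
  structure(
    list(
      phylo = ph,
      parent = parent,
      bl = bl,
      children = children,
      level = level,
      levels = levels,
      leaf_index = leaf_index,
      label = label,
      root = root,
      n_leaves = n_tips,
      n_nodes = n_nodes,
      max_level = max(level)
    ),
    class = "ms_tree"
  )
}

#' @export
print.ms_tree <- function(x, ...) {
  cat("<ms_tree> ", x$n_leaves, " leaves, ", x$n_nodes, " nodes, ",
      x$max_level + 1L, " levels\n", sep = "")
  invisible(x)
}

#' Serialize an indexed phylogeny back to newick
#'
#' @param tree An `ms_tree` object.
#' @return A newick string.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "ms_tree"))
  ape::write.tree(tree$phylo)
}

#' Leaf-to-root ancestor path
#'
#' @param tree An `ms_tree` object.
#' @param leaf A leaf label present in the tree's leaf index.
#' @return Integer node ids ordered leaf first, root last; consecutive
#'   entries are child then parent.
#' @export
ancestor_path <- function(tree, leaf) {
  stopifnot(inherits(tree, "ms_tree"))
  id <- tree$leaf_index[leaf]
  if (length(id) != 1L || is.na(id)) {
    stop("unknown leaf label: ", leaf, call. = FALSE)
  }
  path <- integer(tree$level[id] + 1L)
  node <- as.integer(id)
  for (i in seq_along(path)) {
    path[i] <- node
    node <- tree$parent[node]
  }
  path
}
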