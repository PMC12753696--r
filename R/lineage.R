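#' Build the fixed intestinal cell lineage
#'
#' Constructs the binary lineage of the 20 adult intestine cells, all of
#' which descend from the single E blastomere of the 8-cell embryo.  E
#' divides four times (E -> E2 -> E4 -> E8 -> E16) and four of the sixteen
#' E16 cells divide once more, giving 20 cells arranged in nine
#' anteroposterior rings (ring I holds 4 cells, rings II-IX hold 2 each).
#'
#' Node identifiers are the E-rooted division paths: `"E"`, `"Ea"`, `"Ep"`,
#' `"Eaa"`, ... with `a` (anterior) ordered before `p` (posterior).  The
#' division stage of a node is the number of divisions separating it from E
#' (E = 0, E2 daughters = 1, ..., the 20-cell generation = 5).
#'
#' @param rings integer vector of ring sizes, anterior to posterior; must
#'   sum to 20.  Default `c(4, 2, 2, 2, 2, 2, 2, 2, 2)` (rings I-IX).
#' @param dividing character vector of exactly 4 E16 node ids that undergo
#'   the final division, or `NULL` for the default (the 4 anterior-most E16
#'   cells).  Which four cells divide last is not fixed by the lineage
#'   literature at this resolution, so it is exposed as configuration.
#' @return An object of class `lineage_tree`: a list with elements `nodes`,
#'   `parent` (named character, `NA` at the root), `children` (named list),
#'   `root`, `stage` (named integer), `leaves` (anterior-to-posterior), and
#'   `ring_map` (data frame with columns `leaf`, `ring`, `slot`).
#' @examples
#' tr <- build_intestine_lineage()
#' length(tr$leaves)  # 20
#' @export
build_intestine_lineage <- function(rings = c(4L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L),
                                    dividing = NULL) {
  rings <- as.integer(rings)
  if (any(is.na(rings)) || any(rings < 1L)) {
    stop("`rings` must be positive integers")
  }
  if (sum(rings) != 20L) {
    stop("ring sizes must sum to 20 (got ", sum(rings), ")")
  }

  nodes <- "E"
  parent <- c(E = NA_character_)
  gen <- "E"
  for (d in 1:4) {
    kids <- unlist(lapply(gen, function(g) paste0(g, c("a", "p"))))
    parent[kids] <- rep(gen, each = 2L)
    nodes <- c(nodes, kids)
    gen <- kids
  }
  e16 <- gen
  if (is.null(dividing)) {
    dividing <- e16[1:4]
  }
  dividing <- as.character(dividing)
  if (length(dividing) != 4L || anyDuplicated(dividing) ||
      !all(dividing %in% e16)) {
    stop("`dividing` must name 4 distinct E16 nodes")
  }
  extra <- unlist(lapply(dividing, function(g) paste0(g, c("a", "p"))))
  parent[extra] <- rep(dividing, each = 2L)
  nodes <- c(nodes, extra)

  children <- split(names(parent)[-1L], parent[-1L])
  children <- lapply(children, sort)   # a before p
  leaves <- nodes[!(nodes %in% names(children))]
  leaves <- leaves[order(leaves)]      # lexicographic = anterior to posterior
  stage <- stats::setNames(nchar(nodes) - 1L, nodes)

  ring_map <- data.frame(
    leaf = leaves,
    ring = rep(seq_along(rings), rings),
    slot = unlist(lapply(rings, seq_len)),
    stringsAsFactors = FALSE
  )

  structure(
    list(nodes = nodes, parent = parent, children = children, root = "E",
         stage = stage, leaves = leaves, ring_map = ring_map),
    class = "lineage_tree"
  )
}

#' Construct a lineage-like tree from an edge list
#'
#' Utility for building arbitrary rooted binary trees in the same
#' representation as [build_intestine_lineage()], mainly for parsimony
#' analyses and testing on small trees.
#'
#' @param parent named character vector mapping each non-root node to its
#'   parent; the single node that never appears as a name is the root... the
#'   root is the unique value not among the names.
#' @return A `lineage_tree` list (without a `ring_map`).
#' @export
make_tree <- function(parent) {
  kids <- names(parent)
  root <- setdiff(unique(parent), kids)
  if (length(root) != 1L) stop("edge list must define exactly one root")
  nodes <- c(root, kids)
  children <- lapply(split(kids, parent[kids]), sort)
  leaves <- sort(nodes[!(nodes %in% names(children))])
  stage <- stats::setNames(integer(length(nodes)), nodes)
  ord <- tree_preorder_from(root, children)
  for (n in ord[-1L]) stage[n] <- stage[parent[[n]]] + 1L
  p <- c(stats::setNames(NA_character_, root), parent)
  structure(
    list(nodes = nodes, parent = p[nodes], children = children, root = root,
         stage = stage, leaves = leaves, ring_map = NULL),
    class = "lineage_tree"
  )
}

tree_preorder_from <- function(root, children) {
  out <- character(0)
  stack <- root
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, n)
    ch <- children[[n]]
    if (!is.null(ch)) stack <- c(stack, rev(ch))
  }
  out
}

#' Node traversal orders
#'
#' @param tree a `lineage_tree`.
#' @return Character vector of node ids, root-first (`tree_preorder`) or
#'   leaves-first (`tree_postorder`).
#' @keywords internal
tree_preorder <- function(tree) {
  tree_preorder_from(tree$root, tree$children)
}

tree_postorder <- function(tree) {
  rev(tree_preorder(tree))
}

#' Leaves spanned by a subtree
#'
#' @param tree a `lineage_tree`.
#' @param node a node id.
#' @return Character vector of the leaves descending from (and including)
#'   `node`.
#' @export
subtree_leaves <- function(tree, node) {
  desc <- tree_preorder_from(node, tree$children)
  intersect(tree$leaves, desc)
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("<lineage_tree> root", x$root, "-", length(x$nodes), "nodes,",
      length(x$leaves), "leaves\n")
  if (!is.null(x$ring_map)) {
    cat("rings:", paste(tabulate(x$ring_map$ring), collapse = " "), "\n")
  }
  invisible(x)
}
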