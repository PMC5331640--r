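# Rooted branch-length trees for UniFrac. Parsing, serialization and tip
# pruning are delegated to ape; this layer adds strict validation and the
# postorder branch decomposition UniFrac consumes. Trees are used rooted
# exactly as written: no midpoint re-rooting (UniFrac values depend on the
# root, so the choice must be explicit and fixed).

# Degenerate single-leaf tree: representable, but rejected by UniFrac and
# yields an empty postorder branch list.
single_leaf_tree <- function(label, length = 0) {
  structure(list(edge = matrix(integer(0), 0L, 2L),
                 edge.length = numeric(0),
                 tip.label = label, Nnode = 0L,
                 root.edge = length),
            class = c("single_leaf", "phylo"))
}

#' Parse a Newick string into a validated rooted tree
#'
#' Standard Newick dialect: quoted labels supported, `[...]` comments
#' ignored, polytomies allowed. Unspecified branch lengths default to 0;
#' negative branch lengths and duplicate leaf labels are rejected. The tree
#' is kept rooted as written.
#'
#' @param text a single Newick statement terminated by `;`.
#' @return An [ape::read.tree()]-style `phylo` object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  stripped <- gsub("\\[[^]]*\\]", "", text)
  if (!grepl(";", stripped))
    mv_parse_error("Newick statement must be terminated by ';'")
  # balanced-parenthesis check with position, for a useful message
  chars <- strsplit(stripped, "")[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        mv_parse_error(sprintf("unbalanced ')' at position %d", i))
    }
  }
  if (depth != 0L)
    mv_parse_error(sprintf("unbalanced parentheses: %d '(' left open", depth))
  bare <- trimws(sub(";.*$", "", stripped))
  if (!grepl("(", bare, fixed = TRUE)) {
    # lone leaf, e.g. "A:2;" — the root is itself the leaf
    lab <- sub(":.*$", "", bare)
    len <- if (grepl(":", bare, fixed = TRUE))
      as.numeric(sub("^.*:", "", bare)) else 0
    if (!nzchar(lab) || is.na(len))
      mv_parse_error(sprintf("cannot parse Newick leaf statement '%s'", bare))
    if (len < 0) mv_validation_error("negative branch length")
    return(single_leaf_tree(lab, len))
  }
  tree <- tryCatch(ape::read.tree(text = stripped),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree))
    mv_parse_error("malformed Newick statement")
  # ape keeps surrounding quotes on quoted labels; strip them
  tree$tip.label <- gsub("^'(.*)'$|^\"(.*)\"$", "\\1\\2", tree$tip.label)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) mv_validation_error("not a phylo object")
  if (inherits(tree, "single_leaf")) return(tree)
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0, nrow(tree$edge))
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (any(tree$edge.length < 0))
    mv_validation_error("negative branch length")
  if (anyDuplicated(tree$tip.label))
    mv_validation_error(sprintf("duplicate leaf label '%s'",
                                tree$tip.label[duplicated(tree$tip.label)][1L]))
  tree
}

#' Read / write Newick files
#' @param path file path.
#' @return `read_newick`: a `phylo`; `write_newick`: the path, invisibly.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) mv_format_error(sprintf("file not found: '%s'", path))
  parse_newick(paste(readLines(path), collapse = ""))
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree, path) {
  writeLines(serialize_newick(tree), path)
  invisible(path)
}

#' @rdname read_newick
#' @export
serialize_newick <- function(tree) {
  if (inherits(tree, "single_leaf"))
    return(sprintf("%s:%.10g;", tree$tip.label, tree$root.edge))
  ape::write.tree(tree, digits = 12)
}

total_branch_length <- function(tree) {
  if (inherits(tree, "single_leaf")) return(tree$root.edge)
  sum(tree$edge.length)
}

#' Postorder branch decomposition
#'
#' Every non-root branch once, children before parents, each paired with the
#' set of leaf labels descending through it. A lone root-leaf tree yields an
#' empty list.
#'
#' @param tree a validated `phylo`.
#' @return List of `list(length =, leaves =)` entries in postorder.
#' @export
postorder_branches <- function(tree) {
  tree <- validate_tree(tree)
  if (inherits(tree, "single_leaf")) return(list())
  bi <- branch_incidence(tree)
  lapply(seq_along(bi$lengths), function(k)
    list(length = bi$lengths[k],
         leaves = colnames(bi$incidence)[bi$incidence[k, ] > 0]))
}

# Internal workhorse for UniFrac: branch lengths plus a (branches x leaves)
# 0/1 incidence matrix in postorder, columns named by leaf label.
branch_incidence <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  nodeset <- matrix(0, nnode, ntip)
  nodeset[cbind(seq_len(ntip), seq_len(ntip))] <- 1
  ne <- nrow(tr$edge)
  inc <- matrix(0, ne, ntip, dimnames = list(NULL, tr$tip.label))
  for (k in seq_len(ne)) {
    child <- tr$edge[k, 2L]
    inc[k, ] <- nodeset[child, ]
    nodeset[tr$edge[k, 1L], ] <- nodeset[tr$edge[k, 1L], ] + nodeset[child, ]
  }
  inc <- (inc > 0) + 0
  list(lengths = if (is.null(tr$edge.length)) rep(0, ne) else tr$edge.length,
       incidence = inc)
}

#' Prune a tree to a subset of leaves
#'
#' Retains exactly the requested leaves; unary internal nodes left behind
#' are collapsed with their branch lengths summed, so all pairwise path
#' lengths among retained leaves are unchanged. At least two taxa must be
#' retained (a one-leaf pruned tree has no UniFrac use and is not
#' representable).
#'
#' @param tree a `phylo`.
#' @param taxa character vector of leaf labels to keep (subset of the
#'   tree's leaves).
#' @return The pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, taxa) {
  tree <- validate_tree(tree)
  labs <- tree$tip.label
  unknown <- setdiff(taxa, labs)
  if (length(unknown))
    mv_validation_error(sprintf("taxon '%s' is not a leaf of the tree",
                                unknown[1L]))
  if (length(taxa) < 2L)
    mv_validation_error("pruning to fewer than 2 taxa is not supported")
  if (setequal(taxa, labs)) return(tree)
  validate_tree(ape::keep.tip(tree, taxa))
}

# All pairwise leaf-to-leaf path lengths (used by tests and the synthetic
# tree construction checks).
leaf_path_lengths <- function(tree) {
  ape::cophenetic.phylo(tree)
}
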