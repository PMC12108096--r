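#' Read a rooted, time-calibrated binary tree from Newick
#'
#' Parses a Newick string (or file) into a `timetree`: a rooted, strictly
#' binary tree whose branch lengths are interpreted as absolute time (millions
#' of years). Branches receive deterministic indices in postorder, so reading
#' the same Newick twice always yields the same branch numbering. The root age
#' is taken as the maximum tip depth; trees whose tip depths differ by more
#' than a relative tolerance of 1e-6 are flagged non-ultrametric with a
#' warning (real chronograms carry rounding error, so this does not abort).
#'
#' @param text Newick string (mutually exclusive with `file`).
#' @param file Path to a Newick file.
#' @return A `timetree` object: list with elements `phylo` (postorder-ordered
#'   [ape::phylo]), `n_tips`, `root_age`, `ultrametric` (logical) and
#'   `branches` (tibble with `branch`, `parent`, `child`, `length`, `label`,
#'   `terminal`).
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' branches(tr)
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file)) {
    abort("supply exactly one of `text` or `file`")
  }
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  phy <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e)))
  )
  if (is.null(phy)) abort(paste0("Newick parse error: unreadable text near ",
                                 substr(trimws(text), 1, 30)))
  if (is.null(phy$edge.length) || anyNA(phy$edge.length)) {
    abort("Newick parse error: missing branch length")
  }
  if (any(phy$edge.length < 0)) abort("negative branch length")
  if (!ape::is.rooted(phy) || !ape::is.binary(phy)) {
    deg <- tabulate(phy$edge[, 1])
    bad <- which(deg > 2)[1]
    abort(paste0("tree must be rooted and strictly binary",
                 if (!is.na(bad)) paste0(": node ", bad, " has ", deg[bad],
                                         " children")))
  }
  phy <- ape::reorder.phylo(phy, "postorder")
  n_tip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  root_age <- max(depth[seq_len(n_tip)])
  ultra <- TRUE
  if (root_age > 0) {
    rel <- (root_age - depth[seq_len(n_tip)]) / root_age
    if (any(rel > 1e-6)) {
      ultra <- FALSE
      warn("tree is not ultrametric: tip depths differ by more than 1e-6 relative")
    }
  }
  br <- tibble(
    branch = seq_len(nrow(phy$edge)),
    parent = phy$edge[, 1],
    child = phy$edge[, 2],
    length = phy$edge.length,
    label = ifelse(phy$edge[, 2] <= n_tip, phy$tip.label[phy$edge[, 2]], NA_character_),
    terminal = phy$edge[, 2] <= n_tip
  )
  structure(
    list(phylo = phy, n_tips = n_tip, root_age = root_age,
         ultrametric = ultra, branches = br),
    class = "timetree"
  )
}

#' Branch table of a time tree
#'
#' @param tree A `timetree`.
#' @return Tibble with one row per branch in deterministic postorder:
#'   `branch` index, `parent`/`child` node ids, `length` (MY), tip `label`
#'   (NA for internal branches) and `terminal` flag.
#' @export
branches <- function(tree) {
  stopifnot(inherits(tree, "timetree"))
  tree$branches
}

#' @export
print.timetree <- function(x, ...) {
  cat("<timetree> ", x$n_tips, " tips, ", nrow(x$branches),
      " branches, root age ", format(x$root_age), " MY",
      if (!x$ultrametric) " (non-ultrametric)", "\n", sep = "")
  invisible(x)
}

#' Bundled 11-taxon example chronogram
#'
#' A synthetic ultrametric 11-taxon tree with root age 25 MY, shipped at
#' `inst/extdata/tree_11taxa.nwk`. Its two shortest terminal branches (1 MY)
#' make it suitable for studying tip-branch sensitivity to rate artifacts.
#'
#' @return A `timetree`.
#' @export
example_tree <- function() {
  read_newick(file = system.file("extdata", "tree_11taxa.nwk",
                                 package = "phyturnover", mustWork = TRUE))
}

# edge arrays for the C++ core (1-based node ids, postorder)
tree_arrays <- function(tree) {
  phy <- tree$phylo
  list(child = phy$edge[, 2], parent = phy$edge[, 1],
       elen = phy$edge.length, n_tip = tree$n_tips)
}
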