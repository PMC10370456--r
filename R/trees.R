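#' Read a tree from Newick text or file
#'
#' Trees are handled unrooted throughout: rooted inputs (degree-2 root) are
#' unrooted on parse, merging the two root edges.  Missing branch lengths
#' default to 0.  Quoted labels and `[]` comments follow the usual Newick
#' conventions of [ape::read.tree].
#'
#' @param text Newick string (one tree).
#' @param file path to a Newick file; if it holds several trees (one per
#'   line) a list is returned.
#' @return an unrooted `phylo` object (or list of them for multi-tree files).
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file)) stop("give exactly one of text/file")
  if (!is.null(text)) {
    check_newick_syntax(text)
    tr <- ape::read.tree(text = text)
    if (is.null(tr)) stop("malformed Newick string")
    return(as_unrooted(tr))
  }
  tr <- ape::read.tree(file = file)
  if (is.null(tr)) stop("no trees read from ", file)
  if (inherits(tr, "multiPhylo")) lapply(tr, as_unrooted) else as_unrooted(tr)
}

# cheap structural validation so parse errors carry a character offset
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L; quoted <- FALSE; bracket <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (quoted) { if (ch == "'") quoted <- FALSE; next }
    if (bracket) { if (ch == "]") bracket <- FALSE; next }
    if (ch == "'") quoted <- TRUE
    else if (ch == "[") bracket <- TRUE
    else if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unbalanced ')' at character ", i)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at character ",
         length(chars))
  invisible(TRUE)
}

#' Write trees as Newick
#'
#' @param tree a `phylo` or list of them.
#' @param file optional path; one tree per line.  When `NULL` the Newick
#'   string(s) are returned.
#' @param digits significant digits for branch lengths.
#' @return Newick string(s) (invisibly when writing to file).
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  trees <- if (inherits(tree, "phylo")) list(tree) else tree
  txt <- vapply(trees, function(t) ape::write.tree(t, digits = digits), "")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  if (inherits(tree, "phylo")) txt[1] else txt
}

# unroot, default missing branch lengths to 0, validate labels
as_unrooted <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree$tip.label <- gsub("^'(.*)'$", "\\1", tree$tip.label)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate taxon labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (ape::Ntip(tree) > 2 && ape::is.rooted(tree)) tree <- ape::unroot(tree)
  if (any(tree$edge.length < 0)) stop("negative branch length")
  ape::reorder.phylo(tree, "cladewise")
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge induces a two-block partition of the taxa.  The
#' canonical form of a split is the sorted label set of the block containing
#' the lexicographically smallest taxon, so it is invariant to tree
#' orientation and leaf order.  Trivial splits (singleton blocks) are
#' excluded.
#'
#' @param tree a `phylo`.
#' @return character vector of canonical splits (comma-joined label sets);
#'   length m-3 for a fully resolved unrooted tree, empty for a star tree.
#' @export
tree_bipartitions <- function(tree) {
  tree <- as_unrooted(tree)
  m <- ape::Ntip(tree)
  labs <- tree$tip.label
  ref <- sort(labs)[1]
  post <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", m + tree$Nnode)
  for (i in seq_len(m)) desc[[i]] <- labs[i]
  for (k in seq_len(nrow(post$edge))) {
    p <- post$edge[k, 1]; ch <- post$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  internal <- which(post$edge[, 2] > m)
  out <- character(0)
  for (k in internal) {
    blk <- desc[[post$edge[k, 2]]]
    if (length(blk) <= 1 || length(blk) >= m - 1) next
    if (!(ref %in% blk)) blk <- setdiff(labs, blk)
    out <- c(out, paste(sort(blk), collapse = ","))
  }
  unique(out)
}

#' Canonical topology hash
#'
#' Deterministic identifier of an unrooted topology: the sorted canonical
#' split set, joined.  Equal iff the topologies are identical (same taxa
#' assumed); branch lengths are ignored.
#'
#' @param tree a `phylo`.
#' @return character scalar.
#' @export
topology_hash <- function(tree) {
  paste(sort(tree_bipartitions(tree)), collapse = "|")
}

check_same_taxa <- function(t1, t2) {
  a <- sort(t1$tip.label); b <- sort(t2$tip.label)
  if (!identical(a, b)) {
    miss1 <- setdiff(b, a); miss2 <- setdiff(a, b)
    stop("taxon sets differ",
         if (length(miss2)) paste0("; missing from tree 2: ",
                                   paste(miss2, collapse = ", ")) else "",
         if (length(miss1)) paste0("; missing from tree 1: ",
                                   paste(miss1, collapse = ", ")) else "")
  }
  invisible(TRUE)
}

#' Robinson-Foulds distance
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' trees.  Symmetric; 0 iff the unrooted topologies are identical.
#' Multifurcating trees are accepted (their smaller split sets are compared
#' as-is).
#'
#' @param t1,t2 `phylo` objects over the same taxa.
#' @return non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  check_same_taxa(t1, t2)
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Robinson-Foulds distance as a percentage
#'
#' `d_RF / (2 (m - 3)) * 100` where `m` is the number of tips: the RF
#' distance relative to its maximum for two fully resolved unrooted trees.
#'
#' @param t1,t2 fully resolved `phylo` objects over the same taxa, m >= 4.
#' @return percentage in `[0, 100]`; 0 iff identical topologies.
#' @export
rf_percent <- function(t1, t2) {
  m <- ape::Ntip(t1)
  if (m < 4) stop("rf_percent needs at least 4 taxa")
  for (t in list(t1, t2)) {
    tu <- as_unrooted(t)
    if (nrow(tu$edge) != 2 * ape::Ntip(tu) - 3)
      stop("rf_percent requires fully resolved trees")
  }
  rf_distance(t1, t2) / (2 * (m - 3)) * 100
}

#' Topological identity
#'
#' `TRUE` iff the two trees have the same unrooted topology (branch lengths
#' ignored).
#'
#' @param t1,t2 `phylo` objects over the same taxa.
#' @return logical.
#' @export
same_topology <- function(t1, t2) {
  rf_distance(t1, t2) == 0
}

#' Enumerate all unrooted binary topologies
#'
#' Every distinct unrooted binary topology on the given taxa, exactly once;
#' there are (2m-5)!! of them.  Guarded at m <= 8 (10,395 topologies)
#' because the count grows super-exponentially.
#'
#' @param taxa character vector of 3 to 8 unique labels.
#' @return list of `phylo` objects (no branch lengths assigned).
#' @export
enumerate_topologies <- function(taxa) {
  m <- length(taxa)
  if (anyDuplicated(taxa)) stop("duplicate taxon labels")
  if (m < 3) stop("need at least 3 taxa")
  if (m > 8)
    stop("topology enumeration is limited to m <= 8 (requested m = ", m,
         "; there would be (2m-5)!! topologies)")
  tl <- phangorn::allTrees(m, rooted = FALSE, tip.label = taxa)
  lapply(tl, function(t) {
    t$edge.length <- rep(0, nrow(t$edge))
    ape::reorder.phylo(t, "cladewise")
  })
}
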