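# Distance-based phylogenetics: protein distance matrices, neighbor
# joining with deterministic tie-breaks, column-bootstrap support, and
# the clade-membership test used as orthology evidence. Trees are ape
# "phylo" objects throughout, so newick I/O and rooting come from ape.

#' Protein distance matrix from an alignment
#'
#' Pairwise-deletion p-distance (`mismatches / compared columns`) or its
#' Kimura protein correction `d = -ln(1 - p - 0.2 p^2)`; p-distances at
#' or above 0.85 are capped there before correction (with a warning), as
#' the correction diverges.
#'
#' @param msa an [alignment()].
#' @param correction `"p"` or `"kimura_protein"`.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(msa, correction = c("p", "kimura_protein")) {
  correction <- match.arg(correction)
  k <- length(msa$rows)
  if (k < 3L) stop("need at least 3 rows")
  mat <- do.call(rbind, strsplit(msa$rows, ""))
  D <- matrix(0, k, k, dimnames = list(msa$ids, msa$ids))
  capped <- FALSE
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!any(ok)) stop("zero ungapped overlap between '", msa$ids[i],
                       "' and '", msa$ids[j], "'")
    p <- sum(mat[i, ok] != mat[j, ok]) / sum(ok)
    if (correction == "kimura_protein") {
      if (p >= 0.85) { p <- 0.85; capped <- TRUE }
      d <- -log(1 - p - 0.2 * p^2)
    } else d <- p
    D[i, j] <- D[j, i] <- d
  }
  if (capped) warning("p-distance >= 0.85 capped before Kimura correction")
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with a deterministic tie-break (the
#' lowest-index pair is joined when Q-scores tie). Negative branch
#' lengths are clamped to zero with the deficit transferred to the
#' sibling branch, preserving path lengths through the joined node.
#'
#' @param D symmetric distance matrix with at least 3 taxa.
#' @return an unrooted [ape] `phylo` tree.
#' @export
nj_tree <- function(D) {
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix not symmetric")
  n <- nrow(D)
  stopifnot(n >= 3L)
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # active nodes carry ape node numbers: tips 1..n, internals n+1, n+2, ...
  node_of <- seq_len(n)
  next_node <- n + 2L   # n+1 reserved for the final (root-like) node
  edges <- matrix(0L, 0L, 2L); lens <- numeric()
  act <- seq_len(n)
  Dm <- D
  while (length(act) > 2L) {
    r <- length(act)
    sums <- rowSums(Dm[act, act])
    # Q matrix, lowest-index tie-break
    best <- NULL; bestq <- Inf
    for (ii in seq_len(r - 1L)) for (jj in (ii + 1L):r) {
      a <- act[ii]; b <- act[jj]
      q <- (r - 2) * Dm[a, b] - sums[ii] - sums[jj]
      if (q < bestq - 1e-12) { bestq <- q; best <- c(ii, jj) }
    }
    a <- act[best[1]]; b <- act[best[2]]
    la <- Dm[a, b] / 2 + (sums[best[1]] - sums[best[2]]) / (2 * (r - 2))
    lb <- Dm[a, b] - la
    # clamp negatives, transfer deficit to the sibling branch
    if (la < 0) { lb <- lb + la; la <- 0 }
    if (lb < 0) { la <- la + lb; lb <- 0 }
    lb <- max(lb, 0)
    new_id <- if (r == 3L) NA else next_node
    u <- next_node; next_node <- next_node + 1L
    edges <- rbind(edges, c(u, node_of[a]), c(u, node_of[b]))
    lens <- c(lens, la, lb)
    # distances to the new node
    rest <- setdiff(act, c(a, b))
    newd <- (Dm[a, rest] + Dm[b, rest] - Dm[a, b]) / 2
    Dm <- rbind(cbind(Dm, 0), 0)
    m <- nrow(Dm)
    Dm[m, rest] <- Dm[rest, m] <- newd
    node_of <- c(node_of, u)
    act <- c(rest, m)
  }
  # join the last two active nodes through the final internal node n+1
  a <- act[1]; b <- act[2]
  root <- n + 1L
  edges <- rbind(edges, c(root, node_of[a]), c(root, node_of[b]))
  lens <- c(lens, Dm[a, b] / 2, Dm[a, b] / 2)
  # renumber internal nodes to ape convention (root-ish first)
  internal <- sort(unique(edges[edges > n]))
  remap <- integer(max(internal))
  remap[root] <- n + 1L
  others <- setdiff(internal, root)
  if (length(others)) remap[others] <- n + 1L + seq_along(others)
  e <- edges
  e[e > n] <- remap[e[e > n]]
  tr <- list(edge = e, edge.length = lens, tip.label = labels,
             Nnode = length(internal))
  class(tr) <- "phylo"
  # normalize edge ordering/structure through a newick round-trip
  ape::read.tree(text = ape::write.tree(tr))
}

#' Bootstrap support for an alignment's NJ tree
#'
#' Columns are resampled with replacement `n_reps` times; support for
#' each internal bipartition of the original tree is the fraction of
#' replicate trees containing it. Supports are stored as node labels.
#'
#' @param msa an [alignment()].
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed (reproducible resampling).
#' @param correction distance correction, see [distance_matrix()].
#' @param return_trees also return the replicate trees (for support
#'   queries on arbitrary splits, see [split_support()]).
#' @return list with `tree` (`phylo`, node labels = support fractions),
#'   `support` (numeric vector per internal node; `NA` for the root node
#'   of the unrooted representation) and, optionally, `trees`.
#' @export
bootstrap_support <- function(msa, n_reps = 100L, seed = 1L,
                              correction = c("p", "kimura_protein"),
                              return_trees = FALSE) {
  correction <- match.arg(correction)
  stopifnot(n_reps >= 1L)
  tree <- nj_tree(distance_matrix(msa, correction))
  ncol_aln <- nchar(msa$rows[1])
  boots <- .with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
      rows <- vapply(strsplit(msa$rows, ""), function(x)
        paste(x[cols], collapse = ""), "")
      bm <- alignment(msa$ids, rows)
      tryCatch(nj_tree(distance_matrix(bm, correction)),
               error = function(e) NULL)
    })
  })
  boots <- Filter(Negate(is.null), boots)
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  support <- counts / n_reps
  tree$node.label <- ifelse(is.na(support), "", format(support, digits = 3))
  out <- list(tree = tree, support = support)
  if (return_trees) out$trees <- boots
  out
}

#' Bootstrap support of an arbitrary leaf bipartition
#'
#' Fraction of replicate trees in which `leaves` (or its complement)
#' forms a split.
#'
#' @param trees list of `phylo` trees over the same tip set.
#' @param leaves character vector of tip labels on one side of the split.
#' @return support fraction in `[0, 1]`.
#' @export
split_support <- function(trees, leaves) {
  if (!length(trees)) return(NA_real_)
  hits <- vapply(trees, function(tr) {
    tips <- tr$tip.label
    S <- sort(match(leaves, tips))
    if (anyNA(S)) return(FALSE)
    comp <- sort(setdiff(seq_along(tips), S))
    if (!length(comp) || !length(S)) return(TRUE)  # trivial split
    parts <- ape::prop.part(tr)
    any(vapply(parts, function(p)
      identical(sort(p), S) || identical(sort(p), comp), TRUE))
  }, TRUE)
  mean(hits)
}

#' Clade-membership test
#'
#' After rooting the tree on the outgroup, the smallest clade containing
#' the query leaf and all reference leaves is found; the test passes when
#' that clade excludes every contrast leaf (by default, all leaves that
#' are neither query, reference nor outgroup). This is the "positioned in
#' a clade together with" criterion used as phylogenetic orthology
#' evidence.
#'
#' @param tree a `phylo` tree.
#' @param query_leaf the query tip label.
#' @param reference_leaves tip labels the query must group with.
#' @param outgroup_leaves tip labels used to root the tree (non-empty).
#' @param contrast_leaves tip labels that must be excluded; defaults to
#'   all remaining leaves.
#' @return list with `in_clade` (logical) and `clade_leaves` (labels of
#'   the smallest containing clade).
#' @export
is_in_clade_with <- function(tree, query_leaf, reference_leaves,
                             outgroup_leaves, contrast_leaves = NULL) {
  tips <- tree$tip.label
  stopifnot(query_leaf %in% tips, all(reference_leaves %in% tips),
            length(outgroup_leaves) >= 1L, all(outgroup_leaves %in% tips))
  if (query_leaf %in% outgroup_leaves) stop("query is in the outgroup")
  if (is.null(contrast_leaves))
    contrast_leaves <- setdiff(tips, c(query_leaf, reference_leaves,
                                       outgroup_leaves))
  rooted <- tryCatch(
    ape::root(tree, outgroup = outgroup_leaves, resolve.root = TRUE),
    error = function(e)
      # non-monophyletic outgroup: root on its first leaf instead
      ape::root(tree, outgroup = outgroup_leaves[1L], resolve.root = TRUE))
  focal <- unique(c(query_leaf, reference_leaves))
  node <- if (length(focal) == 1L) match(focal, rooted$tip.label)
          else ape::getMRCA(rooted, focal)
  clade <- if (node <= length(rooted$tip.label)) rooted$tip.label[node]
           else ape::extract.clade(rooted, node)$tip.label
  list(in_clade = !any(contrast_leaves %in% clade), clade_leaves = clade)
}

#' Read / write trees in newick format
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()], so that
#' externally computed trees (e.g. maximum-likelihood topologies) can be
#' fed to [is_in_clade_with()].
#'
#' @param path file path.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree a `phylo` tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
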