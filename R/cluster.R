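#' Euclidean distance matrix between sample fingerprints
#'
#' @param table a \linkS4class{BucketTable} or a plain samples-by-features
#'   numeric matrix.
#' @return a \code{\link[stats]{dist}} object with sample labels.
#' @export
euclideanDistances <- function(table) {
  x <- if (is(table, "BucketTable")) bucketValues(table) else as.matrix(table)
  if (nrow(x) == 0) stop("table is empty")
  bad <- rownames(x)[apply(x, 1, function(r) any(!is.finite(r)))]
  if (length(bad) > 0)
    stop("missing or non-finite values in row(s): ",
         paste(bad, collapse = ", "))
  dist(x, method = "euclidean")
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering under Ward's minimum-variance criterion in its
#' modern form (Ward.D2): the Lance-Williams recurrence is run on squared
#' Euclidean distances and merge heights are reported back on the distance
#' scale (square root). Heights are therefore monotone non-decreasing.
#' Ties are broken by the lowest (i, j) index pair, so results are
#' bit-reproducible.
#'
#' @param d a \code{\link[stats]{dist}} object or a symmetric non-negative
#'   matrix with zero diagonal.
#' @return an object of class \code{\link[stats]{hclust}} (method
#'   \code{"ward.D2"}), usable with \code{\link{cutDendrogram}},
#'   \code{\link{dendrogramNewick}}, and standard plotting.
#' @export
wardLinkage <- function(d) {
  if (is.matrix(d)) {
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12))
      stop("distance matrix must be symmetric")
    labels <- rownames(d)
    D <- d
  } else {
    D <- as.matrix(d)
    labels <- attr(d, "Labels")
  }
  n <- nrow(D)
  if (n < 2) stop("need at least two samples")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  D2 <- D^2
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  code <- -seq_len(n)            # hclust convention: negative = leaf
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    best <- Inf; bi <- 0L; bj <- 0L
    act <- which(active)
    for (ii in seq_len(length(act) - 1)) {
      i <- act[ii]
      for (j in act[(ii + 1):length(act)]) {
        if (D2[i, j] < best) { best <- D2[i, j]; bi <- i; bj <- j }
      }
    }
    height[s] <- sqrt(best)
    a <- code[bi]; b <- code[bj]
    merge[s, ] <- if (a < 0 && b < 0) sort(c(a, b), decreasing = TRUE)
                  else sort(c(a, b))
    ## Lance-Williams update on squared distances (Ward)
    ni <- sizes[bi]; nj <- sizes[bj]
    for (k in act) {
      if (k == bi || k == bj) next
      nk <- sizes[k]
      v <- ((ni + nk) * D2[k, bi] + (nj + nk) * D2[k, bj] - nk * best) /
        (ni + nj + nk)
      D2[k, bi] <- v; D2[bi, k] <- v
    }
    sizes[bi] <- ni + nj
    active[bj] <- FALSE
    code[bi] <- s
  }
  order <- leafOrder(merge, n)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = "ward.D2",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

## leaf order for plotting: recursive traversal, smaller subtree first
leafOrder <- function(merge, n) {
  sizes <- integer(nrow(merge))
  sz <- function(code) if (code < 0) 1L else sizes[code]
  for (s in seq_len(nrow(merge)))
    sizes[s] <- sz(merge[s, 1]) + sz(merge[s, 2])
  walk <- function(code) {
    if (code < 0) return(-code)
    a <- merge[code, 1]; b <- merge[code, 2]
    if (sz(a) > sz(b)) { tmp <- a; a <- b; b <- tmp }
    c(walk(a), walk(b))
  }
  walk(nrow(merge))
}

#' Cut a dendrogram into k flat clusters
#'
#' Undoes the last k - 1 merges. Cluster ids are deterministic: clusters
#' are numbered by their smallest member leaf index.
#'
#' @param dend an \code{hclust} object (e.g. from
#'   \code{\link{wardLinkage}}).
#' @param k number of clusters, between 1 and the number of leaves.
#' @return named integer vector mapping sample id to cluster id.
#' @export
cutDendrogram <- function(dend, k) {
  n <- length(dend$labels)
  if (k < 1 || k > n) stop("k must be between 1 and ", n)
  cl <- cutree(dend, k = k)
  ## renumber by first appearance in leaf-index order
  relabel <- match(cl, unique(cl))
  names(relabel) <- names(cl)
  relabel
}

#' Species-recovery score of a flat clustering
#'
#' A species is recovered when all of its samples share one cluster and
#' that cluster contains no sample of any other species; purity is the
#' fraction of species recovered. This is the quantitative counterpart of
#' reading a dendrogram for pure single-species clades.
#'
#' @param assignment named vector, sample id -> cluster id.
#' @param truth named vector, sample id -> species label.
#' @return list with \code{recovered} (count of pure species),
#'   \code{purity} (fraction), and \code{per_species} (named logical).
#' @export
speciesRecovery <- function(assignment, truth) {
  if (!setequal(names(assignment), names(truth)))
    stop("assignment and truth must cover the same sample ids")
  truth <- truth[names(assignment)]
  species <- unique(truth)
  ok <- vapply(species, function(sp) {
    cl <- unique(assignment[truth == sp])
    length(cl) == 1 && all(truth[assignment == cl] == sp)
  }, logical(1))
  names(ok) <- species
  list(recovered = sum(ok), purity = sum(ok) / length(species),
       per_species = ok)
}

#' Export a dendrogram as a Newick tree
#'
#' Branch lengths derive from the merge heights (each edge spans the
#' height difference between a node and its parent).
#'
#' @param dend an \code{hclust} object.
#' @param file optional path; when given the tree is written there.
#' @return the Newick string, invisibly when \code{file} is given.
#' @export
dendrogramNewick <- function(dend, file = NULL) {
  phy <- ape::as.phylo(dend)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
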