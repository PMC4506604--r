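# Spatial clustering of mapped variants: Euclidean distances between C-alpha
# atoms, agglomerative average linkage, threshold cut.
#
# The agglomeration is written out explicitly (Lance-Williams update for the
# unweighted average of all cross-pair distances) rather than delegated, so
# the merge order and its tie-breaking are fully specified and reproducible:
# at every step the minimum-distance active pair merges, ties broken by the
# lexicographically smallest pair of smallest member labels.

#' Pairwise C-alpha distance matrix of mapped variants
#'
#' @param mapped table from [map_variants()]; only rows with
#'   `status == "mapped"` are used (the caller excludes unmapped upstream).
#' @return a `calpha_dist`: `labels` (e.g. `"Y370C (A)"`) and `d`, the
#'   symmetric matrix of Euclidean distances in Angstrom at full double
#'   precision. Report rendering rounds to 0.1 Angstrom; the matrix never does.
#' @export
distance_matrix <- function(mapped) {
  m <- mapped[mapped$status == "mapped", , drop = FALSE]
  if (nrow(m) == 0L) stop("no mapped variants to build a distance matrix from")
  if (anyDuplicated(m$label)) {
    stop(sprintf("duplicate labels in mapped set: %s",
                 paste(unique(m$label[duplicated(m$label)]), collapse = ", ")))
  }
  xyz <- as.matrix(m[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz, method = "euclidean"))
  dimnames(d) <- list(m$label, m$label)
  structure(list(labels = m$label, d = d), class = "calpha_dist")
}

#' @export
print.calpha_dist <- function(x, ...) {
  cat(sprintf("C-alpha distance matrix: %d variant(s)\n", length(x$labels)))
  print(round(x$d, 1))
  invisible(x)
}

#' Agglomerative average-linkage clustering
#'
#' Standard bottom-up agglomeration on the given distance matrix. The
#' inter-cluster distance is the unweighted arithmetic mean of all cross-pair
#' distances; with the Lance-Williams size-weighted update this equals a
#' direct recomputation of that mean at every step. Tie-breaking is
#' deterministic as described above, so merge lists are bit-for-bit
#' reproducible.
#'
#' @param dm a `calpha_dist` (or any list with `labels` and symmetric `d`).
#' @return a `snp_tree`: `merges`, an ordered list of
#'   `(members_a, members_b, height)` with heights in Angstrom, plus `labels`
#'   and an [stats::hclust]-compatible `merge`/`height` encoding.
#' @export
average_linkage <- function(dm) {
  labels <- dm$labels
  n <- length(labels)
  stopifnot(n >= 1L, all(dim(dm$d) == c(n, n)))
  merges <- vector("list", max(n - 1L, 0L))
  hc_merge <- matrix(0L, nrow = max(n - 1L, 0L), ncol = 2L)
  hc_height <- numeric(max(n - 1L, 0L))
  d <- dm$d
  active <- seq_len(n)
  members <- as.list(seq_len(n))       # leaf indices per active cluster
  sizes <- rep(1L, n)
  hc_id <- -seq_len(n)                 # hclust encoding: -leaf or +merge step
  min_label <- labels                  # smallest member label per cluster
  for (step in seq_len(max(n - 1L, 0L))) {
    k <- length(active)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        dij <- d[active[i], active[j]]
        pair_key <- sort(c(min_label[i], min_label[j]))
        if (is.null(best) || dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 &&
             (pair_key[1] < best$key[1] ||
              (pair_key[1] == best$key[1] && pair_key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = dij, key = pair_key)
        }
      }
    }
    i <- best$i; j <- best$j
    ai <- active[i]; aj <- active[j]
    merges[[step]] <- list(
      members_a = labels[members[[i]]],
      members_b = labels[members[[j]]],
      height = best$d
    )
    hc_merge[step, ] <- c(hc_id[i], hc_id[j])
    hc_height[step] <- best$d
    # Lance-Williams update for the unweighted cross-pair mean
    ni <- sizes[i]; nj <- sizes[j]
    others <- setdiff(seq_len(k), c(i, j))
    for (o in others) {
      ao <- active[o]
      dv <- (ni * d[ai, ao] + nj * d[aj, ao]) / (ni + nj)
      d[ai, ao] <- dv; d[ao, ai] <- dv
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- ni + nj
    hc_id[i] <- step
    min_label[i] <- min(min_label[i], min_label[j])
    active <- active[-j]; members[j] <- NULL
    sizes <- sizes[-j]; hc_id <- hc_id[-j]; min_label <- min_label[-j]
  }
  structure(
    list(merges = merges, labels = labels, merge = hc_merge, height = hc_height),
    class = "snp_tree"
  )
}

#' @export
print.snp_tree <- function(x, ...) {
  cat(sprintf("Average-linkage tree over %d variant(s)\n", length(x$labels)))
  for (m in x$merges) {
    cat(sprintf("  {%s} + {%s} @ %.1f A\n",
                paste(m$members_a, collapse = ","),
                paste(m$members_b, collapse = ","), m$height))
  }
  invisible(x)
}

#' Convert a `snp_tree` to an [stats::hclust] object
#'
#' @param x a `snp_tree` with at least 2 leaves.
#' @param ... unused.
#' @return an object of class `hclust` (usable with [stats::cutree],
#'   `plot()` dendrograms and [ape::as.phylo]).
#' @export
as.hclust.snp_tree <- function(x, ...) {
  n <- length(x$labels)
  if (n < 2L) stop("an hclust object needs at least 2 leaves")
  hc <- list(merge = x$merge, height = x$height,
             order = leaf_order(x$merge, n),
             labels = x$labels, method = "average",
             dist.method = "euclidean", call = match.call())
  class(hc) <- "hclust"
  hc
}

leaf_order <- function(merge, n) {
  expand <- function(id) {
    if (id < 0L) return(-id)
    c(expand(merge[id, 1]), expand(merge[id, 2]))
  }
  expand(n - 1L)
}

#' Serialize a cluster tree as Newick
#'
#' Convenience export for external dendrogram viewers; requires the `ape`
#' package.
#'
#' @param tree a `snp_tree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("Newick export requires the 'ape' package")
  }
  hc <- stats::as.hclust(tree)
  # Newick reserves spaces and parentheses; sanitize display labels
  hc$labels <- gsub("[^A-Za-z0-9_.-]+", "_", hc$labels)
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Cut a cluster tree at a distance threshold
#'
#' Clusters are the connected groups formed by merges with height not above
#' the threshold. Multi-member clusters are numbered 1..k (largest first, ties
#' by smallest member label); singletons are reported separately with cluster
#' index 0, matching the flagged-structure colouring convention.
#'
#' @param tree a `snp_tree`.
#' @param threshold cut height in Angstrom (> 0).
#' @return list with `assignment` (named integer vector, 0 for singletons),
#'   `clusters` — a table with one row per multi-member cluster: `cluster`,
#'   `members` (comma-joined), `size`, `height` (the largest merge height
#'   inside the cluster, Angstrom) — and `singletons` (labels).
#' @export
cut_tree <- function(tree, threshold) {
  stopifnot(threshold > 0)
  labels <- tree$labels
  n <- length(labels)
  comp <- seq_len(n)
  cluster_h <- numeric(n)  # max merge height per component root
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (m in tree$merges) {
    if (m$height > threshold) next
    a <- find(match(m$members_a[1], labels))
    b <- find(match(m$members_b[1], labels))
    comp[b] <- a
    cluster_h[a] <- max(cluster_h[a], cluster_h[b], m$height)
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)
  multi <- groups[lengths(groups) > 1L]
  # deterministic numbering: size descending, then smallest member label
  if (length(multi) > 0L) {
    ord <- order(-lengths(multi),
                 vapply(multi, function(g) min(labels[g]), character(1)))
    multi <- multi[ord]
  }
  assignment <- stats::setNames(rep(0L, n), labels)
  rows <- list()
  for (ci in seq_along(multi)) {
    g <- multi[[ci]]
    assignment[g] <- ci
    rows[[ci]] <- data.frame(
      cluster = ci,
      members = paste(sort(labels[g]), collapse = ", "),
      size = length(g),
      height = cluster_h[find(g[1])],
      stringsAsFactors = FALSE
    )
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(), members = character(), size = integer(),
               height = numeric(), stringsAsFactors = FALSE)
  list(assignment = assignment, clusters = clusters,
       singletons = labels[assignment == 0L], threshold = threshold)
}
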