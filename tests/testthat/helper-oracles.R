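# Independent oracles used to cross-check the package's own implementations.

# Brute-force average linkage: recomputes the mean of all cross-pair
# distances from the ORIGINAL matrix at every step (no Lance-Williams
# update), with the same deterministic tie-break as the implementation.
oracle_average_linkage <- function(d, labels) {
  clusters <- as.list(seq_along(labels))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq.int(i + 1L, length(clusters))) {
        md <- mean(d[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(labels[clusters[[i]]]), min(labels[clusters[[j]]])))
        if (is.null(best) || md < best$d - 1e-12 ||
            (abs(md - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = md, key = key)
        }
      }
    }
    heights <- c(heights, best$d)
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  heights
}

# Dense-grid burial maximization: the burial count is flat over the whole
# interior of a cavity (every point sees every shell atom), so the argmax is
# a region, not a point; its centroid is the oracle location.
grid_burial_argmax <- function(atoms_xyz, radius = 8, step = 0.5, margin = 2) {
  lo <- apply(atoms_xyz, 2, min) - margin
  hi <- apply(atoms_xyz, 2, max) + margin
  gx <- seq(lo[1], hi[1], by = step)
  gy <- seq(lo[2], hi[2], by = step)
  gz <- seq(lo[3], hi[3], by = step)
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  r2 <- radius^2
  chunk <- 20000L
  counts <- integer(nrow(grid))
  for (start in seq(1L, nrow(grid), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(grid))
    g <- grid[idx, , drop = FALSE]
    d2 <- outer(rowSums(g^2), rowSums(atoms_xyz^2), "+") - 2 * g %*% t(atoms_xyz)
    counts[idx] <- rowSums(d2 <= r2)
  }
  best_n <- max(counts)
  list(point = unname(colMeans(grid[counts == best_n, , drop = FALSE])),
       burial = best_n)
}

# A mapped-variant table built directly from coordinates (bypasses PDB I/O
# where a test only exercises geometry).
mapped_from_points <- function(xyz, labels = NULL) {
  n <- nrow(xyz)
  if (is.null(labels)) labels <- sprintf("A%dG (A)", seq_len(n))
  sub <- sub(" .*$", "", labels)
  data.frame(
    gene = "TOY", wt = "A", pos = seq_len(n), mut = "G", sub = sub,
    chain = "A", resno = seq_len(n), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    status = "mapped", reason = NA_character_, offset_applied = 0L,
    label = labels, stringsAsFactors = FALSE
  )
}

rigid_transform <- function(xyz, angles, shift) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  sweep(xyz %*% t(R), 2, shift, "+")
}

apply_rigid_to_structure <- function(structure_, angles, shift) {
  for (tab in c("atoms", "het")) {
    at <- structure_[[tab]]
    if (nrow(at) == 0L) next
    xyz <- rigid_transform(as.matrix(at[, c("x", "y", "z")]), angles, shift)
    structure_[[tab]]$x <- xyz[, 1]
    structure_[[tab]]$y <- xyz[, 2]
    structure_[[tab]]$z <- xyz[, 3]
  }
  structure_
}
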