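# Probe-sphere binding-pocket detection in the spirit of PASS (Putative
# Active Sites with Spheres): fill surface clefts with probe spheres placed
# tangent to triplets of atom/probe spheres, keep only well-buried,
# clash-free probes, grow the set in accretion layers, then group retained
# probes and report each group's burial-weighted centroid as a putative
# active-site point.
#
# All placements are derived from pairwise geometry and a canonical atom
# ordering (chain, residue number, insertion code, atom name), so the
# procedure is deterministic and equivariant under rigid motions.

#' Pocket-detection parameters
#'
#' Numeric defaults follow the published PASS parameterization: probe radius
#' 1.8 A, burial-count radius 8 A, burial threshold 55 atoms, 1 A probe
#' de-duplication, 3 A single-linkage grouping, minimum 3 probes per pocket,
#' at most 5 accretion layers.
#'
#' @param probe_radius probe sphere radius (Angstrom).
#' @param burial_radius radius of the burial-count sphere (Angstrom).
#' @param burial_threshold minimum burial count for a retained probe.
#' @param dedup_dist probes closer than this merge, keeping the more buried.
#' @param group_dist single-linkage grouping distance for pocket extraction.
#' @param min_probes smallest probe group reported as a pocket.
#' @param max_layers maximum accretion layers after seeding.
#' @param clash_tol tolerated overlap (Angstrom) between a probe and an atom.
#' @param include_het include hetero (ligand) atoms in the burial atom set;
#'   off by default so pockets are detectable in apo structures.
#' @return named list of parameters.
#' @export
pocket_params <- function(probe_radius = 1.8, burial_radius = 8.0,
                          burial_threshold = 55L, dedup_dist = 1.0,
                          group_dist = 3.0, min_probes = 3L, max_layers = 5L,
                          clash_tol = 0.1, include_het = FALSE) {
  list(probe_radius = probe_radius, burial_radius = burial_radius,
       burial_threshold = burial_threshold, dedup_dist = dedup_dist,
       group_dist = group_dist, min_probes = min_probes,
       max_layers = max_layers, clash_tol = clash_tol,
       include_het = include_het)
}

#' Heavy-atom table used for pocket detection
#'
#' Protein heavy atoms (hydrogens dropped) in canonical order, with van der
#' Waals radii from the shipped element table; duplicate coordinates are
#' removed. Hetero atoms are appended only when `include_het` is set.
#'
#' @param structure a `protein_structure`.
#' @param include_het include hetero atoms.
#' @return data.frame with `x`, `y`, `z`, `vdw`.
#' @export
pocket_atoms <- function(structure, include_het = FALSE) {
  at <- structure$atoms
  if (include_het && nrow(structure$het) > 0L) at <- rbind(at, structure$het)
  at <- at[at$elesy != "H", , drop = FALSE]
  at <- at[order(at$chain, at$resno, at$insert, at$elety, method = "radix"), ,
           drop = FALSE]
  vdw <- vdw_radii_table()
  r <- vdw$radius[match(at$elesy, vdw$element)]
  r[is.na(r)] <- 1.70
  out <- data.frame(x = at$x, y = at$y, z = at$z, vdw = r)
  out[!duplicated(round(as.matrix(out[, 1:3]), 6)), , drop = FALSE]
}

#' Burial count of a point
#'
#' Number of heavy-atom centers within `burial_radius` of the point
#' (boundary inclusive). High counts indicate buried, pocket-like positions.
#'
#' @param point numeric length-3 coordinate.
#' @param atoms atom table with `x`, `y`, `z` columns (see [pocket_atoms()]).
#' @param burial_radius count radius in Angstrom (default 8).
#' @return integer count.
#' @export
burial_count <- function(point, atoms, burial_radius = 8.0) {
  stopifnot(burial_radius > 0)
  if (nrow(atoms) == 0L) return(0L)
  burial_counts(matrix(point, nrow = 1L), as.matrix(atoms[, c("x", "y", "z")]),
                burial_radius)
}

# Vectorized burial counts: points (m x 3) against coords (n x 3).
burial_counts <- function(points, coords, radius) {
  if (nrow(points) == 0L) return(integer(0))
  if (nrow(coords) == 0L) return(rep(0L, nrow(points)))
  r2 <- radius^2
  out <- integer(nrow(points))
  chunk <- max(1L, floor(5e6 / nrow(coords)))
  cs2 <- rowSums(coords^2)
  for (start in seq(1L, nrow(points), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(points))
    p <- points[idx, , drop = FALSE]
    d2 <- outer(rowSums(p^2), cs2, "+") - 2 * p %*% t(coords)
    out[idx] <- as.integer(rowSums(d2 <= r2 + 1e-9))
  }
  out
}

# Tangent points to three spheres (vectorized trilateration).
# P1,P2,P3: m x 3 center matrices; R1,R2,R3: effective radii (sphere radius +
# probe radius). Returns a matrix of candidate probe centers (0, 1 or 2 per
# triplet) plus the generating triplet row index (for order-stable
# downstream tie-breaking).
tangent_points <- function(P1, P2, P3, R1, R2, R3) {
  v1 <- P2 - P1
  d <- sqrt(rowSums(v1^2))
  ok <- d > 1e-9
  ex <- v1 / d
  v2 <- P3 - P1
  ipr <- rowSums(ex * v2)
  tmp <- v2 - ipr * ex
  jn <- sqrt(rowSums(tmp^2))
  ok <- ok & jn > 1e-9
  ey <- tmp / jn
  ez <- cbind(ex[, 2] * ey[, 3] - ex[, 3] * ey[, 2],
              ex[, 3] * ey[, 1] - ex[, 1] * ey[, 3],
              ex[, 1] * ey[, 2] - ex[, 2] * ey[, 1])
  xx <- (R1^2 - R2^2 + d^2) / (2 * d)
  yy <- (R1^2 - R3^2 + ipr^2 + jn^2) / (2 * jn) - (ipr / jn) * xx
  z2 <- R1^2 - xx^2 - yy^2
  ok <- ok & is.finite(z2) & z2 >= 0
  z <- sqrt(pmax(z2, 0))
  base <- P1 + xx * ex + yy * ey
  up <- base + z * ez
  dn <- base - z * ez
  idx <- seq_len(nrow(P1))
  two <- ok & z > 1e-6
  one <- ok & !two
  list(points = rbind(up[two, , drop = FALSE], dn[two, , drop = FALSE],
                      base[one, , drop = FALSE]),
       origin = c(idx[two], idx[two], idx[one]))
}

# Triangles (i<j<k) of an adjacency defined by pairwise distance <= cutoff.
neighbor_triplets <- function(coords, cutoff) {
  n <- nrow(coords)
  if (n < 3L) return(matrix(integer(0), ncol = 3L))
  d <- as.matrix(stats::dist(coords))
  adj <- d <= cutoff
  diag(adj) <- FALSE
  out <- list()
  for (i in seq_len(n - 2L)) {
    nb <- which(adj[i, ] & seq_len(n) > i)
    if (length(nb) < 2L) next
    for (a in seq_len(length(nb) - 1L)) {
      j <- nb[a]
      ks <- nb[(a + 1L):length(nb)]
      ks <- ks[adj[j, ks]]
      if (length(ks)) out[[length(out) + 1L]] <- cbind(i, j, ks)
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 3L))
  do.call(rbind, out)
}

# Filter candidate probe centers: no clash against atoms, burial above
# threshold. Returns data.frame x,y,z,burial in candidate order.
filter_candidates <- function(points, origin, atoms_xyz, atoms_vdw, params) {
  if (nrow(points) == 0L) {
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      burial = integer()))
  }
  keep <- rep(TRUE, nrow(points))
  chunk <- max(1L, floor(5e6 / nrow(atoms_xyz)))
  ca2 <- rowSums(atoms_xyz^2)
  limv <- (atoms_vdw + params$probe_radius - params$clash_tol)^2
  for (start in seq(1L, nrow(points), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(points))
    p <- points[idx, , drop = FALSE]
    d2 <- outer(rowSums(p^2), ca2, "+") - 2 * p %*% t(atoms_xyz)
    clash <- d2 < rep(limv, each = nrow(p)) - 1e-9
    keep[idx] <- rowSums(clash) == 0L
  }
  points <- points[keep, , drop = FALSE]
  if (nrow(points) == 0L) {
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      burial = integer()))
  }
  burial <- burial_counts(points, atoms_xyz, params$burial_radius)
  sel <- burial >= params$burial_threshold
  data.frame(x = points[sel, 1], y = points[sel, 2], z = points[sel, 3],
             burial = burial[sel])
}

# Greedy de-duplication: candidates ordered by burial (descending, stable in
# generation order), accepted if at least dedup_dist from every accepted
# center and from every probe in `against`.
dedup_probes <- function(cand, against, dedup_dist) {
  if (nrow(cand) == 0L) return(cand)
  ord <- order(-cand$burial)  # stable: ties keep generation order
  cand <- cand[ord, , drop = FALSE]
  acc <- matrix(numeric(0), ncol = 3L)
  if (!is.null(against) && nrow(against) > 0L) {
    acc <- as.matrix(against[, c("x", "y", "z")])
  }
  n_fixed <- nrow(acc)
  keep <- logical(nrow(cand))
  d2min <- dedup_dist^2
  for (i in seq_len(nrow(cand))) {
    p <- c(cand$x[i], cand$y[i], cand$z[i])
    if (nrow(acc) == 0L ||
        min(rowSums((acc - matrix(p, nrow(acc), 3, byrow = TRUE))^2)) >= d2min) {
      keep[i] <- TRUE
      acc <- rbind(acc, p)
    }
  }
  cand[keep, , drop = FALSE]
}

#' Seed the layer-0 probe set
#'
#' Candidate probes of radius `probe_radius` are placed tangent to every
#' triplet of neighboring atoms (pairwise atom distance at most
#' `2 * max(vdW) + 2 * probe_radius`); candidates clashing with any atom, or
#' with a burial count below `burial_threshold`, are discarded, and
#' near-duplicates (< `dedup_dist` apart) merge keeping the more buried one.
#'
#' @param structure a `protein_structure`.
#' @param params parameter list from [pocket_params()].
#' @return probe data.frame with `x`, `y`, `z`, `burial`, `layer` (= 0).
#' @export
seed_probes <- function(structure, params = pocket_params()) {
  atoms <- pocket_atoms(structure, params$include_het)
  if (nrow(atoms) < 4L) {
    warning("fewer than 4 heavy atoms; no probes seeded", call. = FALSE)
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      burial = integer(), layer = integer()))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  cutoff <- 2 * max(atoms$vdw) + 2 * params$probe_radius
  trip <- neighbor_triplets(xyz, cutoff)
  if (nrow(trip) == 0L) {
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      burial = integer(), layer = integer()))
  }
  rr <- atoms$vdw + params$probe_radius
  tp <- tangent_points(xyz[trip[, 1], , drop = FALSE],
                       xyz[trip[, 2], , drop = FALSE],
                       xyz[trip[, 3], , drop = FALSE],
                       rr[trip[, 1]], rr[trip[, 2]], rr[trip[, 3]])
  cand <- filter_candidates(tp$points, tp$origin, xyz, atoms$vdw, params)
  probes <- dedup_probes(cand, NULL, params$dedup_dist)
  if (nrow(probes) > 0L) probes$layer <- 0L else probes$layer <- integer(0)
  rownames(probes) <- NULL
  probes
}

#' Grow the probe set by accretion layers
#'
#' New probes are placed tangent to two existing probes plus one atom, and to
#' probe triplets, under the same clash/burial/de-duplication filters as
#' seeding (existing probes win de-duplication against new candidates).
#' Accretion stops when a layer adds no probe or after `max_layers` layers.
#'
#' @param probes layer-0 probe set from [seed_probes()].
#' @param structure a `protein_structure`.
#' @param params parameter list from [pocket_params()].
#' @return probe data.frame; each probe records the layer that created it.
#' @export
accrete <- function(probes, structure, params = pocket_params()) {
  if (nrow(probes) == 0L) return(probes)
  atoms <- pocket_atoms(structure, params$include_het)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rr_atom <- atoms$vdw + params$probe_radius
  rp2 <- 2 * params$probe_radius
  for (layer in seq_len(params$max_layers)) {
    px <- as.matrix(probes[, c("x", "y", "z")])
    np <- nrow(px)
    # probe-probe pairs close enough for a common tangent probe to exist
    pd <- as.matrix(stats::dist(px))
    pairs <- which(upper.tri(pd) & pd <= 2 * rp2, arr.ind = TRUE)
    cand_pts <- list(); cand_org <- list(); org_base <- 0L
    if (nrow(pairs) > 0L) {
      # pair + atom: atom must be within reach of both probe centers
      pa_ok <- vapply(seq_len(nrow(atoms)), function(a) {
        da <- sqrt(rowSums((px - matrix(xyz[a, ], np, 3, byrow = TRUE))^2))
        da <= rp2 + rr_atom[a]
      }, logical(np))
      if (np == 1L) pa_ok <- matrix(pa_ok, nrow = 1L)
      tri <- list()
      for (q in seq_len(nrow(pairs))) {
        i <- pairs[q, 1]; j <- pairs[q, 2]
        ks <- which(pa_ok[i, ] & pa_ok[j, ])
        if (length(ks)) tri[[length(tri) + 1L]] <- cbind(i, j, ks)
      }
      if (length(tri)) {
        tri <- do.call(rbind, tri)
        tp <- tangent_points(px[tri[, 1], , drop = FALSE],
                             px[tri[, 2], , drop = FALSE],
                             xyz[tri[, 3], , drop = FALSE],
                             rep(rp2, nrow(tri)), rep(rp2, nrow(tri)),
                             rr_atom[tri[, 3]])
        cand_pts[[length(cand_pts) + 1L]] <- tp$points
      }
      # probe triplets
      ptri <- neighbor_triplets(px, 2 * rp2)
      if (nrow(ptri) > 0L) {
        tp <- tangent_points(px[ptri[, 1], , drop = FALSE],
                             px[ptri[, 2], , drop = FALSE],
                             px[ptri[, 3], , drop = FALSE],
                             rep(rp2, nrow(ptri)), rep(rp2, nrow(ptri)),
                             rep(rp2, nrow(ptri)))
        cand_pts[[length(cand_pts) + 1L]] <- tp$points
      }
    }
    if (!length(cand_pts)) break
    pts <- do.call(rbind, cand_pts)
    cand <- filter_candidates(pts, seq_len(nrow(pts)), xyz, atoms$vdw, params)
    new <- dedup_probes(cand, probes, params$dedup_dist)
    if (nrow(new) == 0L) break
    new$layer <- layer
    probes <- rbind(probes, new)
  }
  rownames(probes) <- NULL
  probes
}

#' Group probes into ranked pockets
#'
#' Probes are grouped by single linkage at `group_dist`; each group's pocket
#' center is the burial-weighted centroid of its probes, its weight the sum
#' of member burial counts. Groups smaller than `min_probes` are dropped;
#' pockets are ranked by weight, descending.
#'
#' @param probes probe set from [accrete()] (or [seed_probes()]).
#' @param params parameter list from [pocket_params()].
#' @return data.frame with `rank`, `x`, `y`, `z` (pocket center), `weight`,
#'   `n_probes`; the probe table with a `pocket` assignment column is
#'   attached as attribute `"probes"`.
#' @export
extract_pockets <- function(probes, params = pocket_params()) {
  empty <- data.frame(rank = integer(), x = numeric(), y = numeric(),
                      z = numeric(), weight = numeric(), n_probes = integer())
  if (nrow(probes) == 0L) return(empty)
  if (nrow(probes) == 1L) {
    grp <- 1L
  } else {
    hc <- stats::hclust(stats::dist(probes[, c("x", "y", "z")]), method = "single")
    grp <- stats::cutree(hc, h = params$group_dist)
  }
  rows <- list()
  for (g in unique(grp)) {
    sel <- grp == g
    if (sum(sel) < params$min_probes) next
    w <- probes$burial[sel]
    rows[[length(rows) + 1L]] <- data.frame(
      x = sum(probes$x[sel] * w) / sum(w),
      y = sum(probes$y[sel] * w) / sum(w),
      z = sum(probes$z[sel] * w) / sum(w),
      weight = sum(w), n_probes = sum(sel), group = g
    )
  }
  if (!length(rows)) return(empty)
  pk <- do.call(rbind, rows)
  ord <- order(-pk$weight, -pk$n_probes)
  pk <- pk[ord, , drop = FALSE]
  pk$rank <- seq_len(nrow(pk))
  probes$pocket <- match(grp, pk$group)
  pk <- pk[, c("rank", "x", "y", "z", "weight", "n_probes")]
  rownames(pk) <- NULL
  attr(pk, "probes") <- probes
  pk
}

#' Detect pockets in one call
#'
#' Convenience wrapper: seed, accrete, extract.
#'
#' @inheritParams seed_probes
#' @return ranked pocket table (see [extract_pockets()]).
#' @export
find_pockets <- function(structure, params = pocket_params()) {
  extract_pockets(accrete(seed_probes(structure, params), structure, params),
                  params)
}

#' Variants near pocket centers
#'
#' One row per (mapped variant, pocket) pair whose C-alpha-to-center distance
#' is at most `hit_radius` (boundary inclusive).
#'
#' @param mapped table from [map_variants()].
#' @param pockets ranked pocket table from [extract_pockets()].
#' @param hit_radius proximity cutoff in Angstrom (default 8).
#' @return data.frame with `label`, `pocket`, `distance` (Angstrom).
#' @export
variant_pocket_hits <- function(mapped, pockets, hit_radius = 8.0) {
  stopifnot(hit_radius >= 0)
  m <- mapped[mapped$status == "mapped", , drop = FALSE]
  out <- data.frame(label = character(), pocket = integer(),
                    distance = numeric(), stringsAsFactors = FALSE)
  if (nrow(m) == 0L || nrow(pockets) == 0L) return(out)
  for (v in seq_len(nrow(m))) {
    dd <- sqrt((pockets$x - m$x[v])^2 + (pockets$y - m$y[v])^2 +
               (pockets$z - m$z[v])^2)
    hit <- which(dd <= hit_radius + 1e-9)
    if (length(hit)) {
      out <- rbind(out, data.frame(label = m$label[v],
                                   pocket = pockets$rank[hit],
                                   distance = dd[hit], stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Write pocket centers as a PDB file of pseudo-atoms
#'
#' Each pocket center becomes a HETATM pseudo-atom (residue `PKT`, chain `P`)
#' so any molecular viewer can display the putative active-site points as
#' spheres over the structure.
#'
#' @param pockets ranked pocket table.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_pockets_pdb <- function(pockets, path) {
  if (nrow(pockets) == 0L) {
    writeLines("END", path)
    return(invisible(path))
  }
  xyz <- as.vector(t(as.matrix(pockets[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("HETATM", nrow(pockets)),
                   resno = pockets$rank, resid = rep("PKT", nrow(pockets)),
                   chain = rep("P", nrow(pockets)), elety = rep("XX", nrow(pockets)),
                   b = pockets$n_probes, o = rep(1, nrow(pockets)))
  invisible(path)
}
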