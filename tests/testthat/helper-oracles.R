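# Independent pure-R oracles used to cross-check the compiled paths.

# Breadth-first flood fill over a 3D logical array; returns a list of
# sorted linear-index vectors, ordered by each component's minimum index.
flood_fill_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  m <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  keep <- switch(as.character(connectivity),
                 "6" = m == 1, "18" = m >= 1 & m <= 2, "26" = m >= 1)
  offs <- offs[keep, , drop = FALSE]
  visited <- array(FALSE, dim = d)
  comps <- list()
  fg <- which(mask)
  for (start in fg) {
    if (visited[start]) next
    queue <- start
    visited[start] <- TRUE
    comp <- integer()
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      comp <- c(comp, cur)
      ijk <- arrayInd(cur, d)
      for (o in seq_len(nrow(offs))) {
        ni <- ijk[1] + offs$dx[o]; nj <- ijk[2] + offs$dy[o]
        nk <- ijk[3] + offs$dz[o]
        if (ni < 1 || nj < 1 || nk < 1 || ni > d[1] || nj > d[2] || nk > d[3])
          next
        lin <- ni + d[1] * ((nj - 1) + d[2] * (nk - 1))
        if (mask[lin] && !visited[lin]) {
          visited[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, min, numeric(1)))]
}

# Transitive-closure partition of boxes under strict overlap, by union-find;
# iterated with re-expansion to a cube, mirroring the stated merge
# semantics but through an independent algorithm.
merge_boxes_oracle <- function(lo, hi) {
  groups <- as.list(seq_len(nrow(lo)))
  repeat {
    n <- length(groups)
    glo <- t(vapply(groups, function(g)
      apply(lo[g, , drop = FALSE], 2, min), numeric(3)))
    ghi <- t(vapply(groups, function(g)
      apply(hi[g, , drop = FALSE], 2, max), numeric(3)))
    # cube expansion
    side <- apply(ghi - glo, 1, max)
    ctr <- (glo + ghi) / 2
    glo <- ctr - side / 2; ghi <- ctr + side / 2
    if (n == 1) break
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    any_merge <- FALSE
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      ov <- pmin(ghi[a, ], ghi[b, ]) - pmax(glo[a, ], glo[b, ])
      if (all(ov > 0)) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) { parent[max(ra, rb)] <- min(ra, rb); any_merge <- TRUE }
      }
    }
    if (!any_merge) break
    roots <- vapply(seq_len(n), find, integer(1))
    groups <- lapply(unique(roots), function(r)
      sort(unlist(groups[roots == r])))
  }
  canonical_partition(groups)
}

canonical_partition <- function(groups) {
  groups <- lapply(groups, function(g) as.integer(sort(g)))
  groups[order(vapply(groups, min, numeric(1)))]
}

# Build an `mcc_cubes` table from bound matrices (tests of the merge stage).
make_cubes <- function(lo, hi, mcs = NULL) {
  if (is.null(mcs)) {
    empty_mask <- dbt_volume(array(0, dim = c(2, 2, 2)))
    mcs <- connected_components(empty_mask)
  }
  out <- data.frame(xmin_mm = lo[, 1], xmax_mm = hi[, 1],
                    ymin_mm = lo[, 2], ymax_mm = hi[, 2],
                    zmin_mm = lo[, 3], zmax_mm = hi[, 3],
                    mc_count = 0L, mc_volume_mm3 = 0,
                    merged_from = 1L, score = 1)
  out$source_cluster <- as.list(seq_len(nrow(out)))
  attr(out, "mcs") <- mcs
  class(out) <- c("mcc_cubes", "data.frame")
  out
}

# Analytic isotropic Gaussian blob sampled at voxel centers.
analytic_blob <- function(dims, spacing, center_mm, s_mm, amplitude = 1) {
  xs <- (seq_len(dims[1]) - 1) * spacing[1] - center_mm[1]
  ys <- (seq_len(dims[2]) - 1) * spacing[2] - center_mm[2]
  zs <- (seq_len(dims[3]) - 1) * spacing[3] - center_mm[3]
  gx <- exp(-xs^2 / (2 * s_mm^2))
  gy <- exp(-ys^2 / (2 * s_mm^2))
  gz <- exp(-zs^2 / (2 * s_mm^2))
  amplitude * (gx %o% gy %o% gz)
}

random_mask <- function(d = c(8, 8, 8), p = 0.3) {
  array(runif(prod(d)) < p, dim = d)
}

# label partition from a `labeled_objects` table, as sorted linear indices
objects_to_partition <- function(obj, dims) {
  canonical_partition(lapply(obj$voxels, function(m)
    m[, 1] + dims[1] * ((m[, 2] - 1) + dims[2] * (m[, 3] - 1))))
}
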