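# Independent oracles used across the test files. These deliberately take
# different algorithmic routes from the package implementation.

# O(n^2) single-linkage clustering via union-find with path halving over
# the full pairwise distance list (strict `<` linking rule).
oracle_single_linkage <- function(pts, d) {
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      dx <- pts[(i + 1):n, 1] - pts[i, 1]
      dy <- pts[(i + 1):n, 2] - pts[i, 2]
      close <- which(sqrt(dx^2 + dy^2) < d)
      for (j in i + close) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Canonical form of a partition (for exact comparison across labellings).
canonical_partition <- function(membership) {
  unname(lapply(split(seq_along(membership), membership), sort))[
    order(vapply(split(seq_along(membership), membership), min, integer(1)))]
}

# Brute-force convex hull area: O(n^3) hull-edge detection (an edge is on
# the hull iff all remaining points lie on one side), then shoelace over
# the angularly ordered hull vertices. Independent of grDevices::chull.
oracle_hull_area <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(0)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      others <- setdiff(seq_len(n), c(i, j))
      cr <- (pts[j, 1] - pts[i, 1]) * (pts[others, 2] - pts[i, 2]) -
        (pts[j, 2] - pts[i, 2]) * (pts[others, 1] - pts[i, 1])
      if (all(cr >= -1e-12) || all(cr <= 1e-12)) {
        on_hull[c(i, j)] <- TRUE
      }
    }
  }
  h <- pts[on_hull, , drop = FALSE]
  if (nrow(h) < 3) return(0)
  ctr <- colMeans(h)
  h <- h[order(atan2(h[, 1] - ctr[1], h[, 2] - ctr[2])), , drop = FALSE]
  y <- h[, 1]; x <- h[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Exact two-sided signed-rank p-value by enumeration of all 2^n sign
# assignments (requires no zero differences and no tied |d|).
oracle_signed_rank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
  min(1, p)
}

# Exact two-sided Mann-Whitney p by enumeration of all C(n1+n2, n1)
# arrangements of the pooled ranks (no ties assumed).
oracle_mann_whitney <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  comb <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[comb], nrow = n1)) - n1 * (n1 + 1) / 2
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(u = u_obs, p = min(1, p))
}

# Pick's theorem area for a simple lattice polygon: A = I + B/2 - 1.
oracle_pick_area <- function(poly) {
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  boundary <- sum(mapply(function(i, j) {
    gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
    gcd(abs(poly[j, 1] - poly[i, 1]), abs(poly[j, 2] - poly[i, 2]))
  }, seq_len(n), nxt))
  yr <- range(poly[, 1]); xr <- range(poly[, 2])
  interior <- 0L
  for (y in seq(yr[1], yr[2])) {
    for (x in seq(xr[1], xr[2])) {
      if (point_in_polygon(y, x, poly) == 1L) interior <- interior + 1L
    }
  }
  interior + boundary / 2 - 1
}

# Ray casting; returns 1 strictly inside, 0 outside or on boundary.
point_in_polygon <- function(y, x, poly) {
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  # on-boundary check
  for (i in seq_len(n)) {
    p1 <- poly[i, ]; p2 <- poly[nxt[i], ]
    cr <- (p2[1] - p1[1]) * (x - p1[2]) - (p2[2] - p1[2]) * (y - p1[1])
    if (abs(cr) < 1e-9 &&
        y >= min(p1[1], p2[1]) && y <= max(p1[1], p2[1]) &&
        x >= min(p1[2], p2[2]) && x <= max(p1[2], p2[2])) {
      return(0L)
    }
  }
  inside <- FALSE
  for (i in seq_len(n)) {
    p1 <- poly[i, ]; p2 <- poly[nxt[i], ]
    if ((p1[1] > y) != (p2[1] > y)) {
      xint <- p1[2] + (y - p1[1]) / (p2[1] - p1[1]) * (p2[2] - p1[2])
      if (x < xint) inside <- !inside
    }
  }
  if (inside) 1L else 0L
}

# Random convex lattice polygon (hull of random integer points).
random_lattice_polygon <- function(k = 12, span = 30) {
  pts <- unique(cbind(sample.int(span, k, replace = TRUE),
                      sample.int(span, k, replace = TRUE)))
  h <- grDevices::chull(pts[, 2], pts[, 1])
  poly <- pts[h, , drop = FALSE]
  if (nrow(poly) < 3) return(random_lattice_polygon(k, span))
  poly
}

# 8-connected component centroids by explicit BFS flood fill (independent
# of EBImage labelling).
flood_fill_centroids <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  res <- list()
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    comp <- matrix(integer(0), ncol = 2)
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      comp <- rbind(comp, p)
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
    res[[length(res) + 1]] <- data.frame(
      y = mean(comp[, 1]) - 1, x = mean(comp[, 2]) - 1, n = nrow(comp))
  }
  do.call(rbind, res)
}

# Small noise-free single-cell field for morphometry tests.
render_single_cell <- function(seed, k = 5, field_px = 512,
                               arbor = c(17, 1.5)) {
  fs <- field_spec(n_cells = 1, n_processes = c(k, k),
                   arbor_radius_um = arbor, seed = seed,
                   field_px = field_px, n_z = 1,
                   noise_sd = 0, background_level = 0)
  render_field(fs)
}
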