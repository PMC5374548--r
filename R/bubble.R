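#' Parameters for flowcell bubble detection
#'
#' None of these values are published for the underlying method; the
#' defaults here are calibrated on the package's simulator geometry (a
#' 2000 x 2000 tile). `eps` is set so that a bubble's polyX hits form one
#' connected cluster: at the simulated bubble density (~150 hits in a
#' radius-300 disc) an eps of tile_width/25 gives each hit ~10 neighbours,
#' safely above the 2-D continuum percolation threshold, while
#' tile_width/50 would fragment the cluster.
#'
#' @param tile_width,tile_height Tile extent in header coordinate units.
#' @param grid Density-filter grid is `grid x grid` cells.
#' @param fold Keep cells whose hit count exceeds `fold` times the tile
#'   mean cell count.
#' @param eps Neighbour radius for density-reachability clustering.
#' @param min_points Minimum hits per cluster (and per reported circle).
#' @param r_min,r_max Acceptable enclosing-circle radius range.
#' @param shape_max Maximum ratio of enclosing-circle radius to mean
#'   hit-to-centroid distance (rejects line-like clusters).
#' @return A list of class `bubble_params`.
#' @export
bubble_params <- function(tile_width = 2000, tile_height = tile_width,
                          grid = 20L, fold = 5, eps = tile_width / 25,
                          min_points = 20L, r_min = tile_width / 100,
                          r_max = tile_width / 4, shape_max = 3) {
  stopifnot(grid >= 1, fold > 0, eps > 0, min_points >= 1,
            r_min >= 0, r_max > r_min)
  structure(list(tile_width = tile_width, tile_height = tile_height,
                 grid = as.integer(grid), fold = fold, eps = eps,
                 min_points = as.integer(min_points), r_min = r_min,
                 r_max = r_max, shape_max = shape_max),
            class = "bubble_params")
}

#' Local-density filter for polyX hits
#'
#' Bubble areas have a higher polyX density than the background, so hits
#' are kept only where the local density is high: the tile is cut into
#' `grid x grid` cells and hits survive when their cell's count exceeds
#' `fold` times the mean cell count. Uniform background is removed almost
#' entirely.
#'
#' @param hits Data frame with columns `x`, `y` (one lane+tile).
#' @param tile_width,tile_height Tile extent.
#' @param grid,fold See [bubble_params()].
#' @return The surviving subset of `hits`.
#' @export
density_filter <- function(hits, tile_width = 2000, tile_height = tile_width,
                           grid = 20L, fold = 5) {
  if (grid < 1) stop("grid must be >= 1", call. = FALSE)
  if (fold <= 0) stop("fold must be positive", call. = FALSE)
  n <- nrow(hits)
  if (n == 0) return(hits)
  cx <- pmin(pmax(floor(hits$x / tile_width * grid), 0), grid - 1)
  cy <- pmin(pmax(floor(hits$y / tile_height * grid), 0), grid - 1)
  cell <- cx * grid + cy
  counts <- table(cell)
  mean_count <- n / (grid * grid)
  keep_cells <- as.integer(names(counts))[counts > fold * mean_count]
  hits[cell %in% keep_cells, , drop = FALSE]
}

#' Cluster polyX hits by density reachability
#'
#' Two hits are neighbours when their Euclidean distance is at most `eps`;
#' clusters are connected components of the neighbour graph with at least
#' `min_points` hits. Clusters are then screened by size (enclosing-circle
#' radius within `[r_min, r_max]`) and shape (enclosing radius over mean
#' hit-to-centroid distance at most `shape_max`, rejecting line-like
#' sets).
#'
#' @param hits Data frame with columns `x`, `y` (one lane+tile, after
#'   [density_filter()]).
#' @param eps,min_points,r_min,r_max,shape_max See [bubble_params()].
#' @return A list of integer index vectors into `hits`, one per surviving
#'   cluster.
#' @export
cluster_hits <- function(hits, eps, min_points = 20L, r_min = 0,
                         r_max = Inf, shape_max = 3) {
  n <- nrow(hits)
  if (n == 0) return(list())
  d <- as.matrix(stats::dist(cbind(hits$x, hits$y)))
  adj <- d <= eps
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier) > 0) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  out <- list()
  for (k in seq_len(cur)) {
    idx <- which(comp == k)
    if (length(idx) < min_points) next
    pts <- cbind(hits$x[idx], hits$y[idx])
    # straggler pruning: background hits that latch onto a bubble cluster
    # sit beyond its rim and skew the fitted circle. For a filled disc the
    # largest legitimate centroid distance is ~1.41x the median distance
    # (max R vs median R/sqrt(2)), so points beyond 1.45x the median are
    # stray and dropped before fitting.
    ctr0 <- colMeans(pts)
    dc <- sqrt((pts[, 1] - ctr0[1])^2 + (pts[, 2] - ctr0[2])^2)
    keep <- dc <= 1.45 * stats::median(dc)
    if (sum(keep) >= min_points) {
      idx <- idx[keep]
      pts <- pts[keep, , drop = FALSE]
    }
    mec <- min_enclosing_circle(pts)
    if (mec$r < r_min || mec$r > r_max) next
    ctr <- colMeans(pts)
    spread <- mean(sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2))
    if (spread > 0 && mec$r / spread > shape_max) next
    out[[length(out) + 1]] <- idx
  }
  out
}

#' Minimum enclosing circle
#'
#' The unique smallest circle containing all points, by the classic
#' move-to-front incremental construction over 1-, 2- and 3-point support
#' sets. Deterministic: the optimum is unique.
#'
#' @param points A numeric matrix (or data frame) with two columns, at
#'   least one row.
#' @return A list with `cx`, `cy`, `r`.
#' @export
min_enclosing_circle <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) == 0) stop("no points", call. = FALSE)
  storage.mode(pts) <- "double"
  tol <- 1e-7
  inside <- function(c, p) {
    (p[1] - c[[1]])^2 + (p[2] - c[[2]])^2 <= c[[3]]^2 * (1 + tol) + tol
  }
  circ2 <- function(p, q) {
    list(cx = (p[1] + q[1]) / 2, cy = (p[2] + q[2]) / 2,
         r = sqrt(sum((p - q)^2)) / 2)
  }
  circ3 <- function(p, q, s) {
    ax <- p[1]; ay <- p[2]; bx <- q[1]; by <- q[2]; cx <- s[1]; cy <- s[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) {
      # collinear: fall back to the farthest pair's diameter circle
      cands <- list(circ2(p, q), circ2(p, s), circ2(q, s))
      cands <- cands[order(vapply(cands, `[[`, numeric(1), "r"),
                           decreasing = TRUE)]
      return(cands[[1]])
    }
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    list(cx = ux, cy = uy, r = sqrt((ax - ux)^2 + (ay - uy)^2))
  }
  cc <- function(c) c(c$cx, c$cy, c$r)
  circ <- list(cx = pts[1, 1], cy = pts[1, 2], r = 0)
  n <- nrow(pts)
  for (i in seq_len(n)) {
    if (inside(cc(circ), pts[i, ])) next
    circ <- list(cx = pts[i, 1], cy = pts[i, 2], r = 0)
    for (j in seq_len(i - 1L)) {
      if (inside(cc(circ), pts[j, ])) next
      circ <- circ2(pts[i, ], pts[j, ])
      for (k in seq_len(j - 1L)) {
        if (inside(cc(circ), pts[k, ])) next
        circ <- circ3(pts[i, ], pts[j, ], pts[k, ])
      }
    }
  }
  circ
}

#' Detect flowcell bubbles from polyX hit coordinates
#'
#' Per lane and tile: density filtering, density-reachability clustering
#' with size/shape screening, robust circle fitting (cluster re-expansion
#' over the full hit set, straggler pruning, then a minimum enclosing
#' circle with influence-based outlier peeling), and a
#' final circle filter (radius within bounds, support at least
#' `min_points`). The returned circles blacklist reads via
#' [bubble_filter()]. Bubble detection is off by default in the pipeline:
#' it mainly pays off on two-channel sequencer output, where bubbles read
#' as dense polyG patches.
#'
#' @param hits Data frame with columns `lane`, `tile`, `x`, `y` — one row
#'   per polyX read with parseable coordinates (see
#'   [collect_polyx_hits()]).
#' @param params A [bubble_params()] list.
#' @return A data frame of class `bubble_circles` with columns `lane`,
#'   `tile`, `cx`, `cy`, `r`, `support`.
#' @export
detect_bubbles <- function(hits, params = bubble_params()) {
  empty <- structure(data.frame(lane = integer(), tile = integer(),
                                cx = numeric(), cy = numeric(),
                                r = numeric(), support = integer()),
                     class = c("bubble_circles", "data.frame"))
  if (is.null(hits) || nrow(hits) == 0) return(empty)
  out <- empty
  for (grp in split(hits, list(hits$lane, hits$tile), drop = TRUE)) {
    dense <- density_filter(grp, params$tile_width, params$tile_height,
                            params$grid, params$fold)
    clusters <- cluster_hits(dense, eps = params$eps,
                             min_points = params$min_points,
                             r_min = params$r_min, r_max = params$r_max,
                             shape_max = params$shape_max)
    for (idx in clusters) {
      # the grid density filter clips sparse cells at a bubble's rim;
      # re-expand the cluster over the full hit set by eps-reachability
      # (background is far below percolation density, so stray chains die
      # out), then prune stragglers again before fitting
      sel <- expand_cluster(grp, dense[idx, , drop = FALSE], params$eps)
      pts <- cbind(grp$x[sel], grp$y[sel])
      # loose quantile prune first: expansion can drag in short background
      # chains whose points are individually low-influence, which the
      # peeling step below would not remove. 1.6x the median centroid
      # distance sits comfortably above a disc's max/median ratio (sqrt(2))
      # so true rim points are never cut.
      ctr0 <- colMeans(pts)
      dc <- sqrt((pts[, 1] - ctr0[1])^2 + (pts[, 2] - ctr0[2])^2)
      keep <- dc <= 1.6 * stats::median(dc)
      if (sum(keep) >= params$min_points) pts <- pts[keep, , drop = FALSE]
      fit <- robust_circle(pts, min_points = params$min_points)
      if (fit$r < params$r_min || fit$r > params$r_max) next
      if (fit$support < params$min_points) next
      out <- rbind(out, data.frame(lane = grp$lane[1], tile = grp$tile[1],
                                   cx = fit$cx, cy = fit$cy, r = fit$r,
                                   support = fit$support))
    }
  }
  class(out) <- c("bubble_circles", "data.frame")
  out
}

# Minimum enclosing circle with influence-based outlier peeling: a
# boundary point is removed only when dropping it shrinks the circle by
# more than `shrink` (a lone background straggler at distance D from a
# radius-R bubble shrinks it by (D-R)/(D+R); a legitimate rim point of a
# well-sampled disc shrinks it by well under 1%).
robust_circle <- function(pts, shrink = 0.03, max_peel = 10L,
                          min_points = 3L) {
  for (it in seq_len(max_peel + 1L)) {
    mec <- min_enclosing_circle(pts)
    if (it > max_peel || nrow(pts) <= min_points) break
    d <- sqrt((pts[, 1] - mec$cx)^2 + (pts[, 2] - mec$cy)^2)
    boundary <- which(d >= mec$r * (1 - 1e-6))
    best <- 0; best_i <- 0L
    for (i in boundary) {
      r2 <- min_enclosing_circle(pts[-i, , drop = FALSE])$r
      s <- (mec$r - r2) / mec$r
      if (s > best) { best <- s; best_i <- i }
    }
    if (best <= shrink) break
    pts <- pts[-best_i, , drop = FALSE]
  }
  list(cx = mec$cx, cy = mec$cy, r = mec$r, support = nrow(pts))
}

# eps-reachability closure of a seed cluster over the full hit set
expand_cluster <- function(all_hits, seed_hits, eps) {
  n <- nrow(all_hits)
  inset <- (all_hits$x * 1e6 + all_hits$y) %in%
    (seed_hits$x * 1e6 + seed_hits$y)
  frontier <- which(inset)
  while (length(frontier) > 0) {
    cand <- which(!inset)
    if (length(cand) == 0) break
    d2 <- outer(all_hits$x[cand], all_hits$x[frontier], `-`)^2 +
      outer(all_hits$y[cand], all_hits$y[frontier], `-`)^2
    nb <- cand[rowSums(d2 <= eps^2) > 0]
    inset[nb] <- TRUE
    frontier <- nb
  }
  which(inset)
}

#' Collect polyX hits with flowcell coordinates from reads
#'
#' Runs [detect_polyx_reads()] and keeps the reads that are polyX and have
#' parseable Illumina coordinates — the input to [detect_bubbles()].
#'
#' @param reads A [fastq_reads] data frame.
#' @param P,L PolyX detection parameters.
#' @return A data frame with columns `lane`, `tile`, `x`, `y`, `base`.
#' @export
collect_polyx_hits <- function(reads, P = 35L, L = 2L) {
  px <- detect_polyx_reads(reads, P = P, L = L)
  sel <- which(px$found)
  if (length(sel) == 0)
    return(data.frame(lane = integer(), tile = integer(), x = integer(),
                      y = integer(), base = character(),
                      stringsAsFactors = FALSE))
  co <- parse_coords(reads$name[sel])
  keep <- !is.na(co$lane)
  data.frame(lane = co$lane[keep], tile = co$tile[keep], x = co$x[keep],
             y = co$y[keep], base = px$base[sel][keep],
             stringsAsFactors = FALSE)
}

#' Plot polyX hits and fitted bubble circles for one tile
#'
#' @param x A `bubble_circles` data frame.
#' @param hits Optional polyX hit data frame to underlay.
#' @param ... Passed to [plot()].
#' @export
plot.bubble_circles <- function(x, hits = NULL, ...) {
  xl <- range(c(hits$x, x$cx - x$r, x$cx + x$r), na.rm = TRUE)
  yl <- range(c(hits$y, x$cy - x$r, x$cy + x$r), na.rm = TRUE)
  plot(NA, xlim = xl, ylim = yl, xlab = "x", ylab = "y",
       main = "polyX hits and detected bubbles", ...)
  if (!is.null(hits)) graphics::points(hits$x, hits$y, pch = ".", col = "grey40")
  th <- seq(0, 2 * pi, length.out = 200)
  for (i in seq_len(nrow(x)))
    graphics::lines(x$cx[i] + x$r[i] * cos(th), x$cy[i] + x$r[i] * sin(th),
                    col = "red")
  invisible(x)
}
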