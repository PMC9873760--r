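#' Image segmentation with pluggable backends
#'
#' Segments an image with one of three backends used by the local feature
#' operators:
#' \describe{
#'   \item{`srm`}{statistical region merging. The granularity parameter `q`
#'     starts at `params$q0` and is doubled (up to `params$max_sweeps` sweeps)
#'     until at least `params$min_segments` (default 3) segments are produced.
#'     Useful for extracting the dominant *shapes* of an image.}
#'   \item{`kmeans_lab`}{k-means clustering of the A and B chromaticity
#'     channels of the Lab representation (`params$k` clusters, seeded by
#'     `params$seed`). Segments are colour motifs and need not be spatially
#'     contiguous.}
#'   \item{`graph`}{greedy graph-based region merging on the 4-neighbour pixel
#'     graph (Felzenszwalb-Huttenlocher merge rule). The scale parameter is
#'     swept over a multiplicative grid and the result closest to
#'     `params$target` segments (default 6) is returned.}
#' }
#'
#' Segment labels are 0-based and ordered by pixel count, descending; ties are
#' broken by the smaller mean linear pixel index. Label 0 is always the
#' largest segment.
#'
#' @param image a [raster_image()]
#' @param backend one of `"srm"`, `"kmeans_lab"`, `"graph"`
#' @param params backend settings, see Details.
#' @return An object of class `segmentation`: list with `label_map` (H x W
#'   integer matrix, 0-based), `n_segments`, `sizes` (pixel counts, descending),
#'   `backend`, and `target_not_met` (TRUE when the backend's segment-count
#'   target could not be reached after the parameter sweep).
#' @export
segment_image <- function(image,
                          backend = c("srm", "kmeans_lab", "graph"),
                          params = list()) {
  stopifnot(inherits(image, "raster_image"))
  backend <- match.arg(backend)
  res <- switch(backend,
    srm        = segment_srm(image, params),
    kmeans_lab = segment_kmeans_lab(image, params),
    graph      = segment_graph(image, params)
  )
  lab <- order_segment_labels(res$labels, image$height, image$width)
  structure(list(label_map = lab$label_map,
                 n_segments = lab$n_segments,
                 sizes = lab$sizes,
                 backend = backend,
                 target_not_met = isTRUE(res$target_not_met)),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation: %d segments, backend=%s%s>\n", x$n_segments,
              x$backend, if (x$target_not_met) ", target not met" else ""))
  invisible(x)
}

# Relabel an integer component vector (length H*W, column-major) so that
# label 0 is the largest segment; ties broken by smaller mean pixel index.
order_segment_labels <- function(labels, h, w) {
  labels <- as.integer(factor(labels))
  counts <- tabulate(labels)
  mean_idx <- vapply(seq_along(counts),
                     function(l) mean(which(labels == l)), numeric(1))
  ord <- order(-counts, mean_idx)
  new_label <- integer(length(counts))
  new_label[ord] <- seq_along(ord) - 1L
  list(label_map = matrix(new_label[labels], h, w),
       n_segments = length(counts),
       sizes = counts[ord])
}

# 4-neighbour edge list for an h x w grid, column-major linear indices.
grid_edges <- function(h, w) {
  idx <- matrix(seq_len(h * w), h, w)
  rbind(cbind(as.vector(idx[-h, ]), as.vector(idx[-1, ])),   # down
        cbind(as.vector(idx[, -w]), as.vector(idx[, -1])))   # right
}

# -- SRM ----------------------------------------------------------------------

segment_srm <- function(image, params) {
  q0 <- params$q0 %||% 1
  max_sweeps <- params$max_sweeps %||% 32L
  min_segments <- params$min_segments %||% 3L

  h <- image$height; w <- image$width; n <- h * w
  ch <- matrix(image$pixels, nrow = n) * 255  # n x 3, 0-255 scale
  edges <- grid_edges(h, w)
  dw <- pmax(abs(ch[edges[, 1], 1] - ch[edges[, 2], 1]),
             abs(ch[edges[, 1], 2] - ch[edges[, 2], 2]),
             abs(ch[edges[, 1], 3] - ch[edges[, 2], 3]))
  eord <- order(dw)
  e1 <- edges[eord, 1]; e2 <- edges[eord, 2]
  log_term <- log(2) + 2 * log(6 * n)  # ln(2/delta), delta = 1/(6 n^2)
  g2 <- 256^2

  parent <- integer(n)
  find <- function(i) {   # union-find with path halving
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  q <- q0
  for (sweep in seq_len(max_sweeps)) {
    parent <- seq_len(n)
    size <- rep(1L, n)
    sums <- ch
    bfac <- g2 * log_term / (2 * q)
    for (k in seq_along(e1)) {
      r1 <- find(e1[k]); r2 <- find(e2[k])
      if (r1 == r2) next
      b2 <- bfac / size[r1] + bfac / size[r2]
      d <- sums[r1, ] / size[r1] - sums[r2, ] / size[r2]
      if (max(d * d) <= b2) {
        parent[r2] <- r1
        size[r1] <- size[r1] + size[r2]
        sums[r1, ] <- sums[r1, ] + sums[r2, ]
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    n_seg <- length(unique(roots))
    if (n_seg >= min_segments)
      return(list(labels = roots, target_not_met = FALSE))
    q <- q * 2
  }
  list(labels = roots, target_not_met = TRUE)
}

# -- k-means on Lab A/B channels ----------------------------------------------

segment_kmeans_lab <- function(image, params) {
  k <- params$k %||% 3L
  seed <- params$seed %||% 1L
  if (k < 2L) stop("kmeans_lab requires k >= 2")
  lab <- rgb_to_lab_mat(image$pixels)[, 2:3, drop = FALSE]
  n_distinct <- nrow(unique(round(lab, 6)))
  target_not_met <- FALSE
  if (n_distinct < k) {
    k <- max(1L, n_distinct)
    target_not_met <- TRUE
  }
  if (k == 1L) return(list(labels = rep(1L, nrow(lab)),
                           target_not_met = TRUE))
  cl <- withr_seed(seed, stats::kmeans(lab, centers = k, nstart = 5,
                                       iter.max = 50))
  list(labels = cl$cluster, target_not_met = target_not_met)
}

# -- graph-based merging (Felzenszwalb-Huttenlocher rule) ---------------------

segment_graph <- function(image, params) {
  target <- params$target %||% 6L
  scales <- params$scales %||% (255 * 2^seq(-8, 8))
  h <- image$height; w <- image$width; n <- h * w
  ch <- matrix(image$pixels, nrow = n) * 255
  edges <- grid_edges(h, w)
  dwt <- sqrt((ch[edges[, 1], 1] - ch[edges[, 2], 1])^2 +
              (ch[edges[, 1], 2] - ch[edges[, 2], 2])^2 +
              (ch[edges[, 1], 3] - ch[edges[, 2], 3])^2)
  eord <- order(dwt)
  e1 <- edges[eord, 1]; e2 <- edges[eord, 2]; ew <- dwt[eord]

  run_fh <- function(k_scale) {
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    size <- rep(1L, n)
    internal <- rep(0, n)   # max internal edge weight per component root
    for (k in seq_along(e1)) {
      r1 <- find(e1[k]); r2 <- find(e2[k])
      if (r1 == r2) next
      if (ew[k] <= min(internal[r1] + k_scale / size[r1],
                       internal[r2] + k_scale / size[r2])) {
        parent[r2] <- r1
        size[r1] <- size[r1] + size[r2]
        internal[r1] <- max(internal[r1], internal[r2], ew[k])
      }
    }
    vapply(seq_len(n), find, integer(1))
  }

  best <- NULL; best_gap <- Inf
  for (s in scales) {
    roots <- run_fh(s)
    n_seg <- length(unique(roots))
    gap <- abs(n_seg - target)
    if (gap < best_gap) { best <- roots; best_gap <- gap }
    if (gap == 0) break
  }
  list(labels = best, target_not_met = best_gap != 0)
}

# -- small utilities ----------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
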