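# Small programmatic fixtures shared across test files.

# solid-colour horizontal bands (rows split 32/16/16 by default)
band_image <- function(heights = c(32, 16, 16), width = 64,
                       colors = list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
  h <- sum(heights)
  px <- array(0, c(h, width, 3))
  r0 <- 0
  for (i in seq_along(heights)) {
    rows <- r0 + seq_len(heights[i])
    for (ch in 1:3) px[rows, , ch] <- colors[[i]][ch]
    r0 <- r0 + heights[i]
  }
  raster_image(px)
}

# two-tone checkerboard
checker_image <- function(n = 16) {
  m <- (row(matrix(0, n, n)) + col(matrix(0, n, n))) %% 2
  px <- array(0, c(n, n, 3))
  px[, , 1] <- m
  px[, , 3] <- 1 - m
  raster_image(px)
}

# four solid quadrants
quadrant_image <- function(n = 48) {
  h <- n / 2
  px <- array(0, c(n, n, 3))
  px[1:h, 1:h, 1] <- 1
  px[1:h, (h + 1):n, 2] <- 1
  px[(h + 1):n, 1:h, 3] <- 1
  px[(h + 1):n, (h + 1):n, ] <- 0.5
  raster_image(px)
}

uniform_image <- function(value = 0.5, n = 32) {
  raster_image(array(value, c(n, n, 3)))
}

# brute-force 4-neighbour connected components on exact colour classes
# (independent oracle for segmentation on images made of solid regions)
cc_oracle <- function(image) {
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  key <- matrix(paste(px[, , 1], px[, , 2], px[, , 3]), h, w)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (lab[i, j] > 0) next
    nxt <- nxt + 1L
    queue <- matrix(c(i, j), ncol = 2)
    lab[i, j] <- nxt
    while (nrow(queue)) {
      p <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] < 1 || q[1] > h || q[2] < 1 || q[2] > w) next
        if (lab[q[1], q[2]] == 0 && key[q[1], q[2]] == key[p[1], p[2]]) {
          lab[q[1], q[2]] <- nxt
          queue <- rbind(queue, q)
        }
      }
    }
  }
  lab
}

# full annotation set for extract_features tests
dummy_annotations <- function() {
  list(concreteness = 0.4, dynamics = -0.2, temperature = 0.1,
       valence = 0.7, presence_person = 1)
}

# small synthetic behavioural cohort with planted LFS structure
lfs_cohort <- function(n_stim = 150, n_low = 12, n_high = 4,
                       n_participants = 5, active_low = 1:4,
                       noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n_stim * (n_low + n_high)), n_stim,
              dimnames = list(NULL, c(paste0("low", seq_len(n_low)),
                                      paste0("high", seq_len(n_high)))))
  level <- c(rep("low", n_low), rep("high", n_high))
  W <- matrix(0, n_low + n_high, n_participants)
  W[active_low, ] <- rnorm(length(active_low) * n_participants, sd = 1)
  Y <- X %*% W + matrix(rnorm(n_stim * n_participants, sd = noise_sd), n_stim)
  list(features = X, level = level, weights = W, ratings = Y)
}
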