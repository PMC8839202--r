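# Shared fixtures: tiny model configurations and independent oracles.

# Two coherent pathways (2^2 = 4^1) at a small input; cheap to build and run.
tiny_config <- function(input = c(16L, 16L), channels = 2L, dropout = 0,
                        seed = 7L) {
  mpunet_config(list(pathway_spec(2, c(3, 4), 5), pathway_spec(4, c(3), 4)),
                input_size = input, input_channels = channels,
                dropout_rate = dropout, seed = seed)
}

# The reference two-pathway configuration (pool 4 / [40, 240] / 240 and
# pool 2 / [40, 80, 160, 220] / 220) at 512x512x3, two classes.
reference_config <- function() {
  mpunet_config(list(pathway_spec(4, c(40, 240), 240),
                     pathway_spec(2, c(40, 80, 160, 220), 220)),
                input_size = c(512L, 512L), input_channels = 3L,
                num_classes = 2L)
}

# Independent connected-component oracle: plain-R breadth-first flood fill.
flood_fill_count <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  offs <- if (connectivity == 4) {
    list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  } else {
    list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
         c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  }
  n <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] == 0 || seen[i, j]) next
    n <- n + 1L
    queue <- list(c(i, j))
    seen[i, j] <- TRUE
    while (length(queue) > 0) {
      cur <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (o in offs) {
        ni <- cur[1] + o[1]; nj <- cur[2] + o[2]
        if (ni >= 1 && nj >= 1 && ni <= h && nj <= w &&
            mask[ni, nj] != 0 && !seen[ni, nj]) {
          seen[ni, nj] <- TRUE
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  n
}

random_soft_map <- function(n = 12) {
  p <- matrix(runif(n * n), n, n)
  t <- matrix(rbinom(n * n, 1, 0.4), n, n)
  list(pred = p, truth = t)
}
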