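# Shared fixtures, memoised per test run. All fixtures are generated in code;
# nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env, inherits = FALSE)) {
    assign(key, force(expr), .fixture_env)
  }
  get(key, .fixture_env, inherits = FALSE)
}

# one small deterministic synthetic leaf
fixture_leaf <- function(seed = 101, ...) {
  dots <- list(...)
  key <- paste0("leaf_", seed, "_",
                paste(names(dots), unlist(dots), sep = "=", collapse = "_"))
  memo(key, generate_leaf(small_leaf_params(seed = seed, ...)))
}

# a filled disk mask
disk_mask <- function(H, W, cr, cc, r) {
  rr <- matrix(seq_len(H), H, W)
  cm <- matrix(seq_len(W), H, W, byrow = TRUE)
  (rr - cr)^2 + (cm - cc)^2 <= r^2
}

# axis-aligned bar mask
bar_mask <- function(H, W, r0, r1, c0, c1) {
  m <- matrix(FALSE, H, W)
  m[r0:r1, c0:c1] <- TRUE
  m
}

# brute-force flood-fill component count (independent oracle)
flood_count <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  nbrs <- if (connectivity == 8) {
    expand.grid(dr = -1:1, dc = -1:1)[-5, ]
  } else {
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  count <- 0
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (!mask[r, c] || seen[r, c]) next
    count <- count + 1
    stack <- list(c(r, c)); seen[r, c] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nbrs))) {
        r2 <- p[1] + nbrs$dr[k]; c2 <- p[2] + nbrs$dc[k]
        if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W &&
            mask[r2, c2] && !seen[r2, c2]) {
          seen[r2, c2] <- TRUE
          stack[[length(stack) + 1]] <- c(r2, c2)
        }
      }
    }
  }
  count
}
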