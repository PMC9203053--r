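# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementation: plain-R enumeration over
# edge-list data frames.

# Random small association network as a raw edge data frame (out-sums <= 1).
random_edge_list <- function(n_nodes, p_edge = 0.5) {
  words <- sprintf("n%02d", seq_len(n_nodes))
  from <- c(); to <- c()
  for (i in seq_len(n_nodes)) {
    for (j in seq_len(n_nodes)) {
      if (i != j && runif(1) < p_edge) {
        from <- c(from, words[i]); to <- c(to, words[j])
      }
    }
  }
  if (length(from) == 0) {
    from <- words[1]; to <- words[2]
  }
  s <- runif(length(from), 0.05, 1)
  for (w in unique(from)) {
    k <- from == w
    tot <- sum(s[k])
    if (tot > 1) s[k] <- s[k] / tot * runif(1, 0.5, 0.999)
  }
  data.frame(source = from, target = to, strength = s)
}

# Minimum summed (1 - AS) weight over all simple paths; cap if unreachable.
oracle_path_length <- function(edges, src, dst, cap = 6) {
  best <- Inf
  recurse <- function(node, total, visited) {
    if (total >= best) return()
    if (node == dst) {
      best <<- total
      return()
    }
    out <- edges[edges$source == node, ]
    for (r in seq_len(nrow(out))) {
      nxt <- out$target[r]
      if (nxt %in% visited) next
      recurse(nxt, total + 1 - out$strength[r], c(visited, nxt))
    }
  }
  recurse(src, 0, src)
  if (!is.finite(best) || best > cap) cap else best
}

# Sum of renormalized-weight products over all directed walks of length
# <= max_steps from src ending at dst (walks may revisit nodes).
oracle_spreading <- function(edges, src, dst, max_steps = 3) {
  norm <- edges
  for (w in unique(edges$source)) {
    k <- norm$source == w
    norm$strength[k] <- norm$strength[k] / sum(norm$strength[k])
  }
  total <- 0
  recurse <- function(node, weight, depth) {
    if (depth > max_steps) return()
    out <- norm[norm$source == node, ]
    for (r in seq_len(nrow(out))) {
      wgt <- weight * out$strength[r]
      if (out$target[r] == dst) total <<- total + wgt
      recurse(out$target[r], wgt, depth + 1)
    }
  }
  recurse(src, 1, 1)
  total
}

# Sum over mediators m (not an endpoint) of AS(new -> m) * AS(m -> base).
oracle_mediator <- function(edges, base, new) {
  total <- 0
  step1 <- edges[edges$source == new, ]
  for (r in seq_len(nrow(step1))) {
    m <- step1$target[r]
    if (m %in% c(base, new)) next
    hit <- edges[edges$source == m & edges$target == base, ]
    if (nrow(hit) == 1) total <- total + step1$strength[r] * hit$strength
  }
  total
}

# Benjamini-Hochberg step-up written directly from its definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# A tiny standard simulated dataset for metric tests.
small_dataset <- function(n_subjects = 20, seed = 42,
                          preset = "paper_stylized", ...) {
  pool <- generate_pair_pool(0.03, 0.96, 90, seed = seed)
  stimuli <- build_stimulus_grid(pool, seed = seed)
  params <- preset_params(preset, n_subjects = n_subjects, seed = seed, ...)
  simulate_experiment(params, stimuli)
}
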