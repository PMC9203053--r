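# Semantic-relatedness metrics over association networks and embeddings.

chain_net <- function() {
  assoc_network(data.frame(
    source = c("stripe", "tiger", "lion"),
    target = c("tiger", "lion", "king"),
    strength = c(0.034, 0.308, 0.021)))
}

test_that("association-network invariants are enforced", {
  expect_error(assoc_network(data.frame(source = "a", target = "a",
                                        strength = 0.5)), "Self-loops")
  expect_error(assoc_network(data.frame(source = "a", target = "b",
                                        strength = 1.2)), "\\(0, 1\\]")
  expect_error(assoc_network(data.frame(source = c("a", "a"),
                                        target = c("b", "c"),
                                        strength = c(0.7, 0.6))),
               "sum to at most 1")
  net <- assoc_network(data.frame(source = "Moo ", target = "COW",
                                  strength = 0.96))
  expect_equal(net$words, c("cow", "moo"))
})

test_that("associative-strength lookup matches direction conventions", {
  net <- assoc_network(data.frame(source = "moo", target = "cow",
                                  strength = 0.96))
  expect_equal(as_strength(net, "cow", "moo", "backward"), 0.96)
  expect_equal(as_strength(net, "moo", "cow", "forward"), 0.96)
  expect_equal(as_strength(net, "cow", "moo", "forward"), 0)
  expect_error(as_strength(net, "cow", "dog"), "dog",
               class = "retromem_missing_word")
})

test_that("all ordered lookups on a random network match the edge list", {
  withr::local_seed(7)
  edges <- random_edge_list(5)
  net <- assoc_network(edges)
  words <- net$words
  for (a in words) {
    for (b in setdiff(words, a)) {
      hit <- edges[edges$source == a & edges$target == b, ]
      want <- if (nrow(hit) == 1) hit$strength else 0
      expect_equal(as_strength(net, a, b, "forward"), want)
      expect_equal(as_strength(net, b, a, "backward"), want)
    }
  }
})

test_that("backward mediator strength sums two-step routes", {
  net <- assoc_network(data.frame(
    source = c("tiger", "lion"), target = c("lion", "mane"),
    strength = c(0.5, 0.2)))
  expect_equal(backward_mediator_strength(net, "mane", "tiger"), 0.10)
  # no two-step route in the reverse direction
  expect_equal(backward_mediator_strength(net, "tiger", "mane"), 0)
})

test_that("mediator strength matches exhaustive enumeration and ignores
           off-path edges", {
  withr::local_seed(11)
  for (rep in 1:10) {
    edges <- random_edge_list(6)
    net <- assoc_network(edges)
    words <- net$words
    pick <- sample(words, 2)
    expect_equal(
      backward_mediator_strength(net, pick[1], pick[2]),
      oracle_mediator(edges, pick[1], pick[2]), tolerance = 1e-12)
  }
  # adding an edge not on any two-step path leaves the value unchanged
  edges <- data.frame(source = c("a", "b"), target = c("b", "c"),
                      strength = c(0.4, 0.3))
  with_extra <- rbind(edges, data.frame(source = "d", target = "e",
                                        strength = 0.9))
  expect_equal(
    backward_mediator_strength(assoc_network(with_extra), "c", "a"),
    backward_mediator_strength(assoc_network(edges), "c", "a"))
})

test_that("weighted path length reproduces the three-edge chain value", {
  expect_equal(weighted_path_length(chain_net(), "stripe", "king"), 2.637)
})

test_that("weighted path length caps unreachable and overlong paths", {
  net <- chain_net()
  expect_equal(weighted_path_length(net, "king", "stripe"), 6)
  expect_equal(weighted_path_length(net, "stripe", "king", cap = 2), 2)
  expect_equal(
    weighted_path_length(net, "stripe", "king", cap = 2,
                         clamp_finite = FALSE), 2.637)
})

test_that("weighted path length equals exhaustive simple-path minimum", {
  withr::local_seed(13)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    edges <- random_edge_list(n, p_edge = 0.4)
    net <- assoc_network(edges)
    pick <- sample(net$words, 2)
    expect_equal(
      weighted_path_length(net, pick[1], pick[2]),
      oracle_path_length(edges, pick[1], pick[2]), tolerance = 1e-12)
  }
})

test_that("hop-shortest variant prefers fewer edges", {
  # direct edge is heavy (weight 0.9); two-hop route is lighter (0.2 total)
  net <- assoc_network(data.frame(
    source = c("a", "a", "b"), target = c("c", "b", "c"),
    strength = c(0.1, 0.9, 0.9)))
  expect_equal(weighted_path_length(net, "a", "c", criterion = "weight"),
               0.2)
  expect_equal(weighted_path_length(net, "a", "c", criterion = "hops"),
               0.9)
})

test_that("spreading activation renormalizes and follows walks", {
  net <- assoc_network(data.frame(source = "src", target = "dst",
                                  strength = 0.3))
  expect_equal(spreading_activation(net, "src", "dst"), 1)
  net3 <- assoc_network(data.frame(
    source = c("src", "a", "a", "a", "a"),
    target = c("a", "dst", "x", "y", "z"),
    strength = c(0.4, 0.1, 0.1, 0.1, 0.1)))
  expect_equal(spreading_activation(net3, "src", "dst"), 0.25)
})

test_that("spreading activation matches brute-force walk enumeration", {
  withr::local_seed(17)
  for (rep in 1:20) {
    edges <- random_edge_list(6, p_edge = 0.5)
    net <- assoc_network(edges)
    pick <- sample(net$words, 2)
    expect_equal(
      spreading_activation(net, pick[1], pick[2], max_steps = 3),
      oracle_spreading(edges, pick[1], pick[2], max_steps = 3),
      tolerance = 1e-12)
  }
})

test_that("per-step outflow of renormalized weights is conserved", {
  withr::local_seed(19)
  edges <- random_edge_list(7, p_edge = 0.6)
  net <- assoc_network(edges)
  P <- retromem:::renormalize_rows(net$adjacency)
  rs <- Matrix::rowSums(P)
  has_out <- net$words %in% edges$source
  expect_equal(unname(rs[has_out]), rep(1, sum(has_out)), tolerance = 1e-12)
  expect_equal(unname(rs[!has_out]), rep(0, sum(!has_out)))
})

test_that("cosine similarity behaves on identity, orthogonality, and a
           hand-computed case", {
  vecs <- embedding_table(rbind(a = c(1, 2, 3), b = c(4, 5, 6),
                                e1 = c(1, 0, 0), e2 = c(0, 1, 0)))
  expect_equal(cosine_similarity(vecs, "a", "a"), 1)
  expect_equal(cosine_similarity(vecs, "e1", "e2"), 0)
  expect_equal(cosine_similarity(vecs, "a", "b"),
               32 / (sqrt(14) * sqrt(77)))
  expect_equal(cosine_similarity(vecs, "a", "b"),
               cosine_similarity(vecs, "b", "a"))
  expect_error(embedding_table(rbind(z = c(0, 0, 0))), "Zero-norm")
  expect_error(cosine_similarity(vecs, "a", "zz"), "zz")
})

test_that("norms and embeddings round-trip through their text formats", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# free association norms", "Moo\tCow\t0.96",
               "tiger\tlion\t0.308"), tf)
  net <- read_association_norms(tf)
  expect_equal(as_strength(net, "cow", "moo", "backward"), 0.96)

  ef <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2 3", "king 0.1 0.2 0.3", "crown 0.3 0.2 0.1"), ef)
  vecs <- read_embeddings(ef)
  expect_equal(ncol(vecs$vectors), 3)
  expect_equal(sort(vecs$words), c("crown", "king"))
  # same file without the header line parses identically
  ef2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("king 0.1 0.2 0.3", "crown 0.3 0.2 0.1"), ef2)
  expect_equal(read_embeddings(ef2)$vectors, vecs$vectors)
})

test_that("relatedness profiles agree with single-metric calls and flag
           missingness instead of zeroing", {
  withr::local_seed(23)
  edges <- random_edge_list(8, p_edge = 0.4)
  net <- assoc_network(edges)
  vecs <- embedding_table(matrix(rnorm(8 * 4), 8,
                                 dimnames = list(net$words, NULL)))
  pairs <- tibble::tibble(
    word_a = sample(net$words, 10, replace = TRUE),
    word_b = sample(net$words, 10, replace = TRUE))
  pairs <- pairs[pairs$word_a != pairs$word_b, ]
  prof <- relatedness_profile(pairs, network = net, vecs = vecs)
  for (i in seq_len(nrow(prof))) {
    a <- prof$word_a[i]; b <- prof$word_b[i]
    expect_equal(prof$as_backward[i], as_strength(net, a, b, "backward"))
    expect_equal(prof$as_forward[i], as_strength(net, a, b, "forward"))
    expect_equal(prof$mediator_strength[i],
                 backward_mediator_strength(net, a, b))
    expect_equal(prof$weighted_path_length[i],
                 weighted_path_length(net, b, a))
    expect_equal(prof$spreading_activation[i],
                 spreading_activation(net, b, a))
    expect_equal(prof$cosine[i], cosine_similarity(vecs, a, b))
  }
  # a word outside the embedding table: cosine missing, network fields kept
  part <- relatedness_profile(
    tibble::tibble(word_a = "stripe", word_b = "tiger"),
    network = chain_net(), vecs = vecs)
  expect_true(is.na(part$cosine))
  expect_false(is.na(part$as_forward))
})
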