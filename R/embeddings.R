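#' Word-embedding table
#'
#' Holds pretrained word vectors of a fixed dimension, as consumed for cosine
#' similarity. Zero-norm vectors are rejected because they have no direction.
#'
#' @param vectors A numeric matrix with one row per word, or a data frame
#'   whose first column is the word and remaining columns the coordinates.
#' @param words Character vector of words (required when `vectors` is a bare
#'   matrix without rownames).
#' @return An object of class `embedding_table`.
#' @export
embedding_table <- function(vectors, words = NULL) {
  if (is.data.frame(vectors)) {
    words <- as.character(vectors[[1]])
    vectors <- as.matrix(vectors[-1])
  }
  if (is.null(words)) words <- rownames(vectors)
  if (is.null(words)) abort("Words are required (argument or rownames).")
  words <- fold_word(words)
  if (anyDuplicated(words)) abort("Duplicate words in embedding table.")
  vectors <- matrix(as.numeric(vectors), nrow = length(words),
                    dimnames = list(words, NULL))
  if (any(!is.finite(vectors))) abort("Embedding vectors must be finite.")
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms == 0)) {
    abort(sprintf("Zero-norm vector(s): %s.",
                  paste(sQuote(words[norms == 0]), collapse = ", ")))
  }
  structure(list(vectors = vectors, norms = norms, words = words),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table: %d words, dimension %d>\n",
              length(x$words), ncol(x$vectors)))
  invisible(x)
}

#' Read word vectors from word-per-line text
#'
#' The de-facto pretrained-vector text dialect: one word per line followed by
#' space-separated floats. An optional first header line `n d` (two integers)
#' is auto-detected and skipped.
#'
#' @param path Path to the text file.
#' @return An [embedding_table()].
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("Empty embedding file.")
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(first) == 2 && !anyNA(suppressWarnings(as.integer(first)))) {
    lines <- lines[-1]
  }
  parts <- strsplit(trimws(lines), "\\s+")
  words <- vapply(parts, `[[`, character(1), 1L)
  vals <- lapply(parts, function(p) as.numeric(p[-1]))
  d <- unique(lengths(vals))
  if (length(d) != 1) abort("All embedding vectors must share one dimension.")
  embedding_table(do.call(rbind, vals), words = words)
}

#' Cosine similarity between two embedded words
#'
#' @param vecs An [embedding_table()].
#' @param a,b Single words; both must be present with nonzero norms.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(vecs, a, b) {
  a <- fold_word(a); b <- fold_word(b)
  missing <- setdiff(c(a, b), vecs$words)
  if (length(missing) > 0) {
    abort(sprintf("Word(s) not in the embedding table: %s.",
                  paste(sQuote(missing), collapse = ", ")),
          class = "retromem_missing_word")
  }
  va <- vecs$vectors[a, ]; vb <- vecs$vectors[b, ]
  val <- sum(va * vb) / (vecs$norms[[a]] * vecs$norms[[b]])
  min(1, max(-1, val))
}

#' Full relatedness profile for word pairs
#'
#' Bundles the network- and embedding-based relatedness metrics for each pair
#' `(word_a, word_b)`, where `word_a` plays the base-list role and `word_b`
#' the secondary-list role: backward AS (`b -> a`), forward AS (`a -> b`),
#' backward mediator strength, weighted path length (`b` to `a`), spreading
#' activation (`b` to `a`), and embedding cosine. Pairs missing from a
#' resource get `NA` in the affected fields rather than zero, and no error is
#' raised.
#'
#' @param pairs Data frame with columns `word_a`, `word_b`.
#' @param network An [assoc_network()] or `NULL`.
#' @param vecs An [embedding_table()] or `NULL`.
#' @param cap,max_steps Passed to [weighted_path_length()] and
#'   [spreading_activation()].
#' @return A tibble with one row per pair and one column per metric.
#' @export
relatedness_profile <- function(pairs, network = NULL, vecs = NULL,
                                cap = 6, max_steps = 3) {
  pairs <- as_tibble(pairs)
  stopifnot(all(c("word_a", "word_b") %in% names(pairs)))
  a <- fold_word(pairs$word_a); b <- fold_word(pairs$word_b)
  n <- length(a)
  na_col <- rep(NA_real_, n)
  out <- tibble(word_a = a, word_b = b,
                as_backward = na_col, as_forward = na_col,
                mediator_strength = na_col, weighted_path_length = na_col,
                spreading_activation = na_col, cosine = na_col)
  if (!is.null(network)) {
    known <- a %in% network$words & b %in% network$words
    for (i in which(known)) {
      out$as_backward[i] <- as_strength(network, a[i], b[i], "backward")
      out$as_forward[i] <- as_strength(network, a[i], b[i], "forward")
      out$mediator_strength[i] <-
        backward_mediator_strength(network, base = a[i], new = b[i])
      out$weighted_path_length[i] <-
        weighted_path_length(network, src = b[i], dst = a[i], cap = cap)
      out$spreading_activation[i] <-
        spreading_activation(network, src = b[i], dst = a[i],
                             max_steps = max_steps)
    }
  }
  if (!is.null(vecs)) {
    known <- a %in% vecs$words & b %in% vecs$words
    for (i in which(known)) {
      out$cosine[i] <- cosine_similarity(vecs, a[i], b[i])
    }
  }
  out
}
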