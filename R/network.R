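#' Free-association network
#'
#' An `assoc_network` is a directed, weighted graph over words in which the
#' weight of an edge `a -> b` is the associative strength (AS): the empirical
#' probability that `b` is produced in free association to `a`. AS values are
#' therefore constrained to (0, 1], self-loops are disallowed, and the total
#' outgoing strength of any word cannot exceed 1 (up to rounding slack).
#'
#' @param edges A data frame with columns `source`, `target`, `strength`
#'   (extra columns are ignored). Words are case-folded and trimmed.
#' @param tol Numeric slack allowed on the outgoing-strength sum constraint.
#' @return An object of class `assoc_network`: the validated edge list (a
#'   tibble), the word vocabulary, and a sparse adjacency matrix.
#' @examples
#' net <- assoc_network(data.frame(
#'   source = c("moo", "tiger"), target = c("cow", "lion"),
#'   strength = c(0.96, 0.31)))
#' as_strength(net, "cow", "moo", direction = "backward")
#' @export
assoc_network <- function(edges, tol = 1e-8) {
  edges <- as_tibble(edges)
  req <- c("source", "target", "strength")
  if (!all(req %in% names(edges))) {
    abort("`edges` needs columns `source`, `target`, `strength`.")
  }
  edges <- dplyr::transmute(
    edges,
    source = fold_word(.data$source),
    target = fold_word(.data$target),
    strength = as.numeric(.data$strength)
  )
  if (any(!is.finite(edges$strength)) ||
      any(edges$strength <= 0) || any(edges$strength > 1)) {
    abort("All associative strengths must lie in (0, 1].")
  }
  if (any(edges$source == edges$target)) {
    abort("Self-loops are not allowed in an association network.")
  }
  dup <- duplicated(edges[c("source", "target")])
  if (any(dup)) abort("Duplicate edges in the association network.")
  out_sums <- tapply(edges$strength, edges$source, sum)
  if (any(out_sums > 1 + tol)) {
    bad <- names(out_sums)[which.max(out_sums)]
    abort(sprintf(
      "Outgoing strengths must sum to at most 1 per word ('%s' sums to %.4f).",
      bad, max(out_sums)))
  }
  words <- sort(unique(c(edges$source, edges$target)))
  idx <- setNames(seq_along(words), words)
  adj <- Matrix::sparseMatrix(
    i = idx[edges$source], j = idx[edges$target], x = edges$strength,
    dims = c(length(words), length(words)), dimnames = list(words, words))
  structure(
    list(edges = edges, words = words, adjacency = adj),
    class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("<assoc_network: %d words, %d edges>\n",
              length(x$words), nrow(x$edges)))
  invisible(x)
}

#' Read free-association norms from a tab-separated edge list
#'
#' Expects three columns `source<TAB>target<TAB>strength`, UTF-8, with `#`
#' comment lines; words are case-folded to lower.
#'
#' @param path Path to the TSV file.
#' @inheritParams assoc_network
#' @return An [assoc_network()].
#' @export
read_association_norms <- function(path, tol = 1e-8) {
  tab <- readr::read_tsv(
    path, comment = "#", col_names = c("source", "target", "strength"),
    col_types = readr::cols(
      source = readr::col_character(),
      target = readr::col_character(),
      strength = readr::col_double()),
    progress = FALSE)
  assoc_network(tab, tol = tol)
}

check_words <- function(network, words) {
  words <- fold_word(words)
  missing <- setdiff(unique(words), network$words)
  if (length(missing) > 0) {
    abort(sprintf("Word(s) not in the association network: %s.",
                  paste(sQuote(missing), collapse = ", ")),
          class = "retromem_missing_word")
  }
  words
}

#' Associative strength between two words
#'
#' Looks up the directed AS edge between two words. With
#' `direction = "forward"` the value is the weight of `a -> b`; with
#' `direction = "backward"` (the default used in the main analyses, where `a`
#' is the base-list word and `b` the secondary-list word) it is the weight of
#' `b -> a`. Absent edges have strength 0; unknown words are an error.
#'
#' @param network An [assoc_network()].
#' @param a,b Word(s); vectors are matched elementwise.
#' @param direction `"backward"` or `"forward"`.
#' @return Numeric vector of strengths in `[0, 1]`.
#' @export
as_strength <- function(network, a, b, direction = c("backward", "forward")) {
  direction <- match.arg(direction)
  stopifnot(length(a) == length(b))
  a <- check_words(network, a)
  b <- check_words(network, b)
  if (direction == "forward") {
    out <- network$adjacency[cbind(a, b)]
  } else {
    out <- network$adjacency[cbind(b, a)]
  }
  as.numeric(out)
}

#' Backward mediator strength
#'
#' Cumulative strength of all two-step associative routes from a secondary
#' word back to its base word through a mediator: the sum over mediators `m`
#' of `AS(new -> m) * AS(m -> base)`. The direct edge does not contribute,
#' and mediators equal to either endpoint are excluded.
#'
#' @param network An [assoc_network()].
#' @param base,new Single words (base-list word, secondary-list word).
#' @param aggregate `"sum"` (cumulative strength, default) or `"max"` (the
#'   single strongest mediated route).
#' @return Non-negative scalar.
#' @export
backward_mediator_strength <- function(network, base, new,
                                       aggregate = c("sum", "max")) {
  aggregate <- match.arg(aggregate)
  base <- check_words(network, base)
  new <- check_words(network, new)
  out_new <- network$adjacency[new, ]
  into_base <- network$adjacency[, base]
  contrib <- as.numeric(out_new) * as.numeric(into_base)
  keep <- !(network$words %in% c(base, new))
  contrib <- contrib[keep]
  if (length(contrib) == 0) return(0)
  if (aggregate == "sum") sum(contrib) else max(contrib, 0)
}

#' Weighted semantic path length
#'
#' Shortest-path distance from `src` to `dst` in the association network where
#' each edge carries weight `1 - AS`. Unreachable pairs, and paths whose
#' minimum exceeds `cap`, are reported as `cap` (the clamp for finite but very
#' long paths can be disabled).
#'
#' @param network An [assoc_network()].
#' @param src,dst Single words.
#' @param cap Upper clamp for unreachable / very long paths (default 6).
#' @param criterion `"weight"` minimizes the summed `1 - AS` weights
#'   (Dijkstra); `"hops"` first minimizes the number of edges and, among
#'   minimum-hop paths, the summed weights.
#' @param clamp_finite If `TRUE` (default) finite lengths above `cap` are also
#'   reported as `cap`.
#' @return Scalar in `[0, cap]`.
#' @examples
#' net <- assoc_network(data.frame(
#'   source = c("stripe", "tiger", "lion"),
#'   target = c("tiger", "lion", "king"),
#'   strength = c(0.034, 0.308, 0.021)))
#' weighted_path_length(net, "stripe", "king")  # 2.637
#' @export
weighted_path_length <- function(network, src, dst, cap = 6,
                                 criterion = c("weight", "hops"),
                                 clamp_finite = TRUE) {
  criterion <- match.arg(criterion)
  assert_scalar_number(cap, "cap", lower = .Machine$double.eps)
  src <- check_words(network, src)
  dst <- check_words(network, dst)
  if (src == dst) return(0)
  g <- igraph::graph_from_data_frame(
    network$edges[c("source", "target")], directed = TRUE,
    vertices = network$words)
  w <- 1 - network$edges$strength
  if (criterion == "hops") {
    # lexicographic (hops, weight): every edge costs n + (1 - AS); since each
    # 1 - AS < n, hop count dominates and weight breaks ties.
    n <- length(network$words)
    d <- igraph::distances(g, v = src, to = dst, mode = "out", weights = w + n)
    d <- as.numeric(d)
    if (is.finite(d)) d <- d - n * floor(d / n + 1e-12)
  } else {
    # Dijkstra is valid: all weights 1 - AS >= 0.
    d <- as.numeric(
      igraph::distances(g, v = src, to = dst, mode = "out", weights = w))
  }
  if (!is.finite(d)) return(cap)
  if (clamp_finite && d > cap) cap else d
}

#' Bounded spreading activation
#'
#' Activation propagated from `src` along the association network for up to
#' `max_steps` steps. Outgoing strengths at every node are first renormalized
#' to sum to 1 (once, statically); a directed walk of length `<= max_steps`
#' ending at `dst` contributes the product of its renormalized weights, and
#' the result is the sum over all such walks (walks may revisit nodes unless
#' `allow_revisits = FALSE`). Nodes with no outgoing edges propagate nothing.
#'
#' @param network An [assoc_network()].
#' @param src,dst Single words.
#' @param max_steps Maximum walk length (default 3).
#' @param allow_revisits If `FALSE`, only node-simple walks contribute
#'   (enumerated explicitly; intended for small graphs).
#' @return Scalar in `[0, max_steps]`; with revisits allowed it is bounded by
#'   1 per step of total outflow, and in practice lies in `[0, 1]` when `dst`
#'   absorbs only part of each step's flow.
#' @export
spreading_activation <- function(network, src, dst, max_steps = 3,
                                 allow_revisits = TRUE) {
  if (!is.numeric(max_steps) || max_steps < 1) {
    abort("`max_steps` must be at least 1.")
  }
  src <- check_words(network, src)
  dst <- check_words(network, dst)
  P <- renormalize_rows(network$adjacency)
  if (allow_revisits) {
    v <- Matrix::t(Matrix::sparseMatrix(
      i = match(src, network$words), j = 1L, x = 1,
      dims = c(length(network$words), 1L)))
    total <- 0
    for (step in seq_len(max_steps)) {
      v <- v %*% P
      total <- total + as.numeric(v[1, match(dst, network$words)])
    }
    return(total)
  }
  # simple-walk variant: depth-limited DFS over distinct-node walks
  words <- network$words
  Pm <- as.matrix(P)
  total <- 0
  recurse <- function(node, weight, visited, depth) {
    if (depth > max_steps) return()
    nbr <- which(Pm[node, ] > 0)
    for (j in nbr) {
      if (words[j] %in% visited) next
      wj <- weight * Pm[node, j]
      if (words[j] == dst) total <<- total + wj
      recurse(j, wj, c(visited, words[j]), depth + 1)
    }
  }
  recurse(match(src, words), 1, src, 1)
  total
}

# Row-stochastic renormalization; zero out-degree rows stay zero.
renormalize_rows <- function(adj) {
  rs <- Matrix::rowSums(adj)
  scale <- ifelse(rs > 0, 1 / rs, 0)
  Matrix::Diagonal(x = scale) %*% adj
}
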