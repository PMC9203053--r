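#' Configuration for surface smoothing and cluster inference
#'
#' @param nx,ny Grid resolution per axis (default 64 x 64 over the observed
#'   span plus a 2% margin).
#' @param s Smoothing parameter of the penalized least-squares smoother,
#'   used as given when supplied (for users who want to quote a raw
#'   smoothing factor directly).
#' @param s_frac When `s` is `NULL`, the equivalent-kernel half-width of the
#'   smoother is set to this fraction of the grid extent (default 0.40, a
#'   smoothing factor of about 40% of the input space, wide enough to cover
#'   the gaps between scattered stimulus pairs).
#' @param robust_iters Robust (bisquare) reweighting iterations (default 3;
#'   0 disables robustness, restoring exact linearity in the data).
#' @param pointwise_alpha One-sided tail probability for the pointwise
#'   above/below thresholds (default 0.01).
#' @param n_permutations Number of label permutations (default 1000; values
#'   below 100 require `allow_few_permutations`).
#' @param threshold_order `"smooth_then_threshold"` (default) takes
#'   cell-wise tail quantiles of the permuted smoothed surfaces, so the
#'   thresholds track the local variance of the smoothed field;
#'   `"threshold_then_smooth"` takes per-cell quantiles of the permuted
#'   binned values and then smooths the two threshold grids (thresholds then
#'   reflect single-pair variability, which is far wider than that of the
#'   smoothed surface, making the test very conservative).
#' @param connectivity Grid-cluster connectivity, 4 or 8 neighbours.
#' @param permutation_scheme How condition labels are scrambled under the
#'   null. `"scramble"` (default) pools the per-pair condition and control
#'   memorability values and randomly reassigns which value fell in which
#'   condition across the whole set, the literal reading of scrambling
#'   condition membership (it requires `m_cond`/`m_control` inputs);
#'   `"sign_flip"` swaps the two condition labels within each pair (a
#'   per-pair sign flip of the difference, which preserves each pair's
#'   marginal values but cannot exceed a `1/2^k` tail probability where only
#'   `k` pairs support a grid region); `"reshuffle"` permutes the difference
#'   values across the pairs' coordinates.
#' @param support_only Restrict cluster formation (true and permuted
#'   surfaces alike) to the data-supported region, i.e. cells within a few
#'   cells of at least one stimulus pair (default `TRUE`); outside support
#'   the surface is pure extrapolation and its exceedances are not evidence.
#' @param margin Fractional margin added to each axis span.
#' @param correct_p Use the (count + 1) / (n + 1) permutation p-value.
#' @param allow_few_permutations Proceed (with a warning) below 100
#'   permutations.
#' @param seed Integer seed for the permutations.
#' @return A `surface_config` list.
#' @export
surface_config <- function(nx = 64, ny = 64, s = NULL, s_frac = 0.40,
                           robust_iters = 3, pointwise_alpha = 0.01,
                           n_permutations = 1000,
                           threshold_order = c("smooth_then_threshold",
                                               "threshold_then_smooth"),
                           connectivity = 4,
                           permutation_scheme = c("scramble", "sign_flip",
                                                  "reshuffle"),
                           support_only = TRUE,
                           margin = 0.02, correct_p = FALSE,
                           allow_few_permutations = FALSE, seed = NULL) {
  threshold_order <- match.arg(threshold_order)
  permutation_scheme <- match.arg(permutation_scheme)
  stopifnot(nx >= 4, ny >= 4, connectivity %in% c(4, 8))
  if (!is.null(s)) assert_scalar_number(s, "s", lower = 1e-12)
  assert_scalar_number(s_frac, "s_frac", lower = 1e-12)
  if (pointwise_alpha <= 0 || pointwise_alpha >= 0.5) {
    abort("`pointwise_alpha` must lie in (0, 0.5).")
  }
  structure(list(
    nx = as.integer(nx), ny = as.integer(ny), s = s, s_frac = s_frac,
    robust_iters = as.integer(robust_iters),
    pointwise_alpha = pointwise_alpha,
    n_permutations = as.integer(n_permutations),
    threshold_order = threshold_order,
    connectivity = as.integer(connectivity),
    permutation_scheme = permutation_scheme,
    support_only = isTRUE(support_only), margin = margin,
    correct_p = correct_p,
    allow_few_permutations = allow_few_permutations, seed = seed),
    class = "surface_config")
}

# ---- penalized least-squares grid smoother -------------------------------
#
# Minimizes ||W^(1/2)(y - z)||^2 + s ||L z||^2 on an nx x ny grid, where L is
# the Neumann (reflecting-boundary) second-difference Laplacian whose
# eigenbasis is the 2-D type-II discrete cosine transform. Missing cells get
# weight 0 and are filled by the penalty. The normal equations
# (W + s L'L) z = W y are solved exactly by a sparse Cholesky factorization;
# for fixed weights the factor is reused across many right-hand sides, which
# is what makes the permutation test cheap.

laplacian_1d <- function(n) {
  if (n == 1) return(Matrix::sparseMatrix(i = 1, j = 1, x = 0))
  d <- c(-1, rep(-2, n - 2), -1)
  Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                     diagonals = list(rep(1, n - 1), d, rep(1, n - 1)),
                     symmetric = FALSE)
}

grid_penalty <- function(nx, ny) {
  Lx <- laplacian_1d(nx)
  Ly <- laplacian_1d(ny)
  L <- Matrix::kronecker(Matrix::Diagonal(ny), Lx) +
    Matrix::kronecker(Ly, Matrix::Diagonal(nx))
  Matrix::crossprod(L)
}

# Returns a solver closure: function(y_vec_times_w) -> z_vec.
make_grid_smoother <- function(w, s, nx, ny, penalty = NULL) {
  if (is.null(penalty)) penalty <- grid_penalty(nx, ny)
  A <- Matrix::Diagonal(x = w) + s * penalty
  fac <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(A), "CsparseMatrix"),
                          LDL = FALSE, perm = TRUE)
  function(wy) as.numeric(Matrix::solve(fac, wy, system = "A"))
}

smooth_grid <- function(y, w, s, robust_iters = 0, penalty = NULL) {
  nx <- nrow(y); ny <- ncol(y)
  yv <- as.numeric(y)
  wv <- as.numeric(w)
  wv[is.na(yv)] <- 0
  yv[is.na(yv)] <- 0
  if (max(wv) <= 0) abort("All weights are zero; nothing to smooth.")
  wv <- wv / max(wv)
  if (is.null(penalty)) penalty <- grid_penalty(nx, ny)
  solver <- make_grid_smoother(wv, s, nx, ny, penalty)
  z <- solver(wv * yv)
  iters <- max(0, robust_iters)
  for (it in seq_len(iters)) {
    r <- yv - z
    r[wv == 0] <- 0
    scale <- 1.4826 * median(abs(r[wv > 0] - median(r[wv > 0])))
    if (!is.finite(scale) || scale <= 0) break
    u <- r / (4.685 * scale)
    rw <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    wr <- wv * rw
    if (max(wr) <= 0) break
    solver <- make_grid_smoother(wr, s, nx, ny, penalty)
    z <- solver(wr * yv)
  }
  matrix(z, nx, ny)
}

# ---- scattered data -> grid ----------------------------------------------

make_grid_axes <- function(x, y, config) {
  span_x <- diff(range(x)); span_y <- diff(range(y))
  if (span_x <= 0 || span_y <= 0) {
    abort("Degenerate span: x and y must each cover a positive range.")
  }
  mx <- config$margin * span_x; my <- config$margin * span_y
  list(x = seq(min(x) - mx, max(x) + mx, length.out = config$nx),
       y = seq(min(y) - my, max(y) + my, length.out = config$ny),
       span = c(span_x * (1 + 2 * config$margin),
                span_y * (1 + 2 * config$margin)))
}

bin_index <- function(v, axis) {
  i <- findInterval(v, axis + c(diff(axis) / 2, Inf))
  pmin(length(axis), i + 1L)
}

# Mean z and count per grid cell; returns list(y = matrix, w = matrix).
bin_to_grid <- function(ix, iy, z, nx, ny) {
  cell <- (iy - 1L) * nx + ix
  sums <- rep(0, nx * ny); counts <- rep(0, nx * ny)
  agg_s <- tapply(z, cell, sum)
  agg_n <- tapply(z, cell, length)
  idx <- as.integer(names(agg_s))
  sums[idx] <- agg_s; counts[idx] <- agg_n
  ymat <- matrix(ifelse(counts > 0, sums / counts, NA_real_), nx, ny)
  list(y = ymat, w = matrix(counts, nx, ny))
}

# Map the half-width fraction to the penalty parameter through the
# smoother's frequency response: the gain 1/(1 + s*lambda^2) falls to 1/2 at
# lambda_c = s^(-1/2) with lambda(theta) = 2 - 2*cos(theta); choosing the
# cutoff so the equivalent kernel half-width is s_frac of the grid extent
# gives s = lambda(pi / h)^-2 with h = s_frac * n cells. An explicit `s`
# bypasses the mapping.
effective_s <- function(config) {
  if (!is.null(config$s)) return(config$s)
  n <- mean(c(config$nx, config$ny))
  h <- max(1, config$s_frac * n)
  (2 - 2 * cos(pi / h))^-2
}

#' Smooth scattered (x, y, z) points onto a surface grid
#'
#' Bins the points to a regular grid (cell value = mean z, cell weight =
#' count) and applies the penalized least-squares smoother described in
#' [surface_config()], filling the inevitable gaps between scattered
#' observations. Robust reweighting down-weights outlying points.
#'
#' @param points Data frame with columns `x`, `y`, `z` (at least 5 points).
#' @param config A [surface_config()].
#' @return A `retro_surface` list: axis vectors `x`, `y`, matrices `z`
#'   (smoothed), `weights` (per-cell data counts), logical `support` (cells
#'   within 3 cells of any datum), and the `s` actually used.
#' @export
smooth_scattered <- function(points, config = surface_config()) {
  points <- as_tibble(points)
  stopifnot(all(c("x", "y", "z") %in% names(points)))
  if (nrow(points) < 5) abort("At least 5 points are required.")
  if (any(!is.finite(points$x)) || any(!is.finite(points$y)) ||
      any(!is.finite(points$z))) {
    abort("`x`, `y` and `z` must be finite.")
  }
  axes <- make_grid_axes(points$x, points$y, config)
  ix <- bin_index(points$x, axes$x)
  iy <- bin_index(points$y, axes$y)
  g <- bin_to_grid(ix, iy, points$z, config$nx, config$ny)
  s <- effective_s(config)
  z <- smooth_grid(g$y, g$w, s, robust_iters = config$robust_iters)
  structure(list(x = axes$x, y = axes$y, z = z, weights = g$w,
                 support = support_mask(g$w), s = s, config = config),
            class = "retro_surface")
}

support_mask <- function(w, radius = 3L) {
  has <- w > 0
  out <- has
  nx <- nrow(w); ny <- ncol(w)
  for (dx in -radius:radius) {
    for (dy in -radius:radius) {
      xs <- pmin(pmax(seq_len(nx) + dx, 1L), nx)
      ys <- pmin(pmax(seq_len(ny) + dy, 1L), ny)
      out <- out | has[xs, ys, drop = FALSE]
    }
  }
  out
}

#' @export
print.retro_surface <- function(x, ...) {
  cat(sprintf("<retro_surface: %d x %d grid, s = %.4g>\n",
              length(x$x), length(x$y), x$s))
  invisible(x)
}

#' Surface grid as a long tibble
#'
#' @param x A `retro_surface` (optionally with thresholds and clusters
#'   attached by [cluster_permutation()]).
#' @param ... Unused.
#' @return Tibble with columns `x`, `y`, `z`, and when available `upper`,
#'   `lower`, `in_cluster`, `cluster_id`, `support`.
#' @method tidy retro_surface
#' @export
tidy.retro_surface <- function(x, ...) {
  xs <- rep(x$x, times = length(x$y))
  ys <- rep(x$y, each = length(x$x))
  zs <- as.numeric(x$z)
  supp <- as.logical(x$support)
  out <- tibble(x = xs, y = ys, z = zs, support = supp)
  for (fld in c("upper", "lower")) {
    if (!is.null(x[[fld]])) out[[fld]] <- as.numeric(x[[fld]])
  }
  if (!is.null(x$cluster_id)) {
    out$cluster_id <- as.integer(x$cluster_id)
    out$in_cluster <- !is.na(out$cluster_id)
  }
  out
}

# ---- cluster labelling ----------------------------------------------------

# Label connected components of a logical matrix; returns integer matrix with
# NA outside and component ids inside, plus component sizes.
label_clusters <- function(mask, connectivity = 4L) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(NA_integer_, nx, ny)
  if (!any(mask)) return(list(labels = lab, sizes = integer(0)))
  idx <- which(mask)
  comp <- 0L
  sizes <- integer(0)
  todo <- rep(FALSE, nx * ny)
  todo[idx] <- TRUE
  offs <- if (connectivity == 4L) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    as.matrix(expand.grid(dx = -1:1, dy = -1:1)[-5, ])
  }
  for (start in idx) {
    if (!todo[start]) next
    comp <- comp + 1L
    queue <- start
    todo[start] <- FALSE
    size <- 0L
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      size <- size + 1L
      lab[cur] <- comp
      cx <- ((cur - 1L) %% nx) + 1L
      cy <- ((cur - 1L) %/% nx) + 1L
      for (k in seq_len(nrow(offs))) {
        nx2 <- cx + offs[k, 1]; ny2 <- cy + offs[k, 2]
        if (nx2 < 1 || nx2 > nx || ny2 < 1 || ny2 > ny) next
        ni <- (ny2 - 1L) * nx + nx2
        if (todo[ni]) {
          todo[ni] <- FALSE
          queue <- c(queue, ni)
        }
      }
    }
    sizes[comp] <- size
  }
  list(labels = lab, sizes = sizes)
}

max_suprathreshold_size <- function(z, upper, lower, connectivity,
                                    mask = NULL) {
  above <- z > upper
  below <- z < lower
  if (!is.null(mask)) {
    above <- above & mask
    below <- below & mask
  }
  max(c(label_clusters(above, connectivity)$sizes,
        label_clusters(below, connectivity)$sizes, 0L))
}

#' Cluster-based permutation test on a smoothed difference surface
#'
#' The true surface is the smoothed per-pair condition-minus-control
#' memorability (or dependence) difference over bivariate (target, cue)
#' relatedness. Each permutation swaps the two condition labels per pair
#' with probability 1/2 (a sign flip of the difference) and re-smooths with
#' identical settings. Pointwise above/below thresholds are the
#' `1 - alpha` / `alpha` tail quantiles of the permuted values (see
#' `threshold_order` in [surface_config()]); suprathreshold clusters of the
#' true surface are scored against the permutation distribution of the
#' maximum suprathreshold cluster size, pooled over both polarities so that
#' "any significant cluster at alpha" has familywise rate about alpha.
#'
#' @param delta_points Data frame with one row per pair: coordinates `x`
#'   (target relatedness), `y` (cue relatedness) and either both condition
#'   values `m_cond`, `m_control`, or a precomputed difference `z`.
#' @param config A [surface_config()]; `seed` fixes the permutations.
#' @return A `retro_clusters` list: `surface` (a `retro_surface` with
#'   `upper`, `lower` and `cluster_id` attached), `clusters` (tibble with
#'   `cluster_id`, `polarity`, `size`, `p`), and `null_max_sizes`.
#' @export
cluster_permutation <- function(delta_points, config = surface_config()) {
  pts <- as_tibble(delta_points)
  stopifnot(all(c("x", "y") %in% names(pts)))
  has_both <- all(c("m_cond", "m_control") %in% names(pts))
  if (has_both) {
    pts$z <- pts$m_cond - pts$m_control
  } else if (!"z" %in% names(pts)) {
    abort("`delta_points` needs `m_cond`/`m_control` or a difference `z`.")
  }
  if (config$permutation_scheme == "scramble" && !has_both) {
    abort(paste("The label-scramble permutation needs both condition",
                "values; supply `m_cond`/`m_control` or choose",
                "permutation_scheme = \'sign_flip\' or \'reshuffle\'."))
  }
  if (config$n_permutations < 100 && !config$allow_few_permutations) {
    abort(paste("Fewer than 100 permutations gives unstable p-values;",
                "set `allow_few_permutations = TRUE` to proceed."))
  }
  if (config$n_permutations < 100 && config$allow_few_permutations) {
    warn("Fewer than 100 permutations: p-values will be coarse.")
  }
  if (!is.null(config$seed)) withr::local_seed(config$seed)

  axes <- make_grid_axes(pts$x, pts$y, config)
  ix <- bin_index(pts$x, axes$x)
  iy <- bin_index(pts$y, axes$y)
  nx <- config$nx; ny <- config$ny
  g <- bin_to_grid(ix, iy, pts$z, nx, ny)
  s <- effective_s(config)
  penalty <- grid_penalty(nx, ny)

  smooth_one <- function(ymat, wmat) {
    smooth_grid(ymat, wmat, s, robust_iters = config$robust_iters,
                penalty = penalty)
  }
  true_z <- smooth_one(g$y, g$w)

  # Weights depend only on the coordinates, which permutations preserve, so
  # with robustness off the Cholesky factor is shared by all permutations.
  reuse <- config$robust_iters == 0
  if (reuse) {
    wv <- as.numeric(g$w); wv <- wv / max(wv)
    solver <- make_grid_smoother(wv, s, nx, ny, penalty)
  }

  B <- config$n_permutations
  n_pair <- nrow(pts)
  perm_surf <- matrix(NA_real_, nx * ny, B)
  perm_binned <- matrix(NA_real_, nx * ny, B)
  for (b in seq_len(B)) {
    zb <- switch(
      config$permutation_scheme,
      scramble = {
        pool <- sample(c(pts$m_cond, pts$m_control))
        pool[seq_len(n_pair)] - pool[n_pair + seq_len(n_pair)]
      },
      sign_flip = pts$z * sample(c(-1, 1), n_pair, replace = TRUE),
      reshuffle = pts$z[sample.int(n_pair)])
    gb <- bin_to_grid(ix, iy, zb, nx, ny)
    perm_binned[, b] <- as.numeric(gb$y)
    perm_surf[, b] <- if (reuse) {
      yv <- as.numeric(gb$y); yv[is.na(yv)] <- 0
      solver(wv * yv)
    } else {
      as.numeric(smooth_one(gb$y, gb$w))
    }
  }

  alpha <- config$pointwise_alpha
  if (config$threshold_order == "smooth_then_threshold") {
    upper <- matrix(apply(perm_surf, 1, quantile, probs = 1 - alpha), nx, ny)
    lower <- matrix(apply(perm_surf, 1, quantile, probs = alpha), nx, ny)
  } else {
    # literal order: threshold the permuted binned values where data exist,
    # then smooth the two threshold grids with the same settings
    has <- g$w > 0
    up_raw <- low_raw <- matrix(NA_real_, nx, ny)
    data_cells <- which(has)
    up_raw[data_cells] <-
      apply(perm_binned[data_cells, , drop = FALSE], 1, quantile,
            probs = 1 - alpha, na.rm = TRUE)
    low_raw[data_cells] <-
      apply(perm_binned[data_cells, , drop = FALSE], 1, quantile,
            probs = alpha, na.rm = TRUE)
    upper <- smooth_one(up_raw, g$w)
    lower <- smooth_one(low_raw, g$w)
  }

  support <- support_mask(g$w)
  mask <- if (config$support_only) support else NULL
  null_max <- vapply(seq_len(B), function(b) {
    zb <- matrix(perm_surf[, b], nx, ny)
    max_suprathreshold_size(zb, upper, lower, config$connectivity, mask)
  }, numeric(1))

  above_cells <- true_z > upper
  below_cells <- true_z < lower
  if (!is.null(mask)) {
    above_cells <- above_cells & mask
    below_cells <- below_cells & mask
  }
  above <- label_clusters(above_cells, config$connectivity)
  below <- label_clusters(below_cells, config$connectivity)
  cluster_id <- above$labels
  offset <- length(above$sizes)
  cluster_id[!is.na(below$labels)] <- below$labels[!is.na(below$labels)] +
    offset
  sizes <- c(above$sizes, below$sizes)
  polarity <- c(rep("above", length(above$sizes)),
                rep("below", length(below$sizes)))
  p_of <- function(k) {
    if (config$correct_p) (sum(null_max >= k) + 1) / (B + 1)
    else sum(null_max >= k) / B
  }
  clusters <- tibble(
    cluster_id = seq_along(sizes), polarity = polarity, size = sizes,
    p = vapply(sizes, p_of, numeric(1)))
  clusters <- dplyr::arrange(clusters, .data$p, dplyr::desc(.data$size))

  surface <- structure(
    list(x = axes$x, y = axes$y, z = true_z, weights = g$w,
         support = support, s = s, config = config,
         upper = upper, lower = lower, cluster_id = cluster_id),
    class = "retro_surface")
  structure(list(surface = surface, clusters = clusters,
                 null_max_sizes = null_max, config = config),
            class = "retro_clusters")
}

#' @export
print.retro_clusters <- function(x, ...) {
  cat(sprintf("<retro_clusters: %d cluster(s), %d permutations>\n",
              nrow(x$clusters), x$config$n_permutations))
  if (nrow(x$clusters) > 0) print(x$clusters, n = 5)
  invisible(x)
}

#' @rdname cluster_permutation
#' @param x A `retro_clusters` object.
#' @method tidy retro_clusters
#' @export
tidy.retro_clusters <- function(x, ...) x$clusters

#' Write a surface (long CSV) and its clusters (JSON)
#'
#' @param clusters A `retro_clusters` result.
#' @param surface_path,clusters_path Output paths.
#' @return Invisibly, the paths.
#' @export
write_surface <- function(clusters, surface_path, clusters_path = NULL) {
  readr::write_csv(tidy(clusters$surface), surface_path, progress = FALSE)
  if (!is.null(clusters_path)) {
    jsonlite::write_json(
      list(clusters = clusters$clusters,
           null_max_sizes = clusters$null_max_sizes),
      clusters_path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(c(surface_path, clusters_path))
}
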