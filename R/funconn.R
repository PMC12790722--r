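#' Lagged pairwise cross-correlation of binned spike counts
#'
#' For every pair of active channels, the correlation index is the
#' maximum over lags `|l| <= max_lag` (in bin steps) of the Pearson
#' correlation between the channels' binned spike-count vectors. Channels
#' with zero-variance counts get correlation 0 with every other channel
#' (and 1 with themselves).
#'
#' @param set A [spike_train_set()].
#' @param bin Count bin width in seconds (default 50 ms).
#' @param max_lag Maximum lag in seconds (default 0.2, i.e. 4 bins).
#' @param min_rate Active-channel threshold in Hz.
#' @param channels Optional explicit channel subset (overrides the
#'   active-channel rule).
#' @return A `correlation_matrix`: list with `channels`, `values`
#'   (symmetric matrix, unit diagonal), `bin`, `max_lag`.
#' @export
pairwise_correlation <- function(set, bin = 0.05, max_lag = 0.2,
                                 min_rate = 0.1, channels = NULL) {
  stopifnot(inherits(set, "spike_train_set"), bin > 0, max_lag >= 0)
  if (is.null(channels))
    channels <- detect_active_channels(mean_firing_rate(set), min_rate)
  channels <- sort(as.integer(channels))
  if (length(channels) < 2L)
    stop("need at least 2 active channels")
  nb <- ceiling(set$duration / bin)
  ev <- set$events
  keep <- ev$channel %in% channels
  bi <- pmin(floor(ev$time[keep] / bin) + 1L, nb)
  ci <- match(ev$channel[keep], channels)
  C <- length(channels)
  X <- matrix(0L, nrow = nb, ncol = C)
  if (any(keep)) {
    tab <- rowsum(rep(1L, length(bi)), (ci - 1L) * nb + bi)
    idx <- as.integer(rownames(tab))
    X[idx] <- tab[, 1L]
  }
  sds <- apply(X, 2L, stats::sd)
  zerovar <- sds == 0
  L <- floor(max_lag / bin)
  best <- matrix(-1, C, C)
  for (l in 0:L) {
    Tn <- nb - l
    if (Tn < 3L) break
    A <- X[seq_len(Tn), , drop = FALSE]
    B <- X[(1L + l):nb, , drop = FALSE]
    M <- suppressWarnings(stats::cor(A, B))   # corr of i(t) with j(t + l)
    M[is.na(M)] <- 0
    best <- pmax(best, M, t(M))
  }
  best[zerovar, ] <- 0
  best[, zerovar] <- 0
  diag(best) <- 1
  dimnames(best) <- list(channels, channels)
  structure(list(channels = channels, values = best,
                 bin = bin, max_lag = max_lag),
            class = "correlation_matrix")
}

#' Functional-connectivity graph from a correlation matrix
#'
#' Links are unordered channel pairs whose correlation index reaches the
#' threshold; nodes are the endpoints of at least one link. Node and link
#' counts are the headline statistics of a functional network.
#'
#' @param matrix A `correlation_matrix` from [pairwise_correlation()].
#' @param threshold Correlation threshold in (0, 1] (default 0.3); see
#'   [surrogate_threshold()] for a significance-based alternative.
#' @return A `functional_graph`: list with `links` (data frame `a`, `b`,
#'   `weight`), `nodes` (channel ids), `n_nodes`, `n_links`, `graph`
#'   (an igraph object), and the construction parameters.
#' @export
build_graph <- function(matrix, threshold = 0.3) {
  stopifnot(inherits(matrix, "correlation_matrix"),
            threshold > 0, threshold <= 1)
  V <- matrix$values
  C <- length(matrix$channels)
  idx <- which(upper.tri(V) & V >= threshold, arr.ind = TRUE)
  links <- data.frame(a = matrix$channels[idx[, 1L]],
                      b = matrix$channels[idx[, 2L]],
                      weight = V[idx])
  links <- links[order(links$a, links$b), , drop = FALSE]
  rownames(links) <- NULL
  nodes <- sort(unique(c(links$a, links$b)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(links$a), to = as.character(links$b),
               weight = links$weight),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes)))
  structure(list(links = links, nodes = nodes,
                 n_nodes = length(nodes), n_links = nrow(links),
                 graph = g,
                 params = list(threshold = threshold, bin = matrix$bin,
                               max_lag = matrix$max_lag)),
            class = "functional_graph")
}

#' @export
print.functional_graph <- function(x, ...) {
  cat(sprintf("<functional_graph> %d nodes, %d links (threshold %g)\n",
              x$n_nodes, x$n_links, x$params$threshold))
  invisible(x)
}

#' Surrogate-based correlation threshold
#'
#' Estimates a significance threshold for [build_graph()] by dithering
#' every spike time with uniform jitter (destroying fine-timescale
#' correlation while preserving rates), recomputing the maximum pairwise
#' correlation of each surrogate, and taking a high quantile of the
#' pooled surrogate correlations.
#'
#' @param set A [spike_train_set()].
#' @param bin,max_lag,min_rate As in [pairwise_correlation()].
#' @param n_surrogates Number of dithered surrogates (default 20).
#' @param dither Uniform jitter half-width in seconds (default 0.1).
#' @param quantile Quantile of the pooled surrogate off-diagonal
#'   correlations (default 0.95).
#' @param seed Integer seed.
#' @return Scalar threshold.
#' @export
surrogate_threshold <- function(set, bin = 0.05, max_lag = 0.2,
                                min_rate = 0.1, n_surrogates = 20,
                                dither = 0.1, quantile = 0.95, seed = NULL) {
  stopifnot(n_surrogates >= 1, dither > 0)
  with_seed(seed, {
    vals <- lapply(seq_len(n_surrogates), function(i) {
      tm <- set$events$time +
        stats::runif(nrow(set$events), -dither, dither)
      tm <- pmin(pmax(tm, 0), set$duration - 1e-9)
      surr <- spike_train_set(set$events$channel, tm, set$duration,
                              set$geometry)
      V <- pairwise_correlation(surr, bin, max_lag, min_rate)$values
      V[upper.tri(V)]
    })
    as.numeric(stats::quantile(unlist(vals), quantile, na.rm = TRUE))
  })
}

#' Compare functional graphs across conditions
#'
#' Node/link accounting before vs after a perturbation (e.g. a synaptic
#' antagonist): per-condition counts, absolute and relative changes, and
#' the gained/lost link sets. Both graphs must have been built with
#' identical parameters.
#'
#' @param pre_graph,post_graph `functional_graph` objects.
#' @return List with `nodes` and `links` count tables (pre, post, delta,
#'   relative change) and data frames `gained`, `lost`.
#' @export
compare_conditions <- function(pre_graph, post_graph) {
  stopifnot(inherits(pre_graph, "functional_graph"),
            inherits(post_graph, "functional_graph"))
  if (!identical(pre_graph$params, post_graph$params))
    stop("graphs were built with different parameters")
  key <- function(g) paste(g$links$a, g$links$b, sep = "-")
  k1 <- key(pre_graph); k2 <- key(post_graph)
  gained <- post_graph$links[!(k2 %in% k1), c("a", "b"), drop = FALSE]
  lost <- pre_graph$links[!(k1 %in% k2), c("a", "b"), drop = FALSE]
  rownames(gained) <- rownames(lost) <- NULL
  count_row <- function(pre, post)
    list(pre = pre, post = post, delta = post - pre,
         relative = if (pre > 0) (post - pre) / pre else NA_real_)
  list(nodes = count_row(pre_graph$n_nodes, post_graph$n_nodes),
       links = count_row(pre_graph$n_links, post_graph$n_links),
       gained = gained, lost = lost)
}

#' Connectivity plot at electrode positions
#'
#' Draws graph nodes at their electrode positions and links coloured by
#' correlation weight; by default only the strongest decile of links is
#' drawn (visualization-only subsampling).
#'
#' @param x A `functional_graph`.
#' @param geometry The [grid_geometry()] of the recording.
#' @param link_fraction Fraction of strongest links to draw (default 0.1).
#' @param ... Unused.
#' @export
plot_functional_graph <- function(x, geometry, link_fraction = 0.1, ...) {
  stopifnot(inherits(x, "functional_graph"))
  pos <- channel_positions(geometry)
  lk <- x$links
  if (nrow(lk) > 0 && link_fraction < 1) {
    keep <- lk$weight >= stats::quantile(lk$weight, 1 - link_fraction)
    lk <- lk[keep, , drop = FALSE]
  }
  graphics::plot(pos$x, pos$y, pch = ".", col = "grey80",
                 xlab = "x (um)", ylab = "y (um)", asp = 1)
  if (nrow(lk)) {
    cols <- grDevices::hcl.colors(100, "viridis")
    wcol <- cols[pmax(1L, ceiling(99 * (lk$weight - min(lk$weight)) /
                                    max(1e-9, diff(range(lk$weight)))) )]
    p1 <- channel_positions(geometry, lk$a)
    p2 <- channel_positions(geometry, lk$b)
    graphics::segments(p1$x, p1$y, p2$x, p2$y, col = wcol)
  }
  np <- channel_positions(geometry, x$nodes)
  graphics::points(np$x, np$y, pch = 16, cex = 0.4, col = "goldenrod")
  invisible(x)
}
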