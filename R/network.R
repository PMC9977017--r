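#' Build the transition network of a trivariate grid at one scale
#'
#' Coarse-grains HR, DC and activity at scale `tau`, rank-normalises, and
#' partitions the 3-D point cloud with the Darbellay-Vajda scheme. Nodes
#' are the occupied leaves; consecutive time points mapping to different
#' cells contribute an undirected edge, and a point staying in its cell
#' marks a self-loop on that node.
#'
#' @param grid a [trivariate_grid]
#' @param tau coarse-graining scale
#' @inheritParams dv_partition
#' @return a `transition_network`: list with `n_nodes`, `edges` (2-column
#'   matrix of node pairs, u < v), `self_loops` (node indices), and
#'   `adjacency` (symmetric 0/1 matrix, diagonal 1 on self-loop nodes)
#' @export
build_transition_network <- function(grid, tau = 1L, min_cell = 8L,
                                     alpha = 0.05) {
  stopifnot(inherits(grid, "trivariate_grid"))
  m <- grid$n %/% tau
  if (m < 50) stop("fewer than 50 coarse-grained samples")
  pts <- cbind(coarse_grain(grid$hr, tau), coarse_grain(grid$dc, tau),
               coarse_grain(grid$act, tau))
  part <- dv_partition(pts, min_cell, alpha)
  cells <- part$assign
  occupied <- sort(unique(cells))
  node <- match(cells, occupied)
  nv <- length(occupied)
  from <- node[-length(node)]
  to <- node[-1]
  self <- sort(unique(from[from == to]))
  ed <- cbind(pmin(from, to), pmax(from, to))[from != to, , drop = FALSE]
  ed <- unique(ed)
  adj <- matrix(0L, nv, nv)
  if (nrow(ed)) {
    adj[ed] <- 1L
    adj[ed[, 2:1, drop = FALSE]] <- 1L
  }
  if (length(self)) diag(adj)[self] <- 1L
  structure(list(n_nodes = nv, edges = ed, self_loops = self,
                 adjacency = adj),
            class = "transition_network")
}

#' @export
print.transition_network <- function(x, ...) {
  cat(sprintf("<transition_network> %d nodes, %d edges, %d self-loops\n",
              x$n_nodes, nrow(x$edges), length(x$self_loops)))
  invisible(x)
}

#' Exact 3- and 4-cycle counts of a simple graph
#'
#' Trace formulas on the adjacency matrix: `loop3 = tr(A^3) / 6` and
#' `loop4 = (tr(A^4) - 2m - 2 sum d_i (d_i - 1)) / 8`.
#'
#' @param adj symmetric 0/1 adjacency matrix with zero diagonal
#' @param k cycle length, 3 or 4
#' @return exact count of k-cycles (as subgraphs)
#' @export
count_cycles <- function(adj, k) {
  if (!k %in% c(3, 4)) stop("k must be 3 or 4")
  A <- adj
  diag(A) <- 0
  A2 <- A %*% A
  if (k == 3) return(as.integer(round(sum(diag(A2 %*% A)) / 6)))
  deg <- rowSums(A)
  m <- sum(A) / 2
  as.integer(round((sum(diag(A2 %*% A2)) - 2 * m -
                      2 * sum(deg * (deg - 1))) / 8))
}

#' Names of the 11 transition-network metrics
#' @return character vector of length 11
#' @export
msnr_metric_names <- function() {
  c("n_nodes", "avg_degree", "n_loops", "loop3", "loop4", "clust1",
    "clust2", "radius", "spectral_radius", "trace", "energy")
}

#' The 11 network-representation metrics of a transition network
#'
#' Degree, cycle and clustering metrics are computed on the simple graph
#' (self-loops excluded); trace, spectral radius and energy use the full
#' adjacency with diagonal 1 on self-loop nodes, so self-transitions are
#' what make the trace non-zero. `n_loops` is the cyclomatic number
#' `|E| - |V| + #components`; `clust1` is LOOP3 divided by the number of
#' connected triples (as defined, without the conventional factor 3);
#' `clust2` is the mean local clustering coefficient (nodes of degree < 2
#' contribute 0); `radius` is the minimum eccentricity on the largest
#' connected component; `energy` is the sum of squared adjacency
#' eigenvalues.
#'
#' @param net a `transition_network`
#' @param transitivity_factor3 if TRUE, multiply `clust1` by the
#'   conventional factor 3 (standard transitivity); default FALSE
#' @return named numeric vector of length 11 (see [msnr_metric_names()])
#' @export
network_metrics <- function(net, transitivity_factor3 = FALSE) {
  stopifnot(inherits(net, "transition_network"))
  if (net$n_nodes < 1) stop("empty graph")
  A <- net$adjacency
  As <- A
  diag(As) <- 0
  g <- igraph::graph_from_adjacency_matrix(As, mode = "undirected")
  deg <- igraph::degree(g)
  m <- igraph::ecount(g)
  ncomp <- igraph::components(g)$no
  loop3 <- count_cycles(As, 3)
  loop4 <- count_cycles(As, 4)
  triples <- sum(deg * (deg - 1) / 2)
  clust1 <- if (triples > 0) loop3 / triples else 0
  if (transitivity_factor3) clust1 <- 3 * clust1
  lc <- igraph::transitivity(g, type = "local", isolates = "zero")
  lc[is.na(lc)] <- 0
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  radius <- if (igraph::vcount(sub) > 1) {
    min(igraph::eccentricity(sub))
  } else 0
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  c(n_nodes = net$n_nodes,
    avg_degree = mean(deg),
    n_loops = m - net$n_nodes + ncomp,
    loop3 = loop3,
    loop4 = loop4,
    clust1 = clust1,
    clust2 = mean(lc),
    radius = radius,
    spectral_radius = max(abs(ev)),
    trace = sum(diag(A)),
    energy = sum(ev^2))
}

#' Multiscale network-representation feature block over an ensemble
#'
#' Per ensemble member: the 11 metrics at each scale. Features are the
#' ensemble sample mean and variance per (metric, scale): 220 features
#' for 11 metrics x 10 scales.
#'
#' @param grids list of gap-free [trivariate_grid] ensemble members
#' @param scales integer scales (default 1:10)
#' @inheritParams dv_partition
#' @return named numeric vector `msnr_<metric>_s<scale>_<mean|var>`,
#'   all means first, then all variances
#' @export
msnr_block <- function(grids, scales = 1:10, min_cell = 8L, alpha = 0.05) {
  if (!length(grids)) stop("ensemble must be non-empty")
  mets <- msnr_metric_names()
  vals <- vapply(grids, function(g) {
    as.vector(vapply(scales, function(tau) {
      network_metrics(build_transition_network(g, tau, min_cell, alpha))
    }, numeric(11)))
  }, numeric(11 * length(scales)))
  vals <- matrix(vals, nrow = 11 * length(scales))
  base <- as.vector(outer(paste0("msnr_", mets),
                          paste0("_s", scales), paste0))
  mu <- rowMeans(vals)
  va <- if (ncol(vals) > 1) apply(vals, 1, var) else rep(0, nrow(vals))
  out <- c(mu, va)
  names(out) <- c(paste0(base, "_mean"), paste0(base, "_var"))
  out
}
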