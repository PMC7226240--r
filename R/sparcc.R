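#' Log-ratio variation matrix
#'
#' The SparCC variation matrix `T`: `t_ij` is the sample variance over runs
#' of `log((x_i + pc) / (x_j + pc))`. It is symmetric with zero diagonal and
#' invariant under per-run rescaling (compositional invariance), which is
#' what makes it usable on closed (relative-abundance) data.
#'
#' @param x a [quant_matrix()] or a numeric proteins x runs matrix with at
#'   least 3 runs and non-negative values.
#' @param pseudocount positive value added to every abundance before taking
#'   logs, protecting zeros; set to 0 only for strictly positive data.
#' @return Symmetric matrix of log-ratio variances.
#' @export
variation_matrix <- function(x, pseudocount = 1) {
  v <- if (inherits(x, "quant_matrix")) x$values else as.matrix(x)
  if (ncol(v) < 3L) stop("need at least 3 runs", call. = FALSE)
  if (any(v < 0)) stop("abundances must be >= 0", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (pseudocount == 0 && any(v == 0)) {
    stop("zero abundances require a positive pseudocount", call. = FALSE)
  }
  lg <- log(v + pseudocount)
  n <- ncol(lg)
  # var(log xi - log xj) = var_i + var_j - 2 cov_ij, via the covariance of
  # the log matrix
  cv <- stats::cov(t(lg))
  d <- diag(cv)
  tmat <- outer(d, d, "+") - 2 * cv
  tmat[tmat < 0] <- 0  # numerical guard
  diag(tmat) <- 0
  dimnames(tmat) <- list(rownames(v), rownames(v))
  tmat
}

#' SparCC basis correlations from a variation matrix
#'
#' Solves the SparCC approximation: under sparsity (most true correlations
#' near zero), the row sums of the variation matrix give a linear system for
#' the basis log-variances `omega_i^2`, from which pairwise correlations are
#' `rho_ij = (omega_i^2 + omega_j^2 - t_ij) / (2 omega_i omega_j)`, clipped
#' to `[-1, 1]`. Strongly correlated pairs violate the sparsity assumption,
#' so the most-correlated pair with `|rho|` above `exclusion_threshold` is
#' iteratively removed from the variance estimation and the system re-solved
#' until no such pair remains or `max_exclusion_iters` is reached; the final
#' correlation matrix is still reported for all pairs.
#'
#' Components whose estimated basis variance turns negative are flagged
#' unreliable: their correlations are set to `NA` with a warning.
#'
#' @param tmat variation matrix from [variation_matrix()], at least 4
#'   components.
#' @param exclusion_threshold `|rho|` above which a pair is excluded from
#'   the basis-variance system (in (0, 1)).
#' @param max_exclusion_iters maximum number of excluded pairs.
#' @return list with `rho` (correlation matrix, unit diagonal), `omega2`
#'   (basis variances), `excluded_pairs` (two-column matrix of indices) and
#'   `unreliable` (component names with negative variance estimates).
#' @export
sparcc_correlations <- function(tmat, exclusion_threshold = 0.1,
                                max_exclusion_iters = 10) {
  d <- nrow(tmat)
  if (d < 4L) stop("need at least 4 components", call. = FALSE)
  if (!(exclusion_threshold > 0 && exclusion_threshold < 1)) {
    stop("exclusion_threshold must be in (0, 1)", call. = FALSE)
  }
  excluded <- matrix(integer(0), ncol = 2)
  include <- matrix(TRUE, d, d)
  diag(include) <- FALSE

  solve_basis <- function(include) {
    m <- include * 1
    diag(m) <- rowSums(include)
    tv <- rowSums(tmat * include)
    as.numeric(solve(m, tv))
  }
  rho_from <- function(omega2) {
    omega2_pos <- pmax(omega2, .Machine$double.eps)
    om <- sqrt(omega2_pos)
    rho <- (outer(omega2_pos, omega2_pos, "+") - tmat) / (2 * outer(om, om))
    rho[rho > 1] <- 1
    rho[rho < -1] <- -1
    diag(rho) <- 1
    rho
  }

  omega2 <- solve_basis(include)
  rho <- rho_from(omega2)
  iter <- 0
  while (iter < max_exclusion_iters) {
    ar <- abs(rho)
    diag(ar) <- 0
    ar[!include] <- 0
    m <- max(ar)
    if (m <= exclusion_threshold) break
    ij <- which(ar == m, arr.ind = TRUE)[1, ]
    include[ij[1], ij[2]] <- FALSE
    include[ij[2], ij[1]] <- FALSE
    excluded <- rbind(excluded, matrix(sort(ij), ncol = 2))
    # a component with too few remaining pairs cannot be estimated
    if (any(rowSums(include) < 2)) {
      include[ij[1], ij[2]] <- TRUE
      include[ij[2], ij[1]] <- TRUE
      excluded <- excluded[-nrow(excluded), , drop = FALSE]
      break
    }
    omega2 <- solve_basis(include)
    rho <- rho_from(omega2)
    iter <- iter + 1
  }

  unreliable <- which(omega2 <= 0)
  if (length(unreliable) > 0L) {
    warning("negative basis variance for component(s) ",
            paste(rownames(tmat)[unreliable], collapse = ", "),
            "; correlations set to NA", call. = FALSE)
    rho[unreliable, ] <- NA_real_
    rho[, unreliable] <- NA_real_
    diag(rho) <- 1
  }
  dimnames(rho) <- dimnames(tmat)
  list(rho = rho, omega2 = stats::setNames(omega2, rownames(tmat)),
       excluded_pairs = excluded,
       unreliable = rownames(tmat)[unreliable])
}

#' SparCC correlations from abundances
#'
#' Convenience wrapper: [variation_matrix()] followed by
#' [sparcc_correlations()].
#'
#' @inheritParams variation_matrix
#' @inheritParams sparcc_correlations
#' @return See [sparcc_correlations()].
#' @export
sparcc <- function(x, pseudocount = 1, exclusion_threshold = 0.1,
                   max_exclusion_iters = 10) {
  sparcc_correlations(variation_matrix(x, pseudocount),
                      exclusion_threshold = exclusion_threshold,
                      max_exclusion_iters = max_exclusion_iters)
}

#' Build the co-occurrence network from a correlation matrix
#'
#' Nodes are proteins; an edge is kept iff `|rho_ij| >= edge_threshold`.
#' The signed correlation is stored as the edge attribute `weight`; shortest
#' paths for centrality use the distance transform `1 - |rho|`. Betweenness
#' centrality is attached as the node attribute `bnc` (isolated nodes score
#' 0).
#'
#' @param rho correlation matrix (symmetric, unit diagonal), e.g.
#'   `sparcc(x)$rho`.
#' @param edge_threshold absolute-correlation cutoff in `[0, 1]`.
#' @param normalized if `TRUE`, betweenness is normalized by the number of
#'   node pairs; default is the raw path count.
#' @return An `igraph` object with node attributes `name`, `bnc` and edge
#'   attributes `weight` (signed rho) and `distance`.
#' @export
build_network <- function(rho, edge_threshold = 0.6, normalized = FALSE) {
  if (!(edge_threshold >= 0 && edge_threshold <= 1)) {
    stop("edge_threshold must be within [0, 1]", call. = FALSE)
  }
  stopifnot(is.matrix(rho), nrow(rho) == ncol(rho))
  adj <- abs(rho) >= edge_threshold
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  if (igraph::ecount(g) > 0) {
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    w <- rho[cbind(ends[, 1], ends[, 2])]
    igraph::E(g)$weight <- w
    igraph::E(g)$distance <- pmax(1 - abs(w), 1e-6)
  }
  igraph::V(g)$bnc <- betweenness_scores(g, normalized = normalized)
  g
}

#' Betweenness centrality on correlation distances
#'
#' Weighted betweenness centrality where the length of an edge is
#' `1 - |rho|` (strong co-occurrence = short distance). Computed with the
#' Brandes algorithm; on an unweighted or empty graph this reduces to the
#' classical pair-count definition (e.g. the center of a 5-node star scores
#' `choose(4, 2) = 6` unnormalized).
#'
#' @param network an `igraph` object; edges may carry a `distance`
#'   attribute (as from [build_network()]), otherwise unit lengths are
#'   used.
#' @param normalized normalize by `(n-1)(n-2)/2`.
#' @return Named numeric vector of scores (0 for isolated nodes).
#' @export
betweenness_scores <- function(network, normalized = FALSE) {
  stopifnot(inherits(network, "igraph"))
  if (igraph::vcount(network) == 0L) return(stats::setNames(numeric(0), character(0)))
  w <- if ("distance" %in% igraph::edge_attr_names(network)) {
    igraph::E(network)$distance
  } else {
    rep(1, igraph::ecount(network))
  }
  b <- igraph::betweenness(network, directed = FALSE, weights = w,
                           normalized = normalized)
  nm <- igraph::V(network)$name
  if (!is.null(nm)) names(b) <- nm
  b
}
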