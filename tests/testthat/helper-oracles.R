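# Independent oracles and small fixture builders shared across tests.

# Tiny quant matrix: p proteins x (2 tissues x 3 times x nbio x ntech runs)
toy_quant <- function(values = NULL, n_proteins = 3, n_bio = 2, n_tech = 1,
                      tissues = "salivary_gland") {
  runs <- expand.grid(tech_rep = seq_len(n_tech), bio_rep = seq_len(n_bio),
                      time = c("T1", "T2", "T3"), tissue = tissues,
                      stringsAsFactors = FALSE)
  runs$extraction <- ifelse(runs$tissue == "cement", "SDS", "native")
  runs$run_id <- sprintf("%s_%s_b%d_t%d", runs$tissue, runs$time,
                         runs$bio_rep, runs$tech_rep)
  if (is.null(values)) {
    values <- matrix(seq_len(n_proteins * nrow(runs)) + 0.0,
                     nrow = n_proteins,
                     dimnames = list(paste0("p", seq_len(n_proteins)),
                                     runs$run_id))
  } else {
    colnames(values) <- runs$run_id
  }
  quant_matrix(values, runs[, c("run_id", "tissue", "extraction", "time",
                                "bio_rep", "tech_rep")])
}

# Brute-force betweenness centrality by enumerating all simple paths.
# dist_mat: symmetric distances, Inf = no edge, diagonal 0.
bnc_enumerate <- function(dist_mat) {
  n <- nrow(dist_mat)
  scores <- numeric(n)
  if (n < 3) return(scores)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      paths <- list()
      lens <- numeric(0)
      dfs <- function(node, visited, len) {
        if (node == t) {
          paths[[length(paths) + 1L]] <<- visited
          lens[length(lens) + 1L] <<- len
          return(invisible(NULL))
        }
        for (nb in which(is.finite(dist_mat[node, ]))) {
          if (nb != node && !(nb %in% visited)) {
            dfs(nb, c(visited, nb), len + dist_mat[node, nb])
          }
        }
      }
      dfs(s, s, 0)
      if (length(lens) == 0L) next
      m <- min(lens)
      shortest <- paths[lens - m < 1e-10]
      for (v in seq_len(n)) {
        through <- vapply(shortest, function(p) {
          v %in% p[-c(1L, length(p))]
        }, TRUE)
        scores[v] <- scores[v] + sum(through) / length(shortest)
      }
    }
  }
  scores
}

# Direct least-squares solve of the SparCC basis system over all pairs
# (the overdetermined system t_ij ~ w_i + w_j solved by QR).
sparcc_lsq_oracle <- function(tmat) {
  d <- nrow(tmat)
  pairs <- t(utils::combn(d, 2))
  a <- matrix(0, nrow(pairs), d)
  a[cbind(seq_len(nrow(pairs)), pairs[, 1])] <- 1
  a[cbind(seq_len(nrow(pairs)), pairs[, 2])] <- 1
  omega2 <- qr.solve(a, tmat[pairs])
  om <- sqrt(pmax(omega2, .Machine$double.eps))
  rho <- (outer(omega2, omega2, "+") - tmat) / (2 * outer(om, om))
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  diag(rho) <- 1
  list(omega2 = omega2, rho = rho)
}

# Compositional samples from a log-normal basis with covariance sigma.
rcomposition <- function(n, sigma, mean_log = 8) {
  d <- nrow(sigma)
  ch <- chol(sigma)
  z <- matrix(stats::rnorm(n * d), ncol = d) %*% ch + mean_log
  w <- exp(z)
  t(w / rowSums(w)) * 1e6
}
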