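#' Global Total Area Sums normalization
#'
#' Rescales every run (column) so that its total equals the grand mean of
#' the raw run totals. Within-run relative proportions are unchanged and the
#' operation is idempotent; the common target constant is arbitrary for all
#' downstream ratio-based analyses and is fixed to the grand mean for
#' reproducibility.
#'
#' @param x a [quant_matrix()] with at least one nonzero value per run.
#' @return The normalized `quant_matrix`.
#' @export
tas_normalize <- function(x) {
  stopifnot(inherits(x, "quant_matrix"))
  totals <- colSums(x$values)
  zero <- which(totals == 0)
  if (length(zero) > 0L) {
    stop("all-zero run(s): ",
         paste(x$runs$run_id[zero], collapse = ", "), call. = FALSE)
  }
  target <- mean(totals)
  x$values <- sweep(x$values, 2, totals / target, "/")
  x
}

#' Pairwise differential representation tests between time points
#'
#' For each protein and each requested comparison, performs a two-sided
#' pooled-variance (Student's) t-test between the normalized abundances at
#' the two time points. By default every run (biological x technical
#' replicate) is an observation; with `replicate_unit = "bio_rep_mean"`
#' technical replicates are averaged per biological replicate first, which
#' is the statistically conservative choice when technical replicates are
#' strongly correlated within a biological replicate.
#'
#' Proteins with fewer than 2 observations in either group, or zero variance
#' in both groups with equal means, are flagged rather than silently
#' dropped: identical groups report `t = 0`, `p = 1`; an untestable group
#' size sets `untestable = TRUE` with `NA` statistics.
#'
#' @param x a normalized [quant_matrix()] (typically one tissue/extraction).
#' @param comparisons character vector among `"T1vT2"`, `"T2vT3"`,
#'   `"T1vT3"`.
#' @param alpha significance level (the study convention is 0.05, unadjusted
#'   across the three comparisons).
#' @param replicate_unit `"run"` or `"bio_rep_mean"`.
#' @param p_adjust if `TRUE`, Benjamini-Hochberg adjust p-values across
#'   proteins within each comparison before applying `alpha` (off by
#'   default, matching the raw p < alpha convention).
#' @return data.frame with columns `protein`, `comparison`, `mean_a`,
#'   `mean_b`, `direction` (`up` if the later time has the larger mean,
#'   `down` if smaller, `flat` if equal), `t_statistic`, `df`, `p_value`,
#'   `significant`, `untestable`.
#' @export
differential_test <- function(x, comparisons = COMPARISONS, alpha = 0.05,
                              replicate_unit = c("run", "bio_rep_mean"),
                              p_adjust = FALSE) {
  stopifnot(inherits(x, "quant_matrix"))
  replicate_unit <- match.arg(replicate_unit)
  comparisons <- match.arg(comparisons, COMPARISONS, several.ok = TRUE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)

  v <- x$values
  runs <- x$runs
  if (replicate_unit == "bio_rep_mean") {
    key <- interaction(runs$time, runs$bio_rep, drop = TRUE)
    agg <- vapply(levels(key), function(k) {
      rowMeans(v[, key == k, drop = FALSE])
    }, numeric(nrow(v)))
    if (nrow(v) == 1L) agg <- matrix(agg, nrow = 1L, dimnames = list(rownames(v), levels(key)))
    time_of <- vapply(strsplit(levels(key), ".", fixed = TRUE), `[`, "", 1L)
    v <- agg
    times <- time_of
  } else {
    times <- as.character(runs$time)
  }

  res <- vector("list", length(comparisons))
  for (ci in seq_along(comparisons)) {
    cmp <- comparisons[ci]
    ta <- substr(cmp, 1, 2)
    tb <- substr(cmp, 4, 5)
    a <- v[, times == ta, drop = FALSE]
    b <- v[, times == tb, drop = FALSE]
    n1 <- ncol(a); n2 <- ncol(b)
    out <- data.frame(
      protein = rownames(v), comparison = cmp,
      mean_a = unname(rowMeans(a)), mean_b = unname(rowMeans(b)),
      direction = NA_character_, t_statistic = NA_real_, df = NA_real_,
      p_value = NA_real_, significant = FALSE, untestable = FALSE,
      stringsAsFactors = FALSE, row.names = NULL
    )
    if (n1 < 2L || n2 < 2L) {
      out$untestable <- TRUE
      res[[ci]] <- out
      next
    }
    s1 <- apply(a, 1, stats::var)
    s2 <- apply(b, 1, stats::var)
    sp2 <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    diff <- out$mean_a - out$mean_b
    t <- ifelse(se == 0, ifelse(diff == 0, 0, sign(diff) * Inf), diff / se)
    df <- n1 + n2 - 2
    p <- 2 * stats::pt(-abs(t), df)
    out$t_statistic <- t
    out$df <- df
    out$p_value <- p
    out$direction <- ifelse(out$mean_b > out$mean_a, "up",
                            ifelse(out$mean_b < out$mean_a, "down", "flat"))
    res[[ci]] <- out
  }
  res <- do.call(rbind, res)
  if (p_adjust) {
    for (cmp in comparisons) {
      i <- res$comparison == cmp & !res$untestable
      res$p_value[i] <- stats::p.adjust(res$p_value[i], method = "BH")
    }
  }
  res$significant <- !res$untestable & !is.na(res$p_value) & res$p_value < alpha
  res
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA from explicit sums of squares.
#' Degenerate inputs are handled explicitly: if both the between- and
#' within-group sums of squares are zero (all observations identical) the
#' result is `F = 0`, `p = 1`; if only the within-group sum is zero the
#' means differ with no residual noise and `F = Inf`, `p = 0`.
#'
#' @param groups list of numeric vectors, one per group; at least 2 groups
#'   with at least 2 values each.
#' @return list with elements `F`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least 2 groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  grand <- mean(values)
  means <- vapply(groups, mean, 0)
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1L
  dfw <- length(values) - length(groups)
  if (ssw == 0 && ssb == 0) {
    return(list(F = 0, p = 1, df_between = dfb, df_within = dfw))
  }
  if (ssw == 0) {
    return(list(F = Inf, p = 0, df_between = dfb, df_within = dfw))
  }
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE),
       df_between = dfb, df_within = dfw)
}
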