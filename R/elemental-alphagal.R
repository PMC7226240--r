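#' Summarize SEM-EDS elemental composition
#'
#' Per element and tissue: mean atomic percent, an abundance class from the
#' stated cutoffs (`high` > 10 atomic %, `low` < 1 atomic %, `mid`
#' otherwise), and a one-way ANOVA across feeding stages T1-T3 (scans as
#' observations). Rarely detected elements -- present in fewer than
#' `rare_min_samples` distinct samples -- are excluded from the analysis
#' and listed separately.
#'
#' @param eds EDS data.frame (see [read_eds_table()]).
#' @param rare_min_samples minimum number of distinct samples an element
#'   must appear in (with nonzero atomic percent) to be analyzed.
#' @param alpha significance level for the ANOVA flag.
#' @return list with `summary` (data.frame: `element`, `tissue`,
#'   `mean_atomic_percent`, `n_scans`, `class`, `F`, `p`, `significant`)
#'   and `excluded` (character vector of rare elements).
#' @export
summarize_elements <- function(eds, rare_min_samples = 2, alpha = 0.05) {
  present <- eds[eds$atomic_percent > 0, , drop = FALSE]
  n_samples <- tapply(present$sample_id, present$element,
                      function(s) length(unique(s)))
  rare <- names(n_samples)[n_samples < rare_min_samples]
  rare <- union(rare, setdiff(unique(eds$element), names(n_samples)))
  keep <- eds[!eds$element %in% rare, , drop = FALSE]

  combos <- unique(keep[, c("element", "tissue")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    el <- combos$element[i]; ti <- combos$tissue[i]
    sub <- keep[keep$element == el & keep$tissue == ti, , drop = FALSE]
    groups <- split(sub$atomic_percent, sub$time)
    groups <- groups[lengths(groups) >= 2L]
    if (length(groups) >= 2L) {
      a <- anova_oneway(groups)
    } else {
      a <- list(F = NA_real_, p = NA_real_)
    }
    m <- mean(sub$atomic_percent)
    data.frame(element = el, tissue = ti, mean_atomic_percent = m,
               n_scans = nrow(sub),
               class = if (m > 10) "high" else if (m < 1) "low" else "mid",
               F = a$F, p = a$p,
               significant = !is.na(a$p) & a$p < alpha,
               stringsAsFactors = FALSE)
  })
  list(summary = do.call(rbind, rows), excluded = sort(rare))
}

#' Spearman correlation between protein and measured atomic composition
#'
#' Rank correlation (average ranks on ties) between a protein group's
#' computed atomic percentages and the measured T1-T3 mean EDS atomic
#' percentages over a shared element panel (default C, N, O, S). Vectors
#' sharing a rank order give exactly `rho = 1`; opposed orders give `-1`.
#'
#' @param protein_percent named atomic-percent vector from sequences (e.g.
#'   summed/mean [atomic_composition()] of a protein group).
#' @param eds_percent named measured atomic-percent vector (e.g. per-element
#'   mean over T1-T3 scans).
#' @param elements element panel; both vectors must cover it.
#' @return list with `rho` and `p` (from [stats::cor.test()] when
#'   computable).
#' @export
correlate_composition <- function(protein_percent, eds_percent,
                                  elements = c("C", "N", "O", "S")) {
  if (length(elements) < 3L) stop("need at least 3 elements", call. = FALSE)
  if (!all(elements %in% names(protein_percent)) ||
      !all(elements %in% names(eds_percent))) {
    stop("both vectors must cover elements: ",
         paste(elements, collapse = ", "), call. = FALSE)
  }
  x <- as.numeric(protein_percent[elements])
  y <- as.numeric(eds_percent[elements])
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Fit the ELISA calibration line
#'
#' Ordinary least-squares line through the (ng, OD) standard pairs, which
#' must include the zero standard. Standards are expected blank-corrected,
#' so the intercept is the residual background. All-equal ODs make the fit
#' degenerate and error out.
#'
#' @param standards data.frame with columns `ng` and `od`.
#' @return list of class `calibration_fit` with `slope` (OD per ng),
#'   `intercept` (OD), `r_squared` and `range` (min/max ng).
#' @export
fit_calibration <- function(standards) {
  if (!all(c("ng", "od") %in% names(standards))) {
    stop("standards must have columns ng, od", call. = FALSE)
  }
  if (nrow(standards) < 3L) stop("need at least 3 standards", call. = FALSE)
  if (!any(standards$ng == 0)) {
    stop("standards must include the 0 ng point", call. = FALSE)
  }
  if (stats::var(standards$od) == 0) {
    stop("degenerate fit: all OD values equal", call. = FALSE)
  }
  fit <- stats::lm(od ~ ng, data = standards)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 range = range(standards$ng)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("calibration_fit: OD = %.4f + %.4f * ng,  R^2 = %.4f\n",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' Quantify alpha-Gal from an ELISA plate
#'
#' Per sample: average the replicate ODs, subtract the mean blank OD,
#' invert the calibration line (`ng = (OD_corrected - intercept) / slope`)
#' and scale to ng alpha-Gal per microgram of coated protein (default
#' coating 100 ng/well, hence a factor of 10). Values driven below zero by
#' noise are floored at 0 and flagged.
#'
#' @param plate ELISA plate data.frame (see [read_elisa_plate()]); must
#'   contain blank wells.
#' @param fit a `calibration_fit` from [fit_calibration()].
#' @param coated_ng protein amount coated per well, in ng.
#' @return data.frame `sample_id`, `mean_od`, `od_corrected`, `ng_per_well`,
#'   `ng_per_ug`, `floored`.
#' @export
quantify_alpha_gal <- function(plate, fit, coated_ng = 100) {
  stopifnot(inherits(fit, "calibration_fit"))
  blanks <- plate$od[plate$role == "blank"]
  if (length(blanks) == 0L) stop("no blank wells on plate", call. = FALSE)
  blank_mean <- mean(blanks)
  samples <- plate[plate$role == "sample", , drop = FALSE]
  if (nrow(samples) == 0L) {
    return(data.frame(sample_id = character(0), mean_od = numeric(0),
                      od_corrected = numeric(0), ng_per_well = numeric(0),
                      ng_per_ug = numeric(0), floored = logical(0)))
  }
  mean_od <- tapply(samples$od, samples$sample_id, mean)
  od_corr <- mean_od - blank_mean
  ng <- (od_corr - fit$intercept) / fit$slope
  floored <- ng < 0
  ng[floored] <- 0
  data.frame(sample_id = names(mean_od),
             mean_od = as.numeric(mean_od),
             od_corrected = as.numeric(od_corr),
             ng_per_well = as.numeric(ng),
             ng_per_ug = as.numeric(ng) * 1000 / coated_ng,
             floored = as.logical(floored),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare alpha-Gal (or other) measurements between groups
#'
#' `mode = "welch_t"` runs all pairwise two-sided Welch t-tests (unequal
#' variances, Welch-Satterthwaite degrees of freedom); `mode = "anova"`
#' runs a one-way ANOVA across all groups (e.g. feeding stages T1-T3).
#' Identical groups report `p = 1` rather than a degenerate statistic.
#'
#' @param values numeric vector of measurements.
#' @param groups group label per measurement (>= 2 values per group).
#' @param mode `"welch_t"` or `"anova"`.
#' @param alpha significance level.
#' @return For `welch_t`: data.frame `group_a`, `group_b`, `t`, `df`, `p`,
#'   `significant`. For `anova`: the [anova_oneway()] list.
#' @export
compare_groups <- function(values, groups, mode = c("welch_t", "anova"),
                           alpha = 0.05) {
  mode <- match.arg(mode)
  split_vals <- split(values, groups)
  if (length(split_vals) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(split_vals) < 2L)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  if (mode == "anova") return(anova_oneway(split_vals))

  gn <- names(split_vals)
  pairs <- utils::combn(gn, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- split_vals[[pairs[1, k]]]
    b <- split_vals[[pairs[2, k]]]
    if (identical(sort(a), sort(b)) && stats::var(a) == 0) {
      return(data.frame(group_a = pairs[1, k], group_b = pairs[2, k],
                        t = 0, df = NA_real_, p = 1, significant = FALSE))
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    data.frame(group_a = pairs[1, k], group_b = pairs[2, k],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, significant = tt$p.value < alpha)
  })
  do.call(rbind, rows)
}
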