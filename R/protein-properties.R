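split_residues <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(chars), c(AA_STANDARD, "X"))
  if (length(bad) > 0L) {
    stop("non-residue character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  chars
}

#' Amino-acid composition (mole percent)
#'
#' Mole percentage of each of the 20 standard residues. Ambiguous `X`
#' residues are excluded from the denominator; their count is returned in
#' the `n_ambiguous` attribute.
#'
#' @param sequence amino-acid sequence (string).
#' @return Named numeric vector over the 20 standard residues summing to
#'   100.
#' @export
aa_composition <- function(sequence) {
  chars <- split_residues(sequence)
  if (length(chars) == 0L) stop("empty sequence", call. = FALSE)
  nx <- sum(chars == "X")
  chars <- chars[chars != "X"]
  if (length(chars) == 0L) stop("sequence contains only X", call. = FALSE)
  counts <- table(factor(chars, levels = AA_STANDARD))
  out <- 100 * as.numeric(counts) / length(chars)
  names(out) <- AA_STANDARD
  attr(out, "n_ambiguous") <- nx
  out
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the defined residues; `X` is skipped
#' with a warning. Always within `[-4.5, 4.5]` and invariant under sequence
#' reversal.
#'
#' @param sequence amino-acid sequence.
#' @return GRAVY score.
#' @export
gravy <- function(sequence) {
  chars <- split_residues(sequence)
  if (length(chars) == 0L) stop("empty sequence", call. = FALSE)
  if (any(chars == "X")) {
    warning("ambiguous residues excluded from GRAVY", call. = FALSE)
    chars <- chars[chars != "X"]
  }
  mean(KD_HYDROPATHY[chars])
}

protein_charge_at_ph <- function(counts, first, last, ph) {
  pos_pk <- c(Nterm = unname(
    if (first %in% names(PKA_NTERM_BY_RESIDUE)) PKA_NTERM_BY_RESIDUE[first]
    else PKA_POSITIVE[["Nterm"]]),
    PKA_POSITIVE[c("K", "R", "H")])
  neg_pk <- c(Cterm = unname(
    if (last %in% names(PKA_CTERM_BY_RESIDUE)) PKA_CTERM_BY_RESIDUE[last]
    else PKA_NEGATIVE[["Cterm"]]),
    PKA_NEGATIVE[c("D", "E", "C", "Y")])
  npos <- c(Nterm = 1, counts[c("K", "R", "H")])
  nneg <- c(Cterm = 1, counts[c("D", "E", "C", "Y")])
  pos <- sum(npos * 10^(pos_pk - ph) / (10^(pos_pk - ph) + 1))
  neg <- sum(nneg * 10^(ph - neg_pk) / (10^(ph - neg_pk) + 1))
  pos - neg
}

#' Theoretical isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge of the termini and the
#' D, E, C, Y, H, K, R side chains crosses zero, found by bisection on
#' `[0, 14]`. Uses the Bjellqvist pKa set (the set behind ExPASy ProtParam),
#' including the residue-dependent terminal pKa exceptions.
#'
#' @param sequence amino-acid sequence.
#' @param tol bisection tolerance in pH units.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence, tol = 1e-4) {
  chars <- split_residues(sequence)
  if (length(chars) == 0L) stop("empty sequence", call. = FALSE)
  counts <- table(factor(chars, levels = c(AA_STANDARD, "X")))
  counts <- stats::setNames(as.numeric(counts), names(counts))
  lo <- 0; hi <- 14
  f <- function(ph) protein_charge_at_ph(counts, chars[1],
                                         chars[length(chars)], ph)
  # net charge is monotone decreasing in pH: positive at 0, negative at 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Instability index
#'
#' Guruprasad dipeptide-weight statistic: `II = (10 / L) * sum(DIWV)` over
#' the `L - 1` ordered adjacent dipeptides. Values above 40 predict an
#' unstable protein in vitro (attached as the `stable` attribute). Unlike
#' GRAVY, the index is order-dependent. Dipeptides containing `X` are
#' skipped.
#'
#' @param sequence amino-acid sequence of length >= 2.
#' @return Instability index with logical attribute `stable` (`II <= 40`).
#' @export
instability_index <- function(sequence) {
  chars <- split_residues(sequence)
  if (length(chars) < 2L) stop("need at least 2 residues", call. = FALSE)
  a <- chars[-length(chars)]
  b <- chars[-1]
  keep <- a != "X" & b != "X"
  ii <- (10 / length(chars)) * sum(DIWV[cbind(a[keep], b[keep])])
  attr(ii, "stable") <- ii <= 40
  ii
}

#' Aliphatic index
#'
#' Relative volume occupied by aliphatic side chains:
#' `AI = X(Ala) + 2.9 X(Val) + 3.9 (X(Ile) + X(Leu))` with `X(.)` the mole
#' percentages. Poly-Ala scores 100, poly-Val 290; residues without an
#' aliphatic side chain contribute 0.
#'
#' @param sequence amino-acid sequence.
#' @return Aliphatic index.
#' @export
aliphatic_index <- function(sequence) {
  comp <- aa_composition(sequence)
  sum(ALIPHATIC_COEF * comp[names(ALIPHATIC_COEF)])
}

#' Atomic composition of a protein chain
#'
#' Sums the free amino-acid molecular formulas and removes `L - 1` waters
#' for the peptide bonds. `X` residues are skipped (warning). Percentages
#' are over the C, H, N, O, S atom counts.
#'
#' @param sequence amino-acid sequence.
#' @return list with `counts` and `percent`, both named over C, H, N, O, S.
#' @export
atomic_composition <- function(sequence) {
  chars <- split_residues(sequence)
  if (length(chars) == 0L) stop("empty sequence", call. = FALSE)
  if (any(chars == "X")) {
    warning("ambiguous residues excluded from atomic composition",
            call. = FALSE)
    chars <- chars[chars != "X"]
  }
  l <- length(chars)
  counts <- colSums(RESIDUE_FORMULA[chars, , drop = FALSE])
  counts <- counts - (l - 1) * c(C = 0, H = 2, N = 0, O = 1, S = 0)
  list(counts = counts, percent = 100 * counts / sum(counts))
}

#' Full physicochemical profile of one sequence
#'
#' @param sequence amino-acid sequence.
#' @return list with `aa_percent`, `pI`, `gravy`, `instability_index`,
#'   `aliphatic_index`, `atomic_counts`, `atomic_percent`.
#' @export
physicochemical_profile <- function(sequence) {
  at <- atomic_composition(sequence)
  list(
    aa_percent = aa_composition(sequence),
    pI = isoelectric_point(sequence),
    gravy = gravy(sequence),
    instability_index = as.numeric(instability_index(sequence)),
    aliphatic_index = aliphatic_index(sequence),
    atomic_counts = at$counts,
    atomic_percent = at$percent
  )
}

#' Amino-acid ratio screen between two groups
#'
#' Flags residues whose group-A / group-B mole-percent ratio falls in
#' either tail: `ratio <= low` or `ratio >= high` (boundaries inclusive).
#' A zero denominator with a nonzero numerator reports an infinite ratio,
#' flagged.
#'
#' @param group_a,group_b named mole-percent vectors over the 20 residues
#'   (e.g. group means of [aa_composition()]).
#' @param low,high tail boundaries of the ratio.
#' @return data.frame `residue`, `ratio`, `flagged`.
#' @export
ratio_screen <- function(group_a, group_b, low = 0.5, high = 1.5) {
  stopifnot(length(group_a) == length(group_b))
  res <- names(group_a)
  ratio <- ifelse(group_b == 0, ifelse(group_a == 0, NA_real_, Inf),
                  group_a / group_b)
  data.frame(residue = res, ratio = ratio,
             flagged = !is.na(ratio) & (ratio <= low | ratio >= high),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-group physicochemical summaries
#'
#' Aggregates sequence properties over comparison groups (e.g. `host`,
#' `tick`, `host_cement`, `tick_cement`). Optionally subsamples a group
#' (the study design subsamples 100 tick sialome-only proteins) with a
#' fixed seed for reproducibility.
#'
#' @param sequences named character vector of sequences.
#' @param groups named character vector or factor: group label per
#'   accession in `sequences`.
#' @param subsample named integer vector, e.g. `c(tick = 100)`: cap on the
#'   number of proteins used per listed group.
#' @param seed RNG seed for the subsample.
#' @return list with `profiles` (per-group mean aa percent, pI, GRAVY,
#'   instability, aliphatic index, atomic percent as a data.frame) and
#'   `aa_percent` (group x residue matrix of mean mole percents).
#' @export
group_property_summary <- function(sequences, groups, subsample = NULL,
                                   seed = 1L) {
  stopifnot(length(sequences) == length(groups))
  groups <- as.character(groups)
  glev <- unique(groups)
  sel <- seq_along(sequences)
  if (!is.null(subsample)) {
    rng <- local({
      set.seed(seed)
      lapply(stats::setNames(nm = names(subsample)), function(g) {
        i <- which(groups == g)
        if (length(i) > subsample[[g]]) sort(sample(i, subsample[[g]])) else i
      })
    })
    drop <- unlist(lapply(names(subsample), function(g) {
      setdiff(which(groups == g), rng[[g]])
    }))
    if (length(drop) > 0) sel <- setdiff(sel, drop)
  }
  sequences <- sequences[sel]
  groups <- groups[sel]

  aa_mat <- matrix(NA_real_, nrow = length(glev), ncol = 20,
                   dimnames = list(glev, AA_STANDARD))
  rows <- lapply(glev, function(g) {
    seqs <- sequences[groups == g]
    if (length(seqs) == 0L) {
      return(data.frame(group = g, n = 0L, pI = NA_real_, gravy = NA_real_,
                        instability = NA_real_, aliphatic = NA_real_))
    }
    profs <- lapply(seqs, physicochemical_profile)
    aa_mat[g, ] <<- rowMeans(vapply(profs, `[[`, numeric(20), "aa_percent"))
    data.frame(
      group = g, n = length(seqs),
      pI = mean(vapply(profs, `[[`, 0, "pI")),
      gravy = mean(vapply(profs, `[[`, 0, "gravy")),
      instability = mean(vapply(profs, `[[`, 0, "instability_index")),
      aliphatic = mean(vapply(profs, `[[`, 0, "aliphatic_index"))
    )
  })
  list(profiles = do.call(rbind, rows), aa_percent = aa_mat)
}
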