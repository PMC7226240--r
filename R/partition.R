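#' Origin/tissue/extraction partition of protein identifications
#'
#' Builds the sialome/cementome set algebra: the cementome is the
#' unique-accession union of the SDS- and urea-extracted cement
#' identifications, and for each origin (tick/host) proteins are counted as
#' sialome-only, cementome-only or shared. Accessions are opaque strings;
#' "unique non-redundant entries" means exact accession equality.
#'
#' @param identifications named list of accession character vectors; names
#'   follow `"tissue.extraction"`, e.g. `salivary_gland.native`,
#'   `cement.SDS`, `cement.urea`. Duplicated accessions within a set are
#'   collapsed.
#' @param annotation data.frame with `accession`, `origin` covering every
#'   identified accession.
#' @return An object of class `partition_summary`: list with `sialome`,
#'   `cementome`, `cement_sds`, `cement_urea` accession sets and a `counts`
#'   data.frame (per origin: `sialome_total`, `cementome_total`,
#'   `sialome_only`, `cementome_only`, `shared`) plus extraction counts.
#' @export
build_partition <- function(identifications, annotation) {
  stopifnot(is.list(identifications))
  tissue_of <- vapply(strsplit(names(identifications), ".", fixed = TRUE),
                      `[`, "", 1L)
  sialome <- unique(unlist(identifications[tissue_of == "salivary_gland"],
                           use.names = FALSE))
  cement_sets <- identifications[tissue_of == "cement"]
  cementome <- unique(unlist(cement_sets, use.names = FALSE))
  sds <- unique(unlist(cement_sets[grepl("\\.SDS$", names(cement_sets))],
                       use.names = FALSE))
  urea <- unique(unlist(cement_sets[grepl("\\.urea$", names(cement_sets))],
                        use.names = FALSE))
  if (is.null(sialome)) sialome <- character(0)
  if (is.null(cementome)) cementome <- character(0)
  if (is.null(sds)) sds <- character(0)
  if (is.null(urea)) urea <- character(0)

  all_acc <- unique(c(sialome, cementome))
  origin <- annotation$origin[match(all_acc, annotation$accession)]
  if (any(is.na(origin))) {
    stop("unannotated accession(s): ",
         paste(utils::head(all_acc[is.na(origin)], 10L), collapse = ", "),
         call. = FALSE)
  }
  names(origin) <- all_acc

  counts <- do.call(rbind, lapply(c("tick", "host"), function(o) {
    s <- sialome[origin[sialome] == o]
    c_ <- cementome[origin[cementome] == o]
    shared <- intersect(s, c_)
    data.frame(origin = o,
               sialome_total = length(s),
               cementome_total = length(c_),
               sialome_only = length(setdiff(s, c_)),
               cementome_only = length(setdiff(c_, s)),
               shared = length(shared),
               stringsAsFactors = FALSE)
  }))

  structure(list(
    sialome = sialome, cementome = cementome,
    cement_sds = sds, cement_urea = urea,
    origin = origin, counts = counts,
    extraction_counts = c(SDS = length(sds), urea = length(urea),
                          union = length(cementome))
  ), class = "partition_summary")
}

#' @export
print.partition_summary <- function(x, ...) {
  cat("partition_summary\n")
  cat("  cementome union (SDS ", x$extraction_counts[["SDS"]], " + urea ",
      x$extraction_counts[["urea"]], ") = ",
      x$extraction_counts[["union"]], " unique accessions\n", sep = "")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Membership of a protein in the tissue partition
#'
#' @param partition a `partition_summary`.
#' @return data.frame `accession`, `origin`, `membership`
#'   (`sialome_only`, `cementome_only`, `shared`).
#' @export
partition_membership <- function(partition) {
  stopifnot(inherits(partition, "partition_summary"))
  acc <- names(partition$origin)
  membership <- ifelse(
    acc %in% partition$sialome & acc %in% partition$cementome, "shared",
    ifelse(acc %in% partition$sialome, "sialome_only", "cementome_only"))
  data.frame(accession = acc, origin = unname(partition$origin),
             membership = membership, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' GO biological-process shares
#'
#' Share of each GO biological-process term within a protein set. The
#' default denominator is the number of (protein, process) annotations in
#' the set (a pie-chart reading: shares sum to 1); `denominator =
#' "proteins"` divides by the number of annotated proteins instead, in
#' which case multi-annotated proteins make shares sum above 1.
#'
#' @param annotation annotation data.frame with `accession` and a
#'   `go_terms` list column.
#' @param proteins accessions defining the analyzed set.
#' @param denominator `"annotations"` or `"proteins"`.
#' @return data.frame `process`, `n`, `share`, sorted by decreasing share.
#' @export
go_process_shares <- function(annotation, proteins,
                              denominator = c("annotations", "proteins")) {
  denominator <- match.arg(denominator)
  ann <- annotation[annotation$accession %in% proteins, , drop = FALSE]
  terms <- unlist(ann$go_terms, use.names = FALSE)
  if (length(terms) == 0L) {
    return(data.frame(process = character(0), n = integer(0),
                      share = numeric(0)))
  }
  tab <- sort(table(terms), decreasing = TRUE)
  denom <- switch(denominator,
                  annotations = sum(tab),
                  proteins = sum(lengths(ann$go_terms) > 0))
  out <- data.frame(process = names(tab), n = as.integer(tab),
                    share = as.numeric(tab) / denom,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Bucket process shares into the top n plus "Other"
#'
#' @param shares data.frame from [go_process_shares()].
#' @param n number of processes displayed individually.
#' @return data.frame of at most `n + 1` rows; the `Other` row carries the
#'   remaining share (`1 - sum(top n)` under the annotations denominator).
#' @export
top_n_with_other <- function(shares, n = 10) {
  if (nrow(shares) <= n) return(shares)
  top <- shares[seq_len(n), , drop = FALSE]
  rest <- shares[-seq_len(n), , drop = FALSE]
  rbind(top, data.frame(process = "Other", n = sum(rest$n),
                        share = sum(rest$share)))
}

#' Score proteins against the key-protein selection criteria
#'
#' Flags, per protein, the four selection criteria used to prioritize
#' cementome proteins: (a) identified in both sialome and cementome; (b)
#' among the `top_k` most abundant proteins of its profile category (mean
#' normalized TAS, non-housekeeping categories only; ties at the boundary
#' are all kept); (c) annotated to a GO biological process holding more
#' than `go_share_threshold` of the annotations in the set; (d) betweenness
#' centrality at or above the `centrality_quantile` of nonzero scores. A
#' missing evidence source skips its criterion with a warning flag rather
#' than silently reporting `FALSE`.
#'
#' @param assignments data.frame from [classify_profiles()].
#' @param partition a `partition_summary` from [build_partition()].
#' @param annotation annotation data.frame with `go_terms`.
#' @param centrality named numeric vector of betweenness scores, or `NULL`.
#' @param quant optional [quant_matrix()] (normalized) used for the
#'   abundance ranking of criterion (b); defaults to equal abundances.
#' @param top_k rank cutoff for criterion (b).
#' @param go_share_threshold share cutoff for criterion (c).
#' @param centrality_quantile quantile cutoff for criterion (d).
#' @return data.frame with one row per protein: the four logical flags,
#'   `criteria_met` (0-4) and `skipped` (criteria without evidence).
#' @export
select_key_proteins <- function(assignments, partition, annotation,
                                centrality = NULL, quant = NULL,
                                top_k = 2, go_share_threshold = 0.04,
                                centrality_quantile = 0.9) {
  proteins <- assignments$protein
  shared_set <- intersect(partition$sialome, partition$cementome)
  shared_flag <- proteins %in% shared_set

  mean_abund <- if (!is.null(quant)) {
    rowMeans(quant$values)[proteins]
  } else {
    stats::setNames(rep(1, length(proteins)), proteins)
  }
  top2_flag <- rep(FALSE, length(proteins))
  for (cat in setdiff(unique(assignments$category), c(NA, "housekeeping"))) {
    i <- which(assignments$category %in% cat)
    ab <- mean_abund[i]
    if (length(ab) == 0L) next
    cutoff <- sort(ab, decreasing = TRUE)[min(top_k, length(ab))]
    top2_flag[i[ab >= cutoff]] <- TRUE
  }

  shares <- go_process_shares(annotation, proteins)
  big_processes <- shares$process[shares$share > go_share_threshold]
  ann <- annotation[match(proteins, annotation$accession), , drop = FALSE]
  go_flag <- vapply(ann$go_terms, function(g) {
    length(g) > 0 && any(g %in% big_processes)
  }, TRUE)

  skipped <- character(0)
  if (is.null(centrality)) {
    centrality_flag <- rep(NA, length(proteins))
    skipped <- c(skipped, "high_network_centrality")
    warning("no centrality table supplied; centrality criterion skipped",
            call. = FALSE)
  } else {
    nonzero <- centrality[centrality > 0]
    cutoff <- if (length(nonzero) > 0) {
      stats::quantile(nonzero, centrality_quantile, names = FALSE)
    } else Inf
    centrality_flag <- !is.na(centrality[proteins]) &
      centrality[proteins] >= cutoff & centrality[proteins] > 0
  }

  flags <- cbind(shared_sialome_cementome = shared_flag,
                 top2_in_profile_category = top2_flag,
                 go_process_share_gt_threshold = go_flag,
                 high_network_centrality = centrality_flag)
  data.frame(protein = proteins, flags,
             criteria_met = rowSums(flags, na.rm = TRUE),
             skipped = paste(skipped, collapse = ";"),
             stringsAsFactors = FALSE, row.names = NULL)
}
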