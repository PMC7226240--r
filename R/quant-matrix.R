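#' Protein quantitation matrix with run metadata
#'
#' A `quant_matrix` holds a protein x run abundance matrix (Total Area Sums
#' units, non-negative) together with the run-level design metadata: tissue
#' (`salivary_gland` or `cement`), extraction buffer (`SDS`, `urea` or
#' `native`), feeding stage (`T1`, `T2`, `T3`), biological replicate and
#' technical replicate.
#'
#' @param values numeric matrix, proteins in rows (rownames = accessions),
#'   runs in columns (colnames = run ids). All values must be finite and
#'   `>= 0`.
#' @param runs data.frame with one row per column of `values` and columns
#'   `run_id`, `tissue`, `extraction`, `time`, `bio_rep`, `tech_rep`.
#' @return An object of class `quant_matrix`.
#' @export
quant_matrix <- function(values, runs) {
  values <- as.matrix(values)
  runs <- as.data.frame(runs, stringsAsFactors = FALSE)
  validate_quant_matrix(structure(list(values = values, runs = runs),
                                  class = "quant_matrix"))
}

validate_quant_matrix <- function(x) {
  stopifnot(inherits(x, "quant_matrix"))
  v <- x$values
  runs <- x$runs
  required <- c("run_id", "tissue", "extraction", "time", "bio_rep", "tech_rep")
  missing_cols <- setdiff(required, names(runs))
  if (length(missing_cols) > 0L) {
    stop("run metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(runs) != ncol(v)) {
    stop("run metadata has ", nrow(runs), " rows but the matrix has ",
         ncol(v), " columns", call. = FALSE)
  }
  if (anyDuplicated(runs$run_id)) {
    stop("duplicated run_id: ",
         paste(unique(runs$run_id[duplicated(runs$run_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(v) > 0L && anyDuplicated(rownames(v))) {
    stop("duplicated protein accession in matrix rows", call. = FALSE)
  }
  if (length(v) > 0L) {
    if (any(!is.finite(v))) stop("abundances must be finite", call. = FALSE)
    if (any(v < 0)) stop("abundances must be >= 0", call. = FALSE)
  }
  bad_time <- setdiff(unique(as.character(runs$time)), TIME_LEVELS)
  if (length(bad_time) > 0L) {
    stop("time labels must be one of ", paste(TIME_LEVELS, collapse = ", "),
         "; found: ", paste(bad_time, collapse = ", "), call. = FALSE)
  }
  if (!is.null(colnames(v)) && !identical(colnames(v), as.character(runs$run_id))) {
    stop("matrix column names must match runs$run_id in order", call. = FALSE)
  }
  colnames(x$values) <- as.character(runs$run_id)
  x
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat("quant_matrix: ", nrow(x$values), " proteins x ", ncol(x$values),
      " runs\n", sep = "")
  if (ncol(x$values) > 0L) {
    cat("  tissues: ", paste(sort(unique(x$runs$tissue)), collapse = ", "),
        "\n  times:   ", paste(sort(unique(x$runs$time)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' Subset a quantitation matrix by run metadata
#'
#' @param x a [quant_matrix()].
#' @param tissue,extraction,time optional character vectors of levels to
#'   keep; `NULL` keeps all.
#' @param proteins optional character vector of accessions to keep.
#' @return A `quant_matrix` restricted to the selected runs/proteins.
#' @export
subset_runs <- function(x, tissue = NULL, extraction = NULL, time = NULL,
                        proteins = NULL) {
  stopifnot(inherits(x, "quant_matrix"))
  keep <- rep(TRUE, nrow(x$runs))
  if (!is.null(tissue)) keep <- keep & x$runs$tissue %in% tissue
  if (!is.null(extraction)) keep <- keep & x$runs$extraction %in% extraction
  if (!is.null(time)) keep <- keep & x$runs$time %in% time
  v <- x$values[, keep, drop = FALSE]
  if (!is.null(proteins)) v <- v[rownames(v) %in% proteins, , drop = FALSE]
  quant_matrix(v, x$runs[keep, , drop = FALSE])
}
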