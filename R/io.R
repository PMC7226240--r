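#' Read and write quantitation matrices
#'
#' The on-disk format is a long-format TSV with one row per (protein, run)
#' cell and columns `protein`, `run_id`, `tissue`, `extraction`, `time`,
#' `bio_rep`, `tech_rep`, `abundance`. The format is self-describing, so
#' `read_quant_matrix(write_quant_matrix(x))` round-trips exactly.
#'
#' Readers validate rather than coerce: a missing metadata column, a
#' duplicated (protein, run) cell or a negative abundance is an error, never
#' silently repaired.
#'
#' @param path file path.
#' @return `read_quant_matrix` returns a [quant_matrix()];
#'   `write_quant_matrix` invisibly returns `path`.
#' @export
read_quant_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("protein", "run_id", "tissue", "extraction", "time",
                "bio_rep", "tech_rep", "abundance")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("quantitation table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df[, c("protein", "run_id")])) {
    stop("duplicated (protein, run) cell in quantitation table", call. = FALSE)
  }
  if (any(!is.finite(df$abundance)) || any(df$abundance < 0)) {
    stop("abundances must be finite and >= 0", call. = FALSE)
  }
  runs <- unique(df[, c("run_id", "tissue", "extraction", "time",
                        "bio_rep", "tech_rep")])
  if (anyDuplicated(runs$run_id)) {
    stop("inconsistent metadata for run_id: ",
         paste(unique(runs$run_id[duplicated(runs$run_id)]), collapse = ", "),
         call. = FALSE)
  }
  runs <- runs[order(match(runs$run_id, unique(df$run_id))), , drop = FALSE]
  rownames(runs) <- NULL
  proteins <- unique(df$protein)
  v <- matrix(0, nrow = length(proteins), ncol = nrow(runs),
              dimnames = list(proteins, runs$run_id))
  v[cbind(match(df$protein, proteins), match(df$run_id, runs$run_id))] <-
    df$abundance
  quant_matrix(v, runs)
}

#' @rdname read_quant_matrix
#' @param x a [quant_matrix()].
#' @export
write_quant_matrix <- function(x, path) {
  stopifnot(inherits(x, "quant_matrix"))
  v <- x$values
  idx <- expand.grid(p = seq_len(nrow(v)), r = seq_len(ncol(v)))
  df <- data.frame(
    protein = rownames(v)[idx$p],
    x$runs[idx$r, c("run_id", "tissue", "extraction", "time",
                    "bio_rep", "tech_rep"), drop = FALSE],
    abundance = v[cbind(idx$p, idx$r)],
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased and the accession is the first whitespace-token
#' of each header. Only the 20 standard residues are accepted; `X` is
#' tolerated (it is excluded from composition denominators downstream). Any
#' other character is an error reporting the offending positions.
#'
#' @param path FASTA file path.
#' @return Named character vector, accession -> sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(stats::setNames(character(0), character(0)))
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  allowed <- c(AA_STANDARD, "X")
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "")[[1]]
    bad <- which(!chars %in% allowed)
    if (length(bad) > 0L) {
      stop("non-residue character(s) in sequence '", names(seqs)[i],
           "' at position(s) ", paste(utils::head(bad, 10L), collapse = ", "),
           call. = FALSE)
    }
  }
  seqs
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read and write protein annotation tables
#'
#' Annotation TSV columns: `accession`, `origin` (`tick` or `host`) and an
#' optional `go_terms` column with `;`-separated GO biological-process
#' labels.
#'
#' @param path file path.
#' @return `read_annotation` returns a data.frame with columns `accession`,
#'   `origin`, `go_terms` (list column).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("accession", "origin") %in% names(df))) {
    stop("annotation table must have columns accession, origin", call. = FALSE)
  }
  bad <- setdiff(unique(df$origin), c("tick", "host"))
  if (length(bad) > 0L) {
    stop("origin must be 'tick' or 'host'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$go_terms)) df$go_terms <- ""
  df$go_terms <- lapply(strsplit(as.character(df$go_terms), ";", fixed = TRUE),
                        function(g) g[nzchar(g)])
  df
}

#' @rdname read_annotation
#' @param annotation annotation data.frame as returned by
#'   [read_annotation()] (the `go_terms` column may be a list or a
#'   `;`-separated character vector).
#' @export
write_annotation <- function(annotation, path) {
  df <- annotation
  if (is.list(df$go_terms)) {
    df$go_terms <- vapply(df$go_terms, paste, "", collapse = ";")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write SEM-EDS elemental composition tables
#'
#' TSV columns: `sample_id`, `tissue`, `time`, `scan`, `element`,
#' `atomic_percent`. Atomic percentages must lie in `[0, 100]` and the
#' retained elements of a scan must sum to at most 100.
#'
#' @param path file path.
#' @export
read_eds_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "tissue", "time", "scan", "element",
                "atomic_percent")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("EDS table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(df$atomic_percent < 0 | df$atomic_percent > 100)) {
    stop("atomic_percent must be within [0, 100]", call. = FALSE)
  }
  sums <- tapply(df$atomic_percent, interaction(df$sample_id, df$scan,
                                                drop = TRUE), sum)
  if (any(sums > 100 + 1e-6)) {
    stop("per-scan atomic percentages sum above 100", call. = FALSE)
  }
  df
}

#' @rdname read_eds_table
#' @param eds EDS data.frame.
#' @export
write_eds_table <- function(eds, path) {
  utils::write.table(eds, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write ELISA plate tables
#'
#' TSV columns: `well`, `role` (`standard`, `blank` or `sample`),
#' `sample_id` (empty for blanks/standards), `ng` (coated BSA-alpha-Gal for
#' standards, NA otherwise), `replicate`, `od`. ODs must be non-negative.
#'
#' @param path file path.
#' @export
read_elisa_plate <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  required <- c("well", "role", "sample_id", "ng", "replicate", "od")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("ELISA table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(df$od < 0)) stop("OD readings must be >= 0", call. = FALSE)
  if (any(df$role == "blank" & !is.na(df$sample_id))) {
    stop("blank wells must not carry a sample_id", call. = FALSE)
  }
  df
}

#' @rdname read_elisa_plate
#' @param plate ELISA plate data.frame.
#' @export
write_elisa_plate <- function(plate, path) {
  utils::write.table(plate, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Export a co-occurrence network
#'
#' Writes the network either as GraphML (node attributes: `name`, `bnc`,
#' optionally `category`; edge attributes: `weight` = SparCC correlation) or
#' as a plain edge-list TSV (`from`, `to`, `rho`).
#'
#' @param network an `igraph` object as built by [build_network()].
#' @param path output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @export
export_network <- function(network, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "igraph"))
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    e <- igraph::as_data_frame(network, what = "edges")
    out <- data.frame(from = e$from, to = e$to,
                      rho = if (nrow(e)) e$weight else numeric(0))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read and write pipeline configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_config` returns a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname read_config
#' @param config named list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
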