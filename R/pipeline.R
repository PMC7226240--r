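#' Run the full sialome/cementome analysis pipeline
#'
#' Chains the stages end-to-end on a synthetic dataset (or on tables read
#' from disk when paths are supplied in `config`): generate -> TAS
#' normalization -> pairwise differential tests per sample type -> profile
#' classification -> origin/tissue partition -> SparCC co-occurrence
#' network with betweenness centrality -> physicochemical panel -> SEM-EDS
#' elemental statistics -> alpha-Gal ELISA quantitation -> report. Every
#' stage writes its result as a plain-text table (TSV/JSON) into
#' `output_dir`, so any stage can be re-run from real data by replacing its
#' input file. The configuration (including the seed) is echoed into the
#' output directory, and the whole run is deterministic given the seed.
#'
#' @param config named list; recognized fields: `synthetic` (arguments to
#'   [synthetic_config()]), `alpha`, `replicate_unit`, `edge_threshold`,
#'   `sparcc_pseudocount`, `exclusion_threshold`, `eds_noise_sd`,
#'   `elisa` (slope/intercept/noise_sd/samples), `selection`
#'   (top_k/go_share_threshold/centrality_quantile), `seed`.
#' @param output_dir directory for stage outputs (created if missing);
#'   `NULL` skips all file output.
#' @return list of stage results: `dataset`, `normalized`, `diff`,
#'   `assignments`, `partition`, `network` (+ `centrality`), `physchem`,
#'   `elements`, `alpha_gal` and `report` (named list of the headline
#'   numbers).
#' @export
run_pipeline <- function(config = list(), output_dir = NULL) {
  defaults <- list(alpha = 0.05, replicate_unit = "run",
                   edge_threshold = 0.6, sparcc_pseudocount = 1,
                   exclusion_threshold = 0.1, eds_noise_sd = 0.5,
                   seed = 1L)
  config <- utils::modifyList(defaults, config)
  if (!is.null(output_dir) &&
      !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  save_tsv <- function(df, name) {
    if (!is.null(output_dir)) {
      utils::write.table(df, file.path(output_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  syn_args <- config$synthetic
  if (is.null(syn_args)) syn_args <- list()
  if (is.null(syn_args$seed)) syn_args$seed <- config$seed
  cfg <- do.call(synthetic_config, syn_args)
  dataset <- generate_dataset(cfg)

  normalized <- tas_normalize(dataset$quant)
  if (!is.null(output_dir)) {
    write_quant_matrix(normalized,
                       file.path(output_dir, "normalized_quant.tsv"))
    write_fasta(dataset$sequences, file.path(output_dir, "sequences.fasta"))
    write_annotation(dataset$annotation,
                     file.path(output_dir, "annotation.tsv"))
    write_config(config[setdiff(names(config), "synthetic")],
                 file.path(output_dir, "config.json"))
  }

  # differential tests and profiles per tissue; a protein is evaluated in
  # the tissue where it is detected (salivary gland preferred when shared)
  sample_sets <- list(
    salivary_gland = subset_runs(normalized, tissue = "salivary_gland"),
    cement = subset_runs(normalized, tissue = "cement")
  )
  diff_all <- list()
  assign_all <- list()
  for (tis in names(sample_sets)) {
    sub <- sample_sets[[tis]]
    detected <- rownames(sub$values)[rowSums(sub$values) > 0]
    if (length(detected) == 0L) next
    sub <- subset_runs(sub, proteins = detected)
    d <- differential_test(sub, alpha = config$alpha,
                           replicate_unit = config$replicate_unit)
    d$tissue <- tis
    a <- classify_profiles(d)
    a$tissue <- tis
    diff_all[[tis]] <- d
    assign_all[[tis]] <- a
  }
  diff <- do.call(rbind, diff_all)
  assignments <- do.call(rbind, assign_all)
  rownames(assignments) <- NULL
  save_tsv(diff, "differential.tsv")
  save_tsv(assignments, "assignments.tsv")

  # partition from per-(tissue, extraction) identification sets
  v <- normalized$values
  idents <- lapply(split(seq_len(nrow(normalized$runs)),
                         paste(normalized$runs$tissue,
                               normalized$runs$extraction, sep = ".")),
                   function(j) {
                     rownames(v)[rowSums(v[, j, drop = FALSE]) > 0]
                   })
  partition <- build_partition(idents, dataset$annotation)
  save_tsv(partition$counts, "partition_counts.tsv")

  # co-occurrence network of cementome tick proteins (the analysis focus);
  # falls back to all detected proteins when too few
  cement <- sample_sets$cement
  tick_acc <- dataset$annotation$accession[dataset$annotation$origin == "tick"]
  net_proteins <- intersect(partition$cementome, tick_acc)
  if (length(net_proteins) < 4L) net_proteins <- rownames(v)
  net_mat <- subset_runs(cement, proteins = net_proteins)
  net_mat$values <- net_mat$values[rowSums(net_mat$values) > 0, ,
                                   drop = FALSE]
  network <- NULL
  centrality <- NULL
  if (nrow(net_mat$values) >= 4L) {
    sp <- sparcc(net_mat$values, pseudocount = config$sparcc_pseudocount,
                 exclusion_threshold = config$exclusion_threshold)
    network <- build_network(sp$rho, edge_threshold = config$edge_threshold)
    centrality <- sort(betweenness_scores(network), decreasing = TRUE)
    if (!is.null(output_dir)) {
      export_network(network, file.path(output_dir, "network.graphml"),
                     "graphml")
      save_tsv(data.frame(protein = names(centrality), bnc = centrality),
               "centrality.tsv")
    }
  }

  # physicochemical panel by comparison group
  mem <- partition_membership(partition)
  grp <- ifelse(mem$origin == "host" & mem$membership == "cementome_only",
                "host",
         ifelse(mem$origin == "tick" & mem$membership == "sialome_only",
                "tick",
         ifelse(mem$origin == "host", "host_cement", "tick_cement")))
  in_seq <- mem$accession %in% names(dataset$sequences)
  physchem <- group_property_summary(dataset$sequences[mem$accession[in_seq]],
                                     grp[in_seq],
                                     subsample = c(tick = 100),
                                     seed = config$seed)
  save_tsv(physchem$profiles, "physchem_groups.tsv")

  # key-protein selection scores
  selection_args <- config$selection
  if (is.null(selection_args)) selection_args <- list()
  selection <- do.call(select_key_proteins, c(
    list(assignments = assignments, partition = partition,
         annotation = dataset$annotation, centrality = centrality,
         quant = normalized), selection_args))
  save_tsv(selection, "selection_scores.tsv")

  # SEM-EDS elemental stage
  eds <- generate_eds_table(normalized, dataset$sequences,
                            noise_sd = config$eds_noise_sd,
                            seed = config$seed)
  elements <- summarize_elements(eds)
  save_tsv(eds, "eds.tsv")
  save_tsv(elements$summary, "element_summary.tsv")

  # alpha-Gal ELISA stage
  elisa_args <- config$elisa
  if (is.null(elisa_args)) elisa_args <- list()
  if (is.null(elisa_args$slope)) elisa_args$slope <- 0.9
  if (is.null(elisa_args$samples)) {
    elisa_args$samples <- c(sialome_T1 = 0.6, sialome_T2 = 0.4,
                            sialome_T3 = 0.2, cementome_T1 = 0.8,
                            cementome_T2 = 0.8, cementome_T3 = 0.7)
  }
  if (is.null(elisa_args$seed)) elisa_args$seed <- config$seed
  elisa <- do.call(generate_elisa_plate, elisa_args)
  cal <- calibrate_plate(elisa$plate)
  alpha_gal <- quantify_alpha_gal(elisa$plate, cal)
  save_tsv(alpha_gal, "alpha_gal.tsv")

  report <- list(
    n_proteins = nrow(dataset$quant$values),
    n_runs = ncol(dataset$quant$values),
    partition = stats::setNames(as.list(partition$extraction_counts),
                                names(partition$extraction_counts)),
    shared_total = sum(partition$counts$shared),
    n_differential = length(unique(
      diff$protein[diff$significant])),
    n_network_edges = if (!is.null(network)) igraph::ecount(network) else 0L,
    top_centrality = if (!is.null(centrality) && length(centrality) > 0) {
      as.list(utils::head(centrality, 5))
    } else list(),
    calibration_r_squared = cal$r_squared,
    config = config[setdiff(names(config), "synthetic")]
  )
  if (!is.null(output_dir)) {
    jsonlite::write_json(report, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  invisible(list(dataset = dataset, normalized = normalized, diff = diff,
                 assignments = assignments, partition = partition,
                 network = network, centrality = centrality,
                 physchem = physchem, selection = selection, eds = eds,
                 elements = elements, alpha_gal = alpha_gal,
                 calibration = cal, report = report))
}
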