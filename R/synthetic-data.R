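# Mean log-abundance trajectory templates, in units of log(effect_size),
# one per developmental-process category. Columns are T1, T2, T3. Each
# category's template realizes exactly its own exact significance triple in
# profile_templates() when noise is small relative to the effect:
# e.g. molting declines monotonically (down, down, down) and
# secondary_cement_production_I peaks at T2 while staying above baseline at
# T3 (up, down, up).
CATEGORY_TRAJECTORIES <- rbind(
  housekeeping                   = c(0, 0, 0),
  molting                        = c(2, 1, 0),
  secondary_cement_production_I  = c(0, 2, 1),
  secondary_cement_production_II = c(1, 2, 0),
  cement_maintenance             = c(1, 1, 0),
  feeding                        = c(0, 1, 2),
  feeding_and_oogenesis          = c(0, 0, 1),
  detachment                     = c(1, 0, 2)
)
colnames(CATEGORY_TRAJECTORIES) <- TIME_LEVELS

#' Configuration of the synthetic sialome/cementome dataset
#'
#' Defines the simulated study: the run design (3 sample types --
#' salivary-gland/native, cement/SDS, cement/urea -- at 3 feeding stages
#' with `n_bio_reps` biological x `n_tech_reps` technical replicates; the
#' defaults give 54 runs), the category composition with per-category
#' log-normal abundance trajectories, tick/host origin labels, tissue
#' membership, and sequence composition classes.
#'
#' @param n_proteins number of proteins to simulate.
#' @param fraction_host fraction of proteins of host (bovine) origin.
#' @param category_weights named numeric vector over the 8 profile
#'   categories, summing to 1; default is equal weight 1/8. Used for tick
#'   proteins.
#' @param host_category_weights category weights for host proteins; the
#'   default concentrates 86% in feeding_and_oogenesis plus the two
#'   secondary-cement-production categories, mirroring the dominance of
#'   those profiles among host-derived proteins.
#' @param membership_weights named weights over `sialome_only`,
#'   `cementome_only`, `shared` tissue membership.
#' @param mean_log_abundance mean of the per-protein baseline natural-log
#'   abundance (Total Area Sums units).
#' @param baseline_sd standard deviation of the per-protein baseline log
#'   abundance (protein-to-protein spread).
#' @param cv_technical,cv_biological coefficients of variation of the
#'   multiplicative technical and biological noise.
#' @param effect_size fold change (> 1, or exactly 1 for a pure null)
#'   applied between time points along each category's template trajectory.
#' @param n_bio_reps,n_tech_reps replicate structure.
#' @param gly_rich_fraction fraction of tick proteins given Gly-biased
#'   sequences (Gly mole percent drawn uniformly from 30-45%).
#' @param sequence_length_range integer `c(min, max)` residues.
#' @param seed RNG seed; a fixed seed makes the generated dataset
#'   byte-identical across calls.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 200,
                             fraction_host = 0.25,
                             category_weights = NULL,
                             host_category_weights = NULL,
                             membership_weights = c(sialome_only = 0.5,
                                                    cementome_only = 0.2,
                                                    shared = 0.3),
                             mean_log_abundance = log(1e5),
                             baseline_sd = 1,
                             cv_technical = 0.1,
                             cv_biological = 0.1,
                             effect_size = 4,
                             n_bio_reps = 2,
                             n_tech_reps = 3,
                             gly_rich_fraction = 0.3,
                             sequence_length_range = c(100L, 400L),
                             seed = 1L) {
  if (is.null(category_weights)) {
    category_weights <- stats::setNames(rep(1 / 8, 8), PROFILE_CATEGORIES)
  }
  if (is.null(host_category_weights)) {
    host_category_weights <- c(
      secondary_cement_production_I = 0.22,
      secondary_cement_production_II = 0.21,
      cement_maintenance = 0.01, feeding = 0.04,
      feeding_and_oogenesis = 0.43, molting = 0.02,
      detachment = 0.01, housekeeping = 0.06
    )
  }
  cfg <- list(n_proteins = n_proteins, fraction_host = fraction_host,
              category_weights = category_weights,
              host_category_weights = host_category_weights,
              membership_weights = membership_weights,
              mean_log_abundance = mean_log_abundance,
              baseline_sd = baseline_sd,
              cv_technical = cv_technical, cv_biological = cv_biological,
              effect_size = effect_size,
              n_bio_reps = n_bio_reps, n_tech_reps = n_tech_reps,
              gly_rich_fraction = gly_rich_fraction,
              sequence_length_range = sequence_length_range,
              seed = seed)

  check_fraction <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("invalid config field '", field, "': must be a fraction in [0, 1]",
           call. = FALSE)
    }
  }
  check_count <- function(field, min = 0L) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < min ||
        v != round(v)) {
      stop("invalid config field '", field, "': must be an integer >= ", min,
           call. = FALSE)
    }
  }
  check_fraction("fraction_host")
  check_fraction("cv_technical")
  check_fraction("cv_biological")
  check_fraction("gly_rich_fraction")
  check_count("n_proteins", 0L)
  check_count("n_bio_reps", 1L)
  check_count("n_tech_reps", 1L)
  check_count("seed")
  for (field in c("category_weights", "host_category_weights")) {
    w <- cfg[[field]]
    if (!setequal(names(w), PROFILE_CATEGORIES) ||
        abs(sum(w) - 1) > 1e-9 || any(w < 0)) {
      stop("invalid config field '", field,
           "': weights over the 8 categories must be >= 0 and sum to 1",
           call. = FALSE)
    }
  }
  if (abs(sum(cfg$membership_weights) - 1) > 1e-9 ||
      !setequal(names(cfg$membership_weights),
                c("sialome_only", "cementome_only", "shared"))) {
    stop("invalid config field 'membership_weights'", call. = FALSE)
  }
  if (!is.numeric(cfg$effect_size) || cfg$effect_size < 1) {
    stop("invalid config field 'effect_size': must be >= 1", call. = FALSE)
  }
  r <- cfg$sequence_length_range
  if (length(r) != 2L || any(r < 10) || r[1] > r[2]) {
    stop("invalid config field 'sequence_length_range'", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

run_design <- function(config) {
  design <- expand.grid(
    tech_rep = seq_len(config$n_tech_reps),
    bio_rep = seq_len(config$n_bio_reps),
    time = TIME_LEVELS,
    sample_type = c("salivary_gland.native", "cement.SDS", "cement.urea"),
    stringsAsFactors = FALSE
  )
  parts <- strsplit(design$sample_type, ".", fixed = TRUE)
  design$tissue <- vapply(parts, `[`, "", 1L)
  design$extraction <- vapply(parts, `[`, "", 2L)
  design$run_id <- sprintf("%s_%s_%s_b%d_t%d", design$tissue,
                           design$extraction, design$time, design$bio_rep,
                           design$tech_rep)
  design[, c("run_id", "tissue", "extraction", "time", "bio_rep", "tech_rep")]
}

sample_sequence <- function(length, gly_rich) {
  if (gly_rich) {
    gly <- stats::runif(1, 0.30, 0.45)
    probs <- stats::setNames(rep((1 - gly) / 19, 20), AA_STANDARD)
    probs["G"] <- gly
  } else {
    probs <- stats::setNames(rep(1 / 20, 20), AA_STANDARD)
  }
  paste(sample(AA_STANDARD, length, replace = TRUE, prob = probs),
        collapse = "")
}

#' Generate a synthetic sialome/cementome dataset with known ground truth
#'
#' Draws protein abundances log-normally around category-specific mean
#' trajectories: for protein i in run (tissue, time, bio, tech),
#' `log A = baseline_i + log(effect_size) * template(category_i, time) +
#' bio effect + tech noise`, with the biological effect shared by all
#' technical replicates of a (tissue, time, biological-replicate) cell.
#' Proteins absent from a tissue (per their membership label) have zero
#' abundance in that tissue's runs. All nonzero abundances are strictly
#' positive.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `quant` ([quant_matrix()]), `annotation`
#'   (data.frame `accession`, `origin`, `go_terms`), `sequences` (named
#'   character) and `truth` (data.frame `protein`, `origin`, `category`,
#'   `membership`, `seq_class`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  design <- run_design(config)
  n <- config$n_proteins

  if (n == 0L) {
    empty_truth <- data.frame(protein = character(0), origin = character(0),
                              category = character(0),
                              membership = character(0),
                              seq_class = character(0))
    v <- matrix(numeric(0), nrow = 0, ncol = nrow(design),
                dimnames = list(character(0), design$run_id))
    return(list(quant = quant_matrix(v, design),
                annotation = data.frame(accession = character(0),
                                        origin = character(0),
                                        go_terms = I(list())),
                sequences = stats::setNames(character(0), character(0)),
                truth = empty_truth))
  }

  proteins <- sprintf("SYNP%04d", seq_len(n))
  origin <- ifelse(stats::runif(n) < config$fraction_host, "host", "tick")
  category <- character(n)
  for (i in seq_len(n)) {
    w <- if (origin[i] == "host") config$host_category_weights else
      config$category_weights
    category[i] <- sample(names(w), 1L, prob = w)
  }
  membership <- sample(names(config$membership_weights), n, replace = TRUE,
                       prob = config$membership_weights)

  baseline <- stats::rnorm(n, config$mean_log_abundance, config$baseline_sd)
  delta <- log(config$effect_size)
  sd_bio <- sqrt(log(1 + config$cv_biological^2))
  sd_tech <- sqrt(log(1 + config$cv_technical^2))

  # biological effects shared across technical replicates (and across the
  # two cement extractions of the same biological material)
  bio_cells <- unique(design[, c("tissue", "time", "bio_rep")])
  bio_key <- function(tissue, time, bio) paste(tissue, time, bio, sep = "|")
  bio_eff <- matrix(stats::rnorm(n * nrow(bio_cells), 0, sd_bio),
                    nrow = n,
                    dimnames = list(proteins,
                                    bio_key(bio_cells$tissue, bio_cells$time,
                                            bio_cells$bio_rep)))

  v <- matrix(0, nrow = n, ncol = nrow(design),
              dimnames = list(proteins, design$run_id))
  in_tissue <- cbind(
    salivary_gland = membership %in% c("sialome_only", "shared"),
    cement = membership %in% c("cementome_only", "shared")
  )
  traj <- CATEGORY_TRAJECTORIES[category, , drop = FALSE]
  for (j in seq_len(nrow(design))) {
    tissue <- design$tissue[j]
    present <- in_tissue[, tissue]
    mu <- baseline + delta * traj[, design$time[j]] +
      bio_eff[, bio_key(tissue, design$time[j], design$bio_rep[j])]
    vals <- exp(mu + stats::rnorm(n, 0, sd_tech))
    v[, j] <- ifelse(present, vals, 0)
  }

  seq_class <- ifelse(origin == "tick" &
                        stats::runif(n) < config$gly_rich_fraction,
                      "gly_rich", "background")
  lens <- sample(seq(config$sequence_length_range[1],
                     config$sequence_length_range[2]), n, replace = TRUE)
  sequences <- stats::setNames(vapply(seq_len(n), function(i) {
    sample_sequence(lens[i], seq_class[i] == "gly_rich")
  }, ""), proteins)

  # simple GO plumbing: category-flavored process labels so that share
  # summaries have structure
  go_terms <- lapply(seq_len(n), function(i) {
    paste0("P:", category[i])
  })

  list(
    quant = quant_matrix(v, design),
    annotation = data.frame(accession = proteins, origin = origin,
                            go_terms = I(go_terms),
                            stringsAsFactors = FALSE),
    sequences = sequences,
    truth = data.frame(protein = proteins, origin = origin,
                       category = category, membership = membership,
                       seq_class = seq_class, stringsAsFactors = FALSE)
  )
}

#' Generate a synthetic SEM-EDS elemental table
#'
#' For every (tissue, time) sample the expected C/N/O/S atomic percentages
#' are the abundance-weighted mean of the member proteins' atomic
#' compositions (renormalized to 100%); each of `n_scans` area scans adds
#' independent Gaussian noise in atomic-percent units, is floored at 0 and
#' renormalized.
#'
#' @param quant a [quant_matrix()].
#' @param sequences named character vector covering all proteins with
#'   nonzero abundance.
#' @param noise_sd Gaussian scan noise, atomic-percent units (>= 0).
#' @param n_scans scans per sample.
#' @param seed RNG seed.
#' @return EDS data.frame (`sample_id`, `tissue`, `time`, `scan`,
#'   `element`, `atomic_percent`).
#' @export
generate_eds_table <- function(quant, sequences, noise_sd = 0.5,
                               n_scans = 3, seed = 1L) {
  stopifnot(inherits(quant, "quant_matrix"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  elements <- c("C", "N", "O", "S")
  used <- rownames(quant$values)[rowSums(quant$values) > 0]
  missing_seq <- setdiff(used, names(sequences))
  if (length(missing_seq) > 0L) {
    stop("no sequence for protein(s): ",
         paste(utils::head(missing_seq, 5L), collapse = ", "), call. = FALSE)
  }
  comp <- t(vapply(rownames(quant$values), function(p) {
    if (!p %in% names(sequences)) return(stats::setNames(rep(0, 4), elements))
    pc <- atomic_composition(sequences[[p]])$percent[elements]
    100 * pc / sum(pc)
  }, numeric(4)))

  set.seed(seed)
  cells <- unique(quant$runs[, c("tissue", "time")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- quant$runs$tissue == cells$tissue[i] &
      quant$runs$time == cells$time[i]
    w <- rowMeans(quant$values[, sel, drop = FALSE])
    if (sum(w) == 0) next
    expected <- colSums(comp * w) / sum(w)
    expected <- 100 * expected / sum(expected)
    sid <- paste(cells$tissue[i], cells$time[i], sep = "_")
    for (scan in seq_len(n_scans)) {
      obs <- pmax(expected + stats::rnorm(length(elements), 0, noise_sd), 0)
      obs <- 100 * obs / sum(obs)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, tissue = cells$tissue[i], time = cells$time[i],
        scan = scan, element = elements, atomic_percent = obs,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic ELISA plate
#'
#' OD model: `OD = intercept + slope * ng + noise`, floored at 0. The
#' intercept plays the role of assay background and is carried by every
#' well, so blank wells (ng = 0, no sample id) read the background. Sample
#' wells use the true alpha-Gal amounts in `samples` (ng per well).
#'
#' @param slope OD per ng.
#' @param intercept background OD.
#' @param noise_sd Gaussian OD noise (>= 0).
#' @param standards numeric vector of standard amounts (ng); must be
#'   non-empty.
#' @param n_blanks number of blank wells (>= 1).
#' @param samples named numeric vector of true ng per sample (ground
#'   truth), each measured in `n_reps` replicate wells.
#' @param n_reps replicate wells per sample and per standard.
#' @param seed RNG seed.
#' @return list with `plate` (ELISA data.frame, see [read_elisa_plate()])
#'   and `truth` (the `samples` vector).
#' @export
generate_elisa_plate <- function(slope, intercept = 0.05, noise_sd = 0.02,
                                 standards = seq(0, 1, by = 0.2),
                                 n_blanks = 3,
                                 samples = NULL, n_reps = 3, seed = 1L) {
  if (length(standards) == 0L) stop("standards must be non-empty",
                                    call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_blanks < 1) stop("need at least one blank well", call. = FALSE)
  set.seed(seed)
  od <- function(ng, n) pmax(intercept + slope * ng +
                               stats::rnorm(n, 0, noise_sd), 0)
  rows <- list()
  well <- 0L
  add <- function(role, sample_id, recorded_ng, true_ng, replicate) {
    well <<- well + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      well = sprintf("W%03d", well), role = role, sample_id = sample_id,
      ng = recorded_ng, replicate = replicate, od = od(true_ng, 1L),
      stringsAsFactors = FALSE)
  }
  for (s in standards) {
    for (r in seq_len(n_reps)) add("standard", NA_character_, s, s, r)
  }
  for (b in seq_len(n_blanks)) add("blank", NA_character_, 0, 0, b)
  if (!is.null(samples)) {
    for (nm in names(samples)) {
      for (r in seq_len(n_reps)) {
        add("sample", nm, NA_real_, samples[[nm]], r)
      }
    }
  }
  plate <- do.call(rbind, rows)
  rownames(plate) <- NULL
  list(plate = plate, truth = samples)
}

#' Blank-correct a plate and fit its calibration line
#'
#' Subtracts the mean blank OD from the standard wells and fits the
#' calibration through the corrected (ng, OD) pairs, as in the assay
#' protocol (blank average subtracted from all reads before conversion).
#' The resulting `calibration_fit` is directly usable by
#' [quantify_alpha_gal()] on the same plate.
#'
#' @param plate ELISA plate data.frame.
#' @return A `calibration_fit` (see [fit_calibration()]).
#' @export
calibrate_plate <- function(plate) {
  blanks <- plate$od[plate$role == "blank"]
  if (length(blanks) == 0L) stop("no blank wells on plate", call. = FALSE)
  std <- plate[plate$role == "standard", , drop = FALSE]
  fit_calibration(data.frame(ng = std$ng, od = std$od - mean(blanks)))
}
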