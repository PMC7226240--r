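#' Default developmental-process profile templates
#'
#' Maps every attainable significance/direction triple over the three
#' pairwise time comparisons (T1vT2, T2vT3, T1vT3; states `up`, `down`,
#' `ns`) to exactly one developmental-process category. The mapping is a
#' documented reconstruction of the profile shapes, not a published table:
#'
#' * `housekeeping` -- (ns, ns, ns): no significant change anywhere.
#' * `molting` -- monotone decline from a T1 high, the signature of
#'   molting-associated proteins switched off after the adult molt:
#'   (down, down, down) and (down, ns, down).
#' * `secondary_cement_production_I` -- T2 peak retained above baseline:
#'   (up, down, up) and (up, down, ns).
#' * `secondary_cement_production_II` -- transient T2 burst dropping below
#'   baseline: (up, down, down).
#' * `cement_maintenance` -- early high maintained through T2, declining
#'   toward detachment: (ns, down, down).
#' * `feeding` -- monotone rise with feeding activity: (up, up, up).
#' * `feeding_and_oogenesis` -- late rise: (ns, up, up) and (ns, ns, up).
#' * `detachment` -- T3-only spike from a suppressed mid-feeding level:
#'   (down, up, up).
#'
#' The 16 remaining triples are filled deterministically by Hamming-nearest
#' assignment to the exact template sets, ties broken by the priority order
#' molting > secondary_I > secondary_II > maintenance > feeding >
#' feeding_and_oogenesis > detachment. Housekeeping is matched exactly only:
#' any protein significant in at least one comparison is, by construction,
#' non-housekeeping.
#'
#' @return data.frame with columns `T1vT2`, `T2vT3`, `T1vT3`, `category`,
#'   `exact` covering all 27 triples.
#' @export
profile_templates <- function() {
  states <- c("up", "down", "ns")
  grid <- expand.grid(T1vT2 = states, T2vT3 = states, T1vT3 = states,
                      stringsAsFactors = FALSE)

  exact <- list(
    housekeeping = list(c("ns", "ns", "ns")),
    molting = list(c("down", "down", "down"), c("down", "ns", "down")),
    secondary_cement_production_I = list(c("up", "down", "up"),
                                         c("up", "down", "ns")),
    secondary_cement_production_II = list(c("up", "down", "down")),
    cement_maintenance = list(c("ns", "down", "down")),
    feeding = list(c("up", "up", "up")),
    feeding_and_oogenesis = list(c("ns", "up", "up"), c("ns", "ns", "up")),
    detachment = list(c("down", "up", "up"))
  )
  priority <- c("molting", "secondary_cement_production_I",
                "secondary_cement_production_II", "cement_maintenance",
                "feeding", "feeding_and_oogenesis", "detachment")

  category <- character(nrow(grid))
  is_exact <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    triple <- as.character(grid[i, 1:3])
    hit <- NULL
    for (cat in names(exact)) {
      if (any(vapply(exact[[cat]], identical, TRUE, y = triple))) {
        hit <- cat
        break
      }
    }
    if (!is.null(hit)) {
      category[i] <- hit
      is_exact[i] <- TRUE
    } else {
      dist <- vapply(priority, function(cat) {
        min(vapply(exact[[cat]],
                   function(tpl) sum(tpl != triple), 0L))
      }, 0L)
      category[i] <- priority[which.min(dist)]
    }
  }
  grid$category <- category
  grid$exact <- is_exact
  grid
}

#' Classify proteins into developmental-process categories
#'
#' Converts each protein's three differential-test records into a
#' significance/direction triple and looks it up in the template table.
#' Proteins without any significant comparison land, by template
#' construction, in `housekeeping`. Proteins with an untestable comparison
#' get `NA` category and `untestable = TRUE`.
#'
#' @param diff_results data.frame from [differential_test()] containing all
#'   three comparisons per protein.
#' @param templates template table as from [profile_templates()]; must map
#'   every triple to exactly one category.
#' @return data.frame with columns `protein`, `pattern` (e.g.
#'   `"up/down/ns"` in T1vT2/T2vT3/T1vT3 order), `category`, `untestable`.
#' @export
classify_profiles <- function(diff_results, templates = profile_templates()) {
  required <- c("protein", "comparison", "direction", "significant",
                "untestable")
  if (!all(required %in% names(diff_results))) {
    stop("diff_results must come from differential_test()", call. = FALSE)
  }
  if (anyDuplicated(templates[, c("T1vT2", "T2vT3", "T1vT3")])) {
    stop("template table maps some triple more than once", call. = FALSE)
  }
  proteins <- unique(diff_results$protein)
  state <- ifelse(diff_results$untestable, NA_character_,
                  ifelse(diff_results$significant, diff_results$direction,
                         "ns"))
  wide <- lapply(COMPARISONS, function(cmp) {
    i <- diff_results$comparison == cmp
    stats::setNames(state[i], diff_results$protein[i])[proteins]
  })
  names(wide) <- COMPARISONS
  if (any(vapply(COMPARISONS, function(cmp) {
    sum(diff_results$comparison == cmp) != length(proteins)
  }, TRUE))) {
    stop("all three comparisons must be present for every protein",
         call. = FALSE)
  }

  key <- paste(wide$T1vT2, wide$T2vT3, wide$T1vT3, sep = "/")
  tkey <- paste(templates$T1vT2, templates$T2vT3, templates$T1vT3, sep = "/")
  idx <- match(key, tkey)
  untestable <- is.na(wide$T1vT2) | is.na(wide$T2vT3) | is.na(wide$T1vT3)
  uncovered <- !untestable & is.na(idx)
  if (any(uncovered)) {
    stop("template table does not cover triple(s): ",
         paste(unique(key[uncovered]), collapse = "; "), call. = FALSE)
  }
  data.frame(
    protein = proteins,
    pattern = ifelse(untestable, NA_character_, key),
    category = ifelse(untestable, NA_character_, templates$category[idx]),
    untestable = untestable,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Category shares per origin
#'
#' Percentage of proteins assigned to each developmental-process category,
#' split by origin (tick/host). Percentages within each origin sum to 100
#' (up to rounding); an empty origin group yields no rows rather than a
#' division error.
#'
#' @param assignments data.frame from [classify_profiles()].
#' @param annotation annotation data.frame with `accession` and `origin`.
#' @param drop_housekeeping if `TRUE`, restrict to differentially
#'   represented proteins (significant in at least one comparison) before
#'   computing shares, as done for profile summaries.
#' @return data.frame with columns `origin`, `category`, `n`, `share_pct`.
#' @export
category_summary <- function(assignments, annotation,
                             drop_housekeeping = FALSE) {
  a <- assignments[!assignments$untestable & !is.na(assignments$category), ,
                   drop = FALSE]
  if (drop_housekeeping) a <- a[a$category != "housekeeping", , drop = FALSE]
  a$origin <- annotation$origin[match(a$protein, annotation$accession)]
  if (any(is.na(a$origin))) {
    stop("unannotated protein(s): ",
         paste(utils::head(a$protein[is.na(a$origin)], 5L), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(a) == 0L) {
    return(data.frame(origin = character(0), category = character(0),
                      n = integer(0), share_pct = numeric(0)))
  }
  counts <- as.data.frame(table(origin = a$origin, category = a$category),
                          stringsAsFactors = FALSE)
  names(counts)[3] <- "n"
  counts <- counts[counts$n > 0 | TRUE, , drop = FALSE]
  totals <- tapply(counts$n, counts$origin, sum)
  counts$share_pct <- 100 * counts$n / as.numeric(totals[counts$origin])
  counts <- counts[counts$n > 0, , drop = FALSE]
  counts[order(counts$origin, -counts$n), , drop = FALSE]
}

#' Write or read a profile template table as JSON
#'
#' @param templates template data.frame as from [profile_templates()].
#' @param path JSON file path.
#' @export
write_templates <- function(templates, path) {
  jsonlite::write_json(templates, path, pretty = TRUE)
  invisible(path)
}

#' @rdname write_templates
#' @export
read_templates <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("T1vT2", "T2vT3", "T1vT3", "category")
  if (!all(required %in% names(df))) {
    stop("template file must have columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  df
}
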