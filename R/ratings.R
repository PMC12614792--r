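#' Validate a long-form ratings table
#'
#' A ratings table has one row per slider response: `participant_id`,
#' `material_id`, `attribute_id` (1--16) and `response`. Duplicate
#' (participant, material, attribute) triples are rejected.
#'
#' @param table Data frame of raw or z-scored responses.
#' @param slider_range Permitted raw response range, or `NULL` to skip the
#'   range check (z-scored tables).
#' @return The table as a validated tibble.
#' @export
validate_ratings <- function(table, slider_range = NULL) {
  needed <- c("participant_id", "material_id", "attribute_id", "response")
  missing <- setdiff(needed, names(table))
  if (length(missing) > 0) {
    rlang::abort(paste0("ratings table is missing columns: ",
                        paste(missing, collapse = ", ")))
  }
  table <- tibble::as_tibble(table)
  table$participant_id <- as.character(table$participant_id)
  table$material_id <- as.character(table$material_id)
  table$attribute_id <- as.integer(table$attribute_id)
  if (!all(table$attribute_id %in% 1:16)) {
    rlang::abort("attribute_id must be in 1..16")
  }
  if (!all(is.finite(table$response))) {
    bad <- which(!is.finite(table$response))
    rlang::abort(paste0("non-finite responses at rows: ",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }
  key <- paste(table$participant_id, table$material_id, table$attribute_id)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    rlang::abort(sprintf("duplicate (participant, material, attribute) triple: %s", d))
  }
  if (!is.null(slider_range)) {
    bad <- which(table$response < slider_range[1] | table$response > slider_range[2])
    if (length(bad) > 0) {
      rlang::abort(paste0("responses outside [", slider_range[1], ", ",
                          slider_range[2], "] at rows: ",
                          paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  table
}

#' Z-score responses within each participant-by-attribute stratum
#'
#' Normalises raw slider responses at the participant level: within each
#' (participant, attribute) stratum (i.e. across the materials that
#' participant rated on that attribute) responses are transformed to mean 0
#' and sample (n-1) standard deviation 1. This removes per-participant offset
#' and gain before averaging across participants.
#'
#' Strata with zero variance carry no ranking information; their responses
#' are set to 0 and the stratum is recorded in the `"zero_variance_strata"`
#' attribute of the result (consumed by [exclude_discordant()]).
#'
#' @param table A ratings table (see [validate_ratings()]).
#' @return The table with `response` replaced by its z-score, plus a
#'   `"zero_variance_strata"` attribute.
#' @export
zscore_participant <- function(table) {
  table <- validate_ratings(table)
  out <- table |>
    dplyr::group_by(.data$participant_id, .data$attribute_id) |>
    dplyr::mutate(
      .sd = stats::sd(.data$response),
      response = dplyr::if_else(
        .data$.sd > 0,
        (.data$response - mean(.data$response)) / .data$.sd,
        0
      )
    ) |>
    dplyr::ungroup()
  flat <- out |>
    dplyr::filter(.data$.sd == 0 | is.na(.data$.sd)) |>
    dplyr::distinct(.data$participant_id, .data$attribute_id)
  out$.sd <- NULL
  attr(out, "zero_variance_strata") <- flat
  out
}

#' Flag participants whose ratings oppose the consensus
#'
#' For each attribute, the provisional mean rating of every material is
#' computed across all participants (including the one under test). A
#' participant is excluded for that attribute when the Pearson correlation
#' between their material ratings and the provisional means is negative or
#' undefined. Zero-variance strata flagged by [zscore_participant()] are
#' excluded as well.
#'
#' @param table A ratings table that has already been z-scored.
#' @return A tibble of exclusions: `participant_id`, `attribute_id`,
#'   `reason` (one of `"negative correlation"`, `"undefined correlation"`,
#'   `"zero variance"`).
#' @export
exclude_discordant <- function(table) {
  flat <- attr(table, "zero_variance_strata")
  table <- validate_ratings(table)
  cons <- table |>
    dplyr::group_by(.data$attribute_id, .data$material_id) |>
    dplyr::summarise(consensus = mean(.data$response), .groups = "drop")
  joined <- dplyr::left_join(table, cons, by = c("attribute_id", "material_id"))
  excl <- joined |>
    dplyr::group_by(.data$participant_id, .data$attribute_id) |>
    dplyr::summarise(
      r = if (dplyr::n() >= 2 &&
              stats::sd(.data$response) > 0 &&
              stats::sd(.data$consensus) > 0) {
        stats::cor(.data$response, .data$consensus)
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::filter(is.na(.data$r) | .data$r < 0) |>
    dplyr::mutate(reason = dplyr::if_else(is.na(.data$r),
                                          "undefined correlation",
                                          "negative correlation")) |>
    dplyr::select("participant_id", "attribute_id", "reason")
  if (!is.null(flat) && nrow(flat) > 0) {
    flat$reason <- "zero variance"
    excl <- dplyr::bind_rows(excl, flat) |>
      dplyr::distinct(.data$participant_id, .data$attribute_id, .keep_all = TRUE)
  }
  # a participant alone on an attribute is never excluded for negativity:
  # the consensus is their own mean, so the correlation is exactly 1
  dplyr::arrange(excl, .data$attribute_id, .data$participant_id)
}

#' Aggregate raw ratings into mean z-score fingerprints
#'
#' The full aggregation pipeline: z-score within participant and attribute,
#' drop discordant participants per attribute, then average the surviving
#' responses across participants for every (material, attribute) cell.
#'
#' @param table A raw ratings table (slider units).
#' @param categories Optional tibble (`material_id`, `category`) to attach
#'   category labels to the resulting fingerprints.
#' @return An object of class `fp_aggregation`: a list with `fingerprints`
#'   (a zscore-scale fingerprint set), `excluded` (the exclusion tibble) and
#'   `n_ratings_used`.
#' @export
aggregate_ratings <- function(table, categories = NULL) {
  z <- zscore_participant(table)
  excl <- exclude_discordant(z)
  kept <- dplyr::anti_join(z, excl, by = c("participant_id", "attribute_id"))
  all_cells <- tidyr::expand_grid(
    material_id = sort(unique(z$material_id)),
    attribute_id = sort(unique(z$attribute_id))
  )
  means <- kept |>
    dplyr::group_by(.data$material_id, .data$attribute_id) |>
    dplyr::summarise(value = mean(.data$response), .groups = "drop")
  empty <- dplyr::anti_join(all_cells, means, by = c("material_id", "attribute_id"))
  if (nrow(empty) > 0) {
    rlang::abort(paste0(
      "no surviving ratings for cell(s): ",
      paste(utils::head(paste0("(", empty$material_id, ", attr ",
                               empty$attribute_id, ")"), 5), collapse = ", ")
    ))
  }
  wide <- means |>
    dplyr::mutate(attr = sprintf("attr%02d", .data$attribute_id)) |>
    dplyr::select("material_id", "attr", "value") |>
    tidyr::pivot_wider(names_from = "attr", values_from = "value") |>
    dplyr::arrange(.data$material_id)
  missing_attr <- setdiff(fp_cols(), names(wide))
  for (a in missing_attr) wide[[a]] <- 0 # attributes never rated: neutral 0
  fps <- fingerprint_set(wide$material_id, wide[fp_cols()], scale = "zscore")
  if (!is.null(categories)) {
    fps$category <- categories$category[match(fps$material_id, categories$material_id)]
  }
  structure(
    list(fingerprints = fps, excluded = excl, n_ratings_used = nrow(kept)),
    class = "fp_aggregation"
  )
}

#' @export
print.fp_aggregation <- function(x, ...) {
  cat("Fingerprint aggregation report\n")
  cat("  materials:     ", nrow(x$fingerprints), "\n")
  cat("  ratings used:  ", x$n_ratings_used, "\n")
  cat("  exclusions:    ", nrow(x$excluded),
      "(participant x attribute)\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.fp_aggregation <- function(x, ...) {
  x$fingerprints |>
    tidyr::pivot_longer(dplyr::all_of(fp_cols()),
                        names_to = "attribute", values_to = "value") |>
    dplyr::mutate(attribute_id = as.integer(sub("attr", "", .data$attribute))) |>
    dplyr::select("material_id", "category", "attribute_id", "value")
}

#' @export
glance.fp_aggregation <- function(x, ...) {
  tibble::tibble(
    n_materials = nrow(x$fingerprints),
    n_ratings_used = x$n_ratings_used,
    n_exclusions = nrow(x$excluded),
    mean_exclusions_per_attribute = nrow(x$excluded) / n_attributes()
  )
}

#' Attribute importance from free-naming responses
#'
#' Combines how often an attribute is mentioned with how early it is ranked.
#' For each attribute: `ap` is the fraction of (participant, trial) responses
#' mentioning it, `ao` its mean rank over those mentions, and the combined
#' importance is `ap * (max(ao) - ao)` with the max taken over attributes that
#' were mentioned at least once. Attributes never mentioned get importance 0.
#'
#' @param naming Tibble of naming responses: `participant_id`, `trial`,
#'   `term`, `rank`.
#' @param clusters Tibble mapping each retained `term` to an `attribute_id`.
#' @return Tibble with one row per schema attribute: `id`, `name`, `ap`,
#'   `ao`, `importance`.
#' @export
attribute_importance <- function(naming, clusters) {
  stopifnot(all(c("participant_id", "trial", "term", "rank") %in% names(naming)),
            all(c("term", "attribute_id") %in% names(clusters)))
  if (any(naming$rank < 1)) rlang::abort("ranks must be >= 1")
  unmapped <- setdiff(unique(naming$term), clusters$term)
  if (length(unmapped) > 0) {
    rlang::abort(paste0("terms without an attribute mapping: ",
                        paste(utils::head(unmapped, 5), collapse = ", ")))
  }
  naming <- dplyr::left_join(tibble::as_tibble(naming), tibble::as_tibble(clusters),
                             by = "term")
  n_responses <- nrow(dplyr::distinct(naming, .data$participant_id, .data$trial))
  per_attr <- naming |>
    dplyr::group_by(.data$attribute_id) |>
    dplyr::summarise(
      n_mentions = dplyr::n_distinct(.data$participant_id, .data$trial),
      ao = mean(.data$rank),
      .groups = "drop"
    ) |>
    dplyr::mutate(ap = .data$n_mentions / n_responses)
  out <- attribute_schema()[, c("id", "name")]
  out <- dplyr::left_join(out, per_attr, by = c(id = "attribute_id"))
  out$ap[is.na(out$ap)] <- 0
  max_ao <- max(out$ao, na.rm = TRUE)
  out$importance <- ifelse(is.na(out$ao), 0, out$ap * (max_ao - out$ao))
  dplyr::select(out, "id", "name", "ap", "ao", "importance")
}

#' Fleiss' kappa for multi-rater nominal assignments
#'
#' Chance-corrected agreement when r raters each sort the same set of
#' responses into the 16 attribute categories. Every response must be rated
#' by the same number of raters (r >= 2); no generalised variant for unequal
#' rater counts is attempted.
#'
#' @param assignments Tibble with `response_id`, `rater_id`, `attribute_id`.
#' @return Kappa in \[-1, 1\] (1 for perfect agreement; defined as 1 when
#'   agreement is perfect even if everything lands in a single category).
#' @export
fleiss_kappa <- function(assignments) {
  counts <- assignment_counts(assignments)
  r <- sum(counts[1, ])
  n <- nrow(counts)
  p_i <- (rowSums(counts^2) - r) / (r * (r - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / (n * r)
  p_e <- sum(p_j^2)
  if (1 - p_e < .Machine$double.eps) {
    return(if (p_bar >= 1 - 1e-12) 1 else 0)
  }
  (p_bar - p_e) / (1 - p_e)
}

assignment_counts <- function(assignments) {
  stopifnot(all(c("response_id", "rater_id", "attribute_id") %in% names(assignments)))
  a <- tibble::as_tibble(assignments)
  key <- paste(a$response_id, a$rater_id)
  if (anyDuplicated(key)) rlang::abort("a rater assigned the same response twice")
  if (!all(a$attribute_id %in% 1:16)) rlang::abort("attribute_id must be in 1..16")
  tab <- table(a$response_id, factor(a$attribute_id, levels = 1:16))
  counts <- unclass(as.matrix(tab))
  r_per <- rowSums(counts)
  if (length(unique(r_per)) != 1) {
    rlang::abort("every response must be rated by the same number of raters")
  }
  if (r_per[1] < 2) rlang::abort("need at least 2 raters per response")
  counts
}

#' Agreement-level counts across raters
#'
#' For each response, takes the size of the largest block of raters choosing
#' the same category (the modal count) and tallies how many responses reach
#' unanimity, at-least-3 agreement and at-least-2 agreement.
#'
#' @inheritParams fleiss_kappa
#' @return Tibble with `unanimous`, `at_least_3`, `at_least_2`, `n_responses`.
#' @export
unanimity_counts <- function(assignments) {
  counts <- assignment_counts(assignments)
  r <- sum(counts[1, ])
  modal <- apply(counts, 1, max)
  tibble::tibble(
    unanimous = sum(modal == r),
    at_least_3 = sum(modal >= 3),
    at_least_2 = sum(modal >= 2),
    n_responses = nrow(counts)
  )
}
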