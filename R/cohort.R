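#' Build a cohort table from a long partner data frame
#'
#' A cohort table is the unit of every analysis in the package: one row per
#' (respondent, partner), a father flag, and one column per registered trait.
#' Missing cells stay missing — a partner lacking a value for one trait is
#' excluded only from analyses of that trait.
#'
#' @param data A data frame with columns `respondent_id`, `partner_ordinal`,
#'   `is_father` (0/1 or logical), optionally `relationship_length_years`,
#'   and one numeric column per registered trait. Empty cells are missing.
#' @param registry A trait registry tibble (see [default_trait_registry()]);
#'   only registered traits present in `data` are analysed.
#' @return A tibble of class `mate_cohort` carrying the registry as an
#'   attribute. Fails if validation finds errors.
#' @seealso [validate_cohort()], [load_cohort()]
#' @export
cohort_table <- function(data, registry = default_trait_registry()) {
  validate_registry(registry)
  data <- tibble::as_tibble(data)
  report <- validate_cohort(data, registry)
  if (nrow(report$errors) > 0L) {
    msgs <- utils::head(report$errors$message, 5L)
    stop("cohort validation failed (", nrow(report$errors), " error(s)):\n  ",
         paste(msgs, collapse = "\n  "), call. = FALSE)
  }
  data$is_father <- as.logical(data$is_father)
  data <- dplyr::arrange(data, .data$respondent_id, .data$partner_ordinal)
  structure(data,
            registry = registry[registry$trait %in% names(data), , drop = FALSE],
            class = c("mate_cohort", class(tibble::tibble())))
}

#' @rdname cohort_table
#' @param x A `mate_cohort` object.
#' @export
trait_registry <- function(x) {
  reg <- attr(x, "registry")
  if (is.null(reg)) stop("object carries no trait registry", call. = FALSE)
  reg
}

#' Validate a cohort data frame against a trait registry
#'
#' Checks the cohort invariants: required columns present, no unknown trait
#' columns, trait values inside their declared scales, partner ordinals unique
#' within respondent, and every respondent listing at least two partners (the
#' inclusion rule of the underlying study design). Also tabulates, per trait,
#' the informative respondents (those with at least two non-missing partner
#' values) and informative partners.
#'
#' @inheritParams cohort_table
#' @return A list of class `cohort_validation` with elements `errors`
#'   (tibble: `respondent_id`, `row`, `rule`, `message`), `warnings`
#'   (character), and `counts` (tibble: `trait`, `n_respondents_informative`,
#'   `n_partners_informative`). Empty `errors` means the cohort passes.
#' @export
validate_cohort <- function(data, registry = default_trait_registry()) {
  data <- tibble::as_tibble(data)
  errors <- list()
  add_error <- function(respondent_id, row, rule, message) {
    errors[[length(errors) + 1L]] <<- tibble::tibble(
      respondent_id = as.character(respondent_id),
      row = as.integer(row), rule = rule, message = message)
  }

  required <- c("respondent_id", "partner_ordinal", "is_father")
  miss <- setdiff(required, names(data))
  if (length(miss) > 0L) {
    add_error(NA, NA, "missing_column",
              paste0("missing required column(s): ", paste(miss, collapse = ", ")))
    return(validation_report(errors, character(), registry[0, ], data))
  }

  meta_cols <- c(required, "relationship_length_years")
  trait_cols <- setdiff(names(data), meta_cols)
  unknown <- setdiff(trait_cols, registry$trait)
  for (col in unknown) {
    add_error(NA, NA, "unknown_trait",
              paste0("column '", col, "' is not a registered trait"))
  }
  traits <- intersect(trait_cols, registry$trait)

  if (any(!data$partner_ordinal %% 1 == 0 | data$partner_ordinal < 1, na.rm = TRUE)) {
    add_error(NA, NA, "bad_ordinal", "partner_ordinal must be a positive integer")
  }

  dup <- data |>
    dplyr::count(.data$respondent_id, .data$partner_ordinal) |>
    dplyr::filter(.data$n > 1L)
  for (i in seq_len(nrow(dup))) {
    add_error(dup$respondent_id[i], NA, "duplicate_ordinal",
              paste0("respondent ", dup$respondent_id[i],
                     ": partner_ordinal ", dup$partner_ordinal[i], " repeated"))
  }

  few <- data |>
    dplyr::count(.data$respondent_id) |>
    dplyr::filter(.data$n < 2L)
  for (i in seq_len(nrow(few))) {
    add_error(few$respondent_id[i], NA, "min_partner_count",
              paste0("respondent ", few$respondent_id[i],
                     " below minimum partner count (has ", few$n[i],
                     ", needs 2)"))
  }

  for (tr in traits) {
    spec <- trait_spec(registry, tr)
    v <- data[[tr]]
    bad <- which(!is.na(v) & (v < spec$scale_min | v > spec$scale_max))
    for (row in bad) {
      add_error(data$respondent_id[row], row, "value_out_of_range",
                paste0("row ", row, ": trait '", tr, "' value ", v[row],
                       " outside scale [", spec$scale_min, ", ",
                       spec$scale_max, "]"))
    }
    if (isTRUE(spec$integer_valued) &&
        any(!is.na(v) & abs(v - round(v)) > 1e-8)) {
      add_error(NA, NA, "non_integer_value",
                paste0("trait '", tr, "' declared integer-valued but holds ",
                       "non-integer values"))
    }
  }

  warnings <- character()
  if (length(traits) == 0L) {
    warnings <- c(warnings, "no registered trait columns present")
  }

  validation_report(errors, warnings, registry[registry$trait %in% traits, ], data)
}

validation_report <- function(errors, warnings, registry, data) {
  errors <- if (length(errors) > 0L) {
    dplyr::bind_rows(errors)
  } else {
    tibble::tibble(respondent_id = character(), row = integer(),
                   rule = character(), message = character())
  }
  counts <- purrr::map_dfr(registry$trait, function(tr) {
    ok <- !is.na(data[[tr]])
    per_resp <- tapply(ok, data$respondent_id, sum)
    tibble::tibble(
      trait = tr,
      n_respondents_informative = sum(per_resp >= 2L),
      n_partners_informative = sum(ok[data$respondent_id %in%
                                        names(per_resp)[per_resp >= 2L]]))
  })
  structure(list(errors = errors, warnings = warnings, counts = counts),
            class = "cohort_validation")
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("Cohort validation:", nrow(x$errors), "error(s),",
      length(x$warnings), "warning(s)\n")
  if (nrow(x$errors) > 0L) print(x$errors)
  invisible(x)
}

#' Read and write cohort CSV files
#'
#' The on-disk format is the long partner table: columns `respondent_id`,
#' `partner_ordinal`, `is_father` (0/1), optionally
#' `relationship_length_years`, then one column per registered trait; empty
#' cells are missing values.
#'
#' @param path Path to the cohort CSV.
#' @param registry_path Optional path to a YAML trait registry; when `NULL`
#'   the built-in 21-trait registry is used.
#' @param registry A registry tibble, overriding `registry_path`.
#' @return `load_cohort()` returns a validated `mate_cohort` tibble;
#'   `write_cohort()` returns `path` invisibly. Round-tripping a cohort
#'   through `write_cohort()` and `load_cohort()` reproduces it exactly.
#' @export
load_cohort <- function(path, registry_path = NULL,
                        registry = NULL) {
  if (is.null(registry)) {
    registry <- if (is.null(registry_path)) default_trait_registry()
                else read_trait_registry(registry_path)
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cohort_table(data, registry)
}

#' @rdname load_cohort
#' @param cohort A `mate_cohort` tibble.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  out$is_father <- as.integer(out$is_father)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Score one TIPI personality domain
#'
#' Each Ten-Item Personality Inventory domain pairs a directly keyed and a
#' reverse-keyed 7-point item. The domain score is the direct item plus the
#' reversed item re-coded (8 minus its value), giving a 2-14 scale.
#'
#' @param direct_item,reversed_item Likert responses in 1-7 (vectorised).
#' @return Numeric domain score(s) in 2-14.
#' @export
#' @examples
#' tipi_domain_score(7, 1)  # 14, scale maximum
#' tipi_domain_score(4, 4)  # 8, midpoint
tipi_domain_score <- function(direct_item, reversed_item) {
  check_likert <- function(x, what) {
    if (any(!is.na(x) & (x < 1 | x > 7))) {
      stop(what, " must lie in 1-7", call. = FALSE)
    }
  }
  check_likert(direct_item, "direct_item")
  check_likert(reversed_item, "reversed_item")
  direct_item + (8 - reversed_item)
}

#' Partner counts per respondent
#'
#' @param cohort A `mate_cohort` tibble.
#' @return A tibble with `respondent_id` and `n_partners`.
#' @export
partner_counts <- function(cohort) {
  dplyr::count(tibble::as_tibble(cohort), .data$respondent_id,
               name = "n_partners")
}

# Informative slot structure for one trait: drop partners missing the trait,
# then respondents left with < 2 values. Returns NULL if nothing remains.
informative_slots <- function(cohort, trait, registry = trait_registry(cohort)) {
  if (!trait %in% names(cohort)) {
    stop("trait '", trait, "' is not a column of the cohort", call. = FALSE)
  }
  keep <- !is.na(cohort[[trait]])
  sub <- cohort[keep, c("respondent_id", trait)]
  sub <- sub[order(sub$respondent_id), ]
  counts <- table(sub$respondent_id)
  good_ids <- names(counts)[counts >= 2L]
  sub <- sub[sub$respondent_id %in% good_ids, ]
  if (nrow(sub) == 0L) return(NULL)
  group <- match(sub$respondent_id, unique(sub$respondent_id))
  c(new_slots(as.numeric(sub[[trait]]), group),
    list(respondent_id = sub$respondent_id, trait = trait))
}
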