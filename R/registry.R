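#' Trait registry
#'
#' The registry declares every partner characteristic the analyses may touch:
#' its name, family (demographic, physical or personality), scale bounds and
#' whether values are integer-coded. Every analysis function looks traits up
#' here, so a trait used anywhere must appear exactly once in the registry.
#'
#' @details
#' `default_trait_registry()` returns the 21-trait registry of the motivating
#' study design: 3 demographic characteristics (residence size 1-4, education
#' 1-4, age difference in months, negative when the woman is older), 13
#' physical characteristics (weight in kg, height in cm, 7-point Likert
#' attractiveness and masculinity, and ordinal image scales for eye colour
#' 1-5 coded grey to black, hair colour 1-9 light to dark, facial masculinity
#' 1-5, beardedness 1-4, muscularity 1-6, BMI 1-6, relative height 1-6,
#' hirsuteness 1-5 and leg-to-body ratio 1-5), and 5 TIPI personality domains
#' scored 2-14 (see [tipi_domain_score()]).
#'
#' @return A tibble with columns `trait`, `family`, `scale_min`, `scale_max`,
#'   `integer_valued`, `description`.
#' @seealso [read_trait_registry()], [load_cohort()]
#' @export
#' @examples
#' default_trait_registry()
default_trait_registry <- function() {
  tibble::tribble(
    ~trait,               ~family,       ~scale_min, ~scale_max, ~integer_valued, ~description,
    "residence",          "demographic",         1,          4,  TRUE,  "size of residence: metropolis (1) to village (4)",
    "education",          "demographic",         1,          4,  TRUE,  "education level: elementary (1) to university (4)",
    "age_difference",     "demographic",      -360,        360,  FALSE, "partner minus respondent age in months; negative = woman older",
    "weight",             "physical",           40,        140,  FALSE, "body weight in kilograms",
    "height",             "physical",          150,        220,  FALSE, "body height in centimetres",
    "attractiveness",     "physical",            1,          7,  TRUE,  "overall attractiveness, 7-point Likert",
    "masculinity",        "physical",            1,          7,  TRUE,  "overall masculinity, 7-point Likert",
    "eye_color",          "physical",            1,          5,  TRUE,  "eye colour image scale: grey, blue, green, brown, black",
    "hair_color",         "physical",            1,          9,  TRUE,  "hair colour image scale: light blond (1) to black (9)",
    "facial_masculinity", "physical",            1,          5,  TRUE,  "facial masculinity image scale, low to high",
    "beardedness",        "physical",            1,          4,  TRUE,  "beardedness image scale: clean shaven to full beard",
    "muscularity",        "physical",            1,          6,  TRUE,  "muscularity image scale, low to high",
    "bmi",                "physical",            1,          6,  TRUE,  "body-mass-index image scale, low to high",
    "relative_height",    "physical",            1,          6,  TRUE,  "relative height image scale: man much taller to woman taller",
    "hirsuteness",        "physical",            1,          5,  TRUE,  "body hair image scale, low to high",
    "leg_to_body_ratio",  "physical",            1,          5,  TRUE,  "leg-to-body-ratio image scale, short to long legs",
    "extraversion",       "personality",         2,         14,  TRUE,  "TIPI extraversion domain score",
    "agreeableness",      "personality",         2,         14,  TRUE,  "TIPI agreeableness domain score",
    "conscientiousness",  "personality",         2,         14,  TRUE,  "TIPI conscientiousness domain score",
    "emotional_stability","personality",         2,         14,  TRUE,  "TIPI emotional stability domain score",
    "openness",           "personality",         2,         14,  TRUE,  "TIPI openness domain score"
  )
}

#' Read or write a trait registry file
#'
#' Registries are stored as YAML: a list of entries each carrying `trait`,
#' `family`, `scale_min`, `scale_max`, `integer_valued` and optionally
#' `description`.
#'
#' @param path Path to a YAML registry file.
#' @return `read_trait_registry()` returns a validated registry tibble;
#'   `write_trait_registry()` returns `path` invisibly.
#' @export
read_trait_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || length(raw) == 0L) {
    stop("registry file '", path, "' contains no trait entries", call. = FALSE)
  }
  reg <- purrr::map_dfr(raw, function(entry) {
    tibble::tibble(
      trait = as.character(entry$trait),
      family = as.character(entry$family),
      scale_min = as.numeric(entry$scale_min),
      scale_max = as.numeric(entry$scale_max),
      integer_valued = isTRUE(entry$integer_valued),
      description = as.character(entry$description %||% "")
    )
  })
  validate_registry(reg)
  reg
}

#' @rdname read_trait_registry
#' @param registry A registry tibble as returned by [default_trait_registry()].
#' @export
write_trait_registry <- function(registry, path) {
  validate_registry(registry)
  entries <- purrr::pmap(registry, function(trait, family, scale_min, scale_max,
                                            integer_valued, description, ...) {
    list(trait = trait, family = family, scale_min = scale_min,
         scale_max = scale_max, integer_valued = integer_valued,
         description = description)
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}

validate_registry <- function(registry) {
  req <- c("trait", "family", "scale_min", "scale_max", "integer_valued")
  missing_cols <- setdiff(req, names(registry))
  if (length(missing_cols) > 0L) {
    stop("registry is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(registry$trait)) {
    dup <- unique(registry$trait[duplicated(registry$trait)])
    stop("registry lists trait(s) more than once: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_scale <- registry$trait[registry$scale_min >= registry$scale_max]
  if (length(bad_scale) > 0L) {
    stop("scale_min must be below scale_max for: ", paste(bad_scale, collapse = ", "),
         call. = FALSE)
  }
  bad_family <- setdiff(unique(registry$family),
                        c("demographic", "physical", "personality"))
  if (length(bad_family) > 0L) {
    stop("unknown trait family: ", paste(bad_family, collapse = ", "), call. = FALSE)
  }
  invisible(registry)
}

registry_traits <- function(registry) registry$trait

trait_spec <- function(registry, trait) {
  row <- registry[registry$trait == trait, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("trait '", trait, "' is not in the registry", call. = FALSE)
  }
  row
}
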