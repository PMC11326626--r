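#' The default six-category exposure annotation scheme
#'
#' The scheme covers the named-entity categories relevant to occupational
#' substance exposure studies: the substances measured, the people exposed
#' (occupations/job titles), where they work (industries/workplaces), what
#' they do (job tasks/activities), the occupational-hygiene devices used to
#' collect samples, and evidence that sampling was personal (carried in the
#' worker's breathing zone) rather than stationary.
#'
#' @return A tibble with columns `category` and `definition`, one row per
#'   category, in canonical scheme order.
#' @export
#' @examples
#' default_scheme()
default_scheme <- function() {
  tibble::tibble(
    category = c(
      "Substance or Exposure Measured",
      "Occupation/Job Title",
      "Industry/Workplace",
      "Job Task/Activity",
      "OH Measurement Device",
      "Sample Type Personal"
    ),
    definition = c(
      "Names of substances, chemicals or pollutants that are measured or sampled.",
      "Phrases characterising the person or group of people who are the subjects of the exposure study.",
      "Phrases denoting the type of workplace or the industry involved in the sampling series.",
      "Specific, well-defined physical activities carried out by workers as part of their duties.",
      "Phrases naming or describing a device, tool, apparatus or sampling head used to measure workplace exposure levels.",
      "Phrases denoting that collected samples represent personal exposures."
    )
  )
}

#' Load and validate an annotation scheme
#'
#' @param source `NULL` for the default six-category exposure scheme, a
#'   character vector of category names, a data frame with a `category`
#'   column (and optionally a `definition` column), or a path to a JSON file
#'   containing either a vector of names or an object with a `categories`
#'   field.
#'
#' @return A validated scheme tibble with columns `category` and
#'   `definition`.
#' @export
#' @examples
#' load_scheme(c("Chemical", "Disease"))
load_scheme <- function(source = NULL) {
  if (is.null(source)) {
    return(default_scheme())
  }
  if (is.character(source) && length(source) == 1L && file.exists(source)) {
    parsed <- jsonlite::read_json(source, simplifyVector = TRUE)
    if (is.list(parsed) && !is.null(parsed$categories)) {
      source <- parsed$categories
    } else {
      source <- parsed
    }
  }
  if (is.character(source)) {
    scheme <- tibble::tibble(category = source, definition = NA_character_)
  } else if (is.data.frame(source)) {
    if (!"category" %in% names(source)) {
      rlang::abort("A scheme data frame needs a `category` column.",
                   class = "expocorpus_config_error")
    }
    scheme <- tibble::tibble(
      category = as.character(source$category),
      definition = if ("definition" %in% names(source)) {
        as.character(source$definition)
      } else {
        NA_character_
      }
    )
  } else {
    rlang::abort("Unsupported scheme source.",
                 class = "expocorpus_config_error")
  }
  validate_scheme(scheme)
}

validate_scheme <- function(scheme) {
  cats <- scheme$category
  if (length(cats) < 1L) {
    rlang::abort("A scheme must list at least one category.",
                 class = "expocorpus_config_error")
  }
  if (anyNA(cats) || any(!nzchar(trimws(cats)))) {
    rlang::abort("Scheme category names must be non-empty.",
                 class = "expocorpus_config_error")
  }
  if (anyDuplicated(cats)) {
    dup <- unique(cats[duplicated(cats)])
    rlang::abort(
      paste0("Duplicate scheme category name(s): ", paste(dup, collapse = ", ")),
      class = "expocorpus_config_error"
    )
  }
  scheme
}

scheme_categories <- function(scheme) {
  if (is.data.frame(scheme)) scheme$category else as.character(scheme)
}

assert_category <- function(category, scheme) {
  cats <- scheme_categories(scheme)
  bad <- setdiff(category, cats)
  if (length(bad) > 0L) {
    rlang::abort(
      paste0("Category not in scheme: ", paste(bad, collapse = ", ")),
      class = "expocorpus_usage_error"
    )
  }
  invisible(category)
}
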