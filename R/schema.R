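#' Cohort variable schema
#'
#' A schema is a tibble with one row per study variable: its `name`, `kind`
#' (`"binary"` or `"continuous"`), `tier` (`"exogenous_root"`, `"behavior"`,
#' or `"outcome_sink"`), `transform` (`"none"` or `"natural_log"`), and free
#' text `units`. Row order is the canonical variable order used for printing
#' factorizations and writing cohort files.
#'
#' Two built-in variants describe an overweight postmenopausal
#' breast-cancer-survivor cohort: `"total_pa"` (19 variables, total physical
#' activity as a single accelerometer volume measure) and `"mvpa_sedentary"`
#' (20 variables, total activity deconstructed into moderate-to-vigorous
#' activity and sedentary minutes).
#'
#' Tiers encode directional plausibility constraints declaratively:
#' `exogenous_root` variables (age, education, tumor stage, years from
#' diagnosis to study entry, neighborhood walkability) may have no parents,
#' and `outcome_sink` variables (physical and mental SF-36 quality of life)
#' may have no children. [default_blacklist()] turns these into forbidden
#' edges for the structure learner.
#'
#' @param variant `"total_pa"` or `"mvpa_sedentary"`.
#' @return A tibble with columns `name`, `kind`, `tier`, `transform`, `units`.
#' @examples
#' cohort_schema("total_pa")
#' @export
cohort_schema <- function(variant = c("total_pa", "mvpa_sedentary")) {
  variant <- match.arg(variant)
  v <- function(name, kind, tier, transform = "none", units = "") {
    tibble::tibble(name = name, kind = kind, tier = tier,
                   transform = transform, units = units)
  }
  base <- dplyr::bind_rows(
    v("TumorStage", "continuous", "exogenous_root", units = "stage (1-3)"),
    v("YrsDXRND", "continuous", "exogenous_root", units = "years"),
    v("Neighborhood", "continuous", "exogenous_root", units = "NEWS score (0-6)"),
    v("Alcohol", "continuous", "behavior", units = "drinks/month"),
    v("Coping", "continuous", "behavior", units = "MB scale (-16 to 16)"),
    v("Education", "continuous", "exogenous_root", units = "college indicator"),
    v("Age", "continuous", "exogenous_root", units = "years"),
    v("Smoke", "binary", "behavior", units = "ever smoked"),
    v("Insomnia", "binary", "behavior", units = "yes/no"),
    v("Depression", "binary", "behavior", units = "yes/no"),
    v("Sleep1", "continuous", "behavior", units = "PROMIS sleep disturbance"),
    v("Arthritis", "binary", "behavior", units = "yes/no"),
    v("BMI", "continuous", "behavior", units = "kg/m^2"),
    v("Sleep2", "continuous", "behavior", units = "PROMIS sleep impairment"),
    v("QOLp", "continuous", "outcome_sink", units = "SF-36 physical (0-100)"),
    v("QOLm", "continuous", "outcome_sink", units = "SF-36 mental (0-100)"),
    v("loginsulin", "continuous", "behavior", "natural_log", "log pg/mL"),
    v("logcrp", "continuous", "behavior", "natural_log", "log pg/mL")
  )
  act <- if (variant == "total_pa") {
    v("PA", "continuous", "behavior", units = "accelerometer counts/min/day")
  } else {
    dplyr::bind_rows(
      v("MVPA", "continuous", "behavior", units = "min/day"),
      v("Sedentary", "continuous", "behavior", units = "min/day")
    )
  }
  out <- dplyr::bind_rows(base, act)
  validate_schema(out)
  structure(out, class = c("bn_schema", class(out)), variant = variant)
}

validate_schema <- function(schema) {
  if (anyDuplicated(schema$name)) {
    bn_abort("variable names must be unique within a schema")
  }
  stopifnot(all(schema$kind %in% c("binary", "continuous")),
            all(schema$tier %in% c("exogenous_root", "behavior", "outcome_sink")),
            all(schema$transform %in% c("none", "natural_log")))
  bad <- schema$transform == "natural_log" & schema$kind != "continuous"
  if (any(bad)) {
    bn_abort(paste0("natural_log transform is only valid for continuous ",
                    "variables: ", paste(schema$name[bad], collapse = ", ")))
  }
  invisible(schema)
}

#' @export
print.bn_schema <- function(x, ...) {
  cat("<cohort schema: ", attr(x, "variant"), ", ",
      nrow(x), " variables>\n", sep = "")
  NextMethod()
}

schema_binary <- function(schema) schema$name[schema$kind == "binary"]
schema_continuous <- function(schema) schema$name[schema$kind == "continuous"]

#' Tier- and type-derived blacklist of forbidden edge directions
#'
#' Builds the set of parent -> child pairs the structure learner must never
#' consider: anything out of an outcome sink, anything into an exogenous
#' root, and every continuous -> binary pair (the conditional-Gaussian
#' restriction: discrete nodes may only have discrete parents).
#'
#' @param schema A [cohort_schema()] tibble.
#' @param extra Optional tibble/data frame with columns `from`, `to` of
#'   additional forbidden pairs.
#' @return A tibble with columns `from`, `to`, one row per forbidden pair.
#' @export
default_blacklist <- function(schema, extra = NULL) {
  nodes <- schema$name
  sinks <- schema$name[schema$tier == "outcome_sink"]
  roots <- schema$name[schema$tier == "exogenous_root"]
  bins <- schema_binary(schema)
  cont <- schema_continuous(schema)
  pairs <- dplyr::bind_rows(
    tidyr::expand_grid(from = sinks, to = nodes),
    tidyr::expand_grid(from = nodes, to = roots),
    tidyr::expand_grid(from = cont, to = bins)
  )
  if (!is.null(extra)) {
    stopifnot(all(c("from", "to") %in% names(extra)))
    if (!all(extra$from %in% nodes) || !all(extra$to %in% nodes)) {
      bn_abort("extra blacklist pairs reference unknown variables")
    }
    pairs <- dplyr::bind_rows(pairs, tibble::as_tibble(extra[c("from", "to")]))
  }
  pairs <- dplyr::distinct(dplyr::filter(pairs, .data$from != .data$to))
  pairs
}

# blacklist as a logical matrix indexed by node name (fast lookup in search)
blacklist_matrix <- function(blacklist, nodes) {
  m <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (!is.null(blacklist) && nrow(blacklist)) {
    keep <- blacklist$from %in% nodes & blacklist$to %in% nodes
    m[cbind(blacklist$from[keep], blacklist$to[keep])] <- TRUE
  }
  m
}
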