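# Threshold table and exclusion rules driving record classification.

#' Default endpoint threshold table
#'
#' Returns the rule table used by [classify_record()] to turn a quantitative
#' bioactivity record into a class label. Each row gives, for one
#' (activity type, endpoint) pair, the comparator and bound of the positive
#' rule and of the negative rule, expressed in the endpoint's canonical unit
#' (micromolar for concentrations, percent for percent-inhibition,
#' dimensionless for ratios). Records falling in neither region are
#' inconclusive (0.5).
#'
#' Defaults: an inhibition IC50/Ki/EC50 at or below 10 uM is an inhibitor and
#' at or above 50 uM a noninhibitor; percent inhibition at or above 50 is an
#' inhibitor and below 25 a noninhibitor; a substrate-assay efflux ratio (or
#' fold-change) of 2 or more indicates a substrate, below 2 a nonsubstrate;
#' a reported Km with demonstrated transport indicates a substrate; apparent
#' permeability alone is always inconclusive. All bounds are plain data in
#' the returned data frame and can be edited or loaded from YAML with
#' [read_curation_config()].
#'
#' @return data.frame with columns `activity_type`, `endpoint`, `unit_class`,
#'   `pos_cmp`, `pos_value`, `neg_cmp`, `neg_value`.
#' @export
#' @examples
#' default_thresholds()
default_thresholds <- function() {
  tab <- rbind(
    data.frame(activity_type = "inhibition",
               endpoint = c("IC50", "Ki", "EC50"),
               unit_class = "conc_uM",
               pos_cmp = "<=", pos_value = 10, neg_cmp = ">=", neg_value = 50),
    data.frame(activity_type = "inhibition", endpoint = "pct_inhibition",
               unit_class = "percent",
               pos_cmp = ">=", pos_value = 50, neg_cmp = "<", neg_value = 25),
    data.frame(activity_type = "substrate",
               endpoint = c("efflux_ratio", "fold_change"),
               unit_class = "ratio",
               pos_cmp = ">=", pos_value = 2, neg_cmp = "<", neg_value = 2),
    data.frame(activity_type = "substrate", endpoint = "Km",
               unit_class = "conc_uM",
               pos_cmp = ">", pos_value = 0, neg_cmp = NA, neg_value = NA),
    data.frame(activity_type = "substrate", endpoint = "Papp",
               unit_class = "cm_per_s",
               pos_cmp = NA, pos_value = NA, neg_cmp = NA, neg_value = NA)
  )
  rownames(tab) <- NULL
  tab
}

#' Default record exclusion rules
#'
#' Records matched by any rule are marked not-applicable (NA) and never enter
#' the majority vote: ATPase-type assays (binding-affinity readouts that are
#' unreliable for substrate/inhibitor classification), records whose assay
#' measured a different transporter than the one the record is filed under,
#' and records from explicitly excluded sources (e.g. an assay series found
#' inconsistent with all other sources).
#'
#' @param assay_types character vector of assay-type patterns (matched
#'   case-insensitively as substrings of `assay_type`).
#' @param sources character vector of `source_id` values to drop outright.
#' @return list with elements `assay_types` and `sources`.
#' @export
default_exclusions <- function(assay_types = "ATPase", sources = character(0)) {
  list(assay_types = assay_types, sources = sources)
}

# Normalize a value to its endpoint's canonical unit.
# conc_uM: nM -> /1000, uM as-is; percent: percent; ratio: ratio or
# dimensionless; cm_per_s: cm_per_s. Incompatible units -> NA.
normalize_value <- function(value, units, unit_class) {
  out <- rep(NA_real_, length(value))
  uc <- rep_len(unit_class, length(value))
  un <- rep_len(units, length(value))
  conv <- !is.na(value)
  out[conv & uc == "conc_uM" & un == "uM"] <- value[conv & uc == "conc_uM" & un == "uM"]
  sel <- conv & uc == "conc_uM" & un == "nM"
  out[sel] <- value[sel] / 1000
  sel <- conv & uc == "percent" & un == "percent"
  out[sel] <- value[sel]
  sel <- conv & uc == "ratio" & un %in% c("ratio", "dimensionless")
  out[sel] <- value[sel]
  sel <- conv & uc == "cm_per_s" & un == "cm_per_s"
  out[sel] <- value[sel]
  out
}

#' Read a curation configuration (thresholds and exclusions) from YAML
#'
#' The file may carry a `thresholds` block (list of rows with the columns of
#' [default_thresholds()]) and an `exclusions` block with `assay_types` and
#' `sources`. Missing blocks fall back to the defaults, so a config file can
#' override just one side.
#'
#' @param path path to a YAML file.
#' @return list with elements `thresholds` (data.frame) and `exclusions`.
#' @export
read_curation_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  thresholds <- if (!is.null(cfg$thresholds)) {
    rows <- lapply(cfg$thresholds, function(r) {
      data.frame(activity_type = r$activity_type, endpoint = r$endpoint,
                 unit_class = r$unit_class,
                 pos_cmp = r$pos_cmp %||% NA, pos_value = r$pos_value %||% NA,
                 neg_cmp = r$neg_cmp %||% NA, neg_value = r$neg_value %||% NA,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  } else {
    default_thresholds()
  }
  exclusions <- default_exclusions(
    assay_types = unlist(cfg$exclusions$assay_types) %||% "ATPase",
    sources = unlist(cfg$exclusions$sources) %||% character(0)
  )
  list(thresholds = thresholds, exclusions = exclusions)
}
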