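#' Codebook describing the registry columns
#'
#' @return data.frame with columns `name`, `type` (`ordinal`, `binary`,
#'   `continuous`) and `label`.
#' @export
registry_codebook <- function() {
  data.frame(
    name = c("sep_level", "sep_binary", "age", "sex", "diabetes",
             "hypertension", "metropolitan", "public_location", "witnessed",
             "bystander_cpr", "bystander_aed", "rti_lt8", "shockable",
             "ed_level12", "cag", "ttm", "surv_admission", "surv_discharge",
             "good_neuro"),
    type = c("ordinal", "binary", "continuous", rep("binary", 16L)),
    label = c(
      "SEP level (NHI premium quartiles Q1-Q4, MA = medical aid)",
      "Low-SEP indicator under the declared binarization cutoff",
      "Age (years)", "Sex (1 = male)", "Diabetes", "Hypertension",
      "Metropolitan residential region", "Arrest in a public location",
      "Witnessed arrest", "Bystander CPR", "Bystander AED use",
      "EMS response-time interval < 8 min", "Initial shockable rhythm",
      "Receiving ED level 1-2", "Coronary angiography",
      "Targeted temperature management", "Survival to admission",
      "Survival to discharge", "Good neurological recovery (CPC 1-2)"),
    stringsAsFactors = FALSE)
}

#' Write / read a registry table as CSV with a YAML codebook
#'
#' Missing cells are encoded as empty strings; the codebook travels as a YAML
#' side file so column types survive the round trip.
#'
#' @param table registry data.frame.
#' @param path CSV path; the codebook is written to `<path>.codebook.yaml`
#'   unless `codebook_path` is given.
#' @param codebook_path optional explicit codebook path.
#' @return `path`, invisibly (writer); the registry data.frame (reader).
#' @export
write_registry <- function(table, path, codebook_path = NULL) {
  if (is.null(codebook_path)) codebook_path <- paste0(path, ".codebook.yaml")
  utils::write.csv(table, path, row.names = FALSE, na = "")
  cb <- attr(table, "codebook")
  if (is.null(cb)) cb <- registry_codebook()
  cb <- cb[cb$name %in% names(table), , drop = FALSE]
  yaml::write_yaml(
    lapply(seq_len(nrow(cb)), function(i) as.list(cb[i, ])), codebook_path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path, codebook_path = NULL) {
  if (is.null(codebook_path)) codebook_path <- paste0(path, ".codebook.yaml")
  tab <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  if (file.exists(codebook_path)) {
    cb <- do.call(rbind, lapply(yaml::read_yaml(codebook_path), as.data.frame))
    attr(tab, "codebook") <- cb
    ord <- cb$name[cb$type == "ordinal"]
    for (v in intersect(ord, names(tab)))
      if (v == "sep_level") tab[[v]] <- factor(tab[[v]], levels = SEP_LEVELS)
  } else {
    attr(tab, "codebook") <- registry_codebook()
    if ("sep_level" %in% names(tab))
      tab$sep_level <- factor(tab$sep_level, levels = SEP_LEVELS)
  }
  tab
}

#' Serialize / load a synthetic configuration as YAML
#'
#' @param config a `synthetic_config`.
#' @param path YAML file path.
#' @return `path` invisibly; the loader returns a `synthetic_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  # named atomic vectors must become named lists: YAML serialization drops
  # the names of atomic vectors otherwise
  namify <- function(x) {
    if (is.list(x)) lapply(x, namify)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  # precision 17 makes the double round-trip exact
  yaml::write_yaml(namify(unclass(config)), path, precision = 17L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unlist_named <- function(x) if (is.list(x)) unlist(x) else x
  cd <- lapply(raw$confounder_distributions, function(d) lapply(d, unlist_named))
  synthetic_config(
    n_per_group = unlist_named(raw$n_per_group),
    structural_coeffs = lapply(raw$structural_coeffs, unlist_named),
    intercepts = unlist_named(raw$intercepts),
    nhi_margins = unlist_named(raw$nhi_margins),
    link = raw$link,
    confounder_distributions = cd,
    missingness_rates = unlist_named(raw$missingness_rates),
    seed = raw$seed)
}

#' Published cohort summary counts by SEP group
#'
#' Group-level counts of the nationwide Korean OHCA cohort (2013-2019,
#' N = 121 516) by insurance-based SEP group, as printed in the published
#' descriptive table. Used for worked examples: percentages, crude odds
#' ratios and standardized mean differences recomputed from printed counts.
#'
#' @return data.frame with a `variable` column and one count column per SEP
#'   group (`NHI_Q1` ... `MA`); the first row holds the group sizes.
#' @export
cohort_summary_counts <- function() {
  path <- system.file("extdata", "cohort_group_counts.csv",
                      package = "ohcapath", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}

#' Expand grouped counts into a subject-level binary table
#'
#' Turns one row of [cohort_summary_counts()] (events per group) into a
#' subject-level data.frame with `sep_level` and a 0/1 column, enabling exact
#' reconstruction of printed percentages and odds ratios with the same code
#' paths used for full registry tables.
#'
#' @param counts data.frame as returned by [cohort_summary_counts()].
#' @param variable which count row to expand.
#' @param groups which SEP groups to include (default all five).
#' @return data.frame with columns `sep_level` and `variable`.
#' @export
expand_counts <- function(counts, variable, groups = SEP_LEVELS) {
  nrow_ <- unlist(counts[counts$variable == "n", groups])
  ev <- unlist(counts[counts$variable == variable, groups])
  if (!length(ev)) stop("variable not found in counts: ", variable)
  out <- data.frame(
    sep_level = factor(rep(rep(groups, times = 2L), c(ev, nrow_ - ev)),
                       levels = SEP_LEVELS))
  out[[variable]] <- rep(rep(c(1L, 0L), each = length(groups)),
                         c(ev, nrow_ - ev))
  out
}
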