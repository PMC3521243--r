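# Activity filtering: the gate every bioactivity must pass before it can
# contribute to seeding or mapping. A qualifying activity is a direct,
# unambiguous binding-assay measurement (assay type B, multi/complex flags
# both 0) of an allowed activity type whose potency is at least as strong as
# the threshold (default 50 uM, boundary inclusive).

# molar multipliers for supported concentration units ("uM" and the micro
# sign spelling are both accepted)
.unit_factors <- c("M" = 1, "mM" = 1e-3, "uM" = 1e-6, "µM" = 1e-6,
                   "nM" = 1e-9, "pM" = 1e-12)

#' Activity filter configuration
#'
#' Bundles the filter parameters: required assay type, the controlled
#' vocabulary of activity types, the potency threshold in molar units, and
#' which types are on a -log10(molar) scale. Log-scale types (-Log Ki, pKd,
#' pA2, pI, pKa) carry no concentration unit and are compared against
#' `-log10(threshold_molar)`; pA2/pI/pKa are treated as log-potency values
#' alongside pKd even though their physical meaning differs, because they
#' share one vocabulary and one threshold — records of these types are noted
#' in the log.
#'
#' @param assay_type Required single-letter assay code (default `"B"`,
#'   binding assay).
#' @param allowed_types Controlled vocabulary of activity types.
#' @param threshold_molar Potency cutoff in mol/L (default `5e-5`, i.e.
#'   50 uM); records at least this potent are kept, boundary inclusive.
#' @param log_types Subset of `allowed_types` measured as -log10(molar).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(assay_type = "B",
                          allowed_types = c("Ki", "Kd", "IC50", "EC50",
                                            "-Log Ki", "pKd", "pA2", "pI", "pKa"),
                          threshold_molar = 5e-5,
                          log_types = c("-Log Ki", "pKd", "pA2", "pI", "pKa")) {
  if (!is.numeric(threshold_molar) || threshold_molar <= 0)
    stop("threshold_molar must be > 0", call. = FALSE)
  if (!all(log_types %in% allowed_types))
    stop("log_types must be a subset of allowed_types", call. = FALSE)
  structure(list(assay_type = assay_type,
                 allowed_types = allowed_types,
                 threshold_molar = threshold_molar,
                 log_types = log_types),
            class = "filter_config")
}

#' Filter activities to qualifying records
#'
#' Applies the qualifying-activity rule: assay type matches, neither the
#' multi- nor the complex-flag is set, the activity type belongs to the
#' allowed vocabulary, and the potency is at least as strong as the
#' threshold. Concentration-type records are converted to molar with their
#' `unit` and kept when `value_molar <= threshold_molar`; log-scale records
#' are kept when `value >= -log10(threshold_molar)`. Records with an
#' unsupported unit on a concentration type are rejected (with a logged
#' reason), never guessed at.
#'
#' @param activities Activity `data.frame` from [read_activities()].
#' @param config A [filter_config()].
#' @param verbose Log per-reason rejection counts to stderr.
#' @return The qualifying subset, with an attribute `rejections` giving the
#'   per-reason counts (so row counts are conserved:
#'   `nrow(input) == nrow(output) + sum(rejections)`).
#' @export
filter_activities <- function(activities, config = filter_config(),
                              verbose = TRUE) {
  stopifnot(inherits(config, "filter_config"))
  n <- nrow(activities)
  reason <- rep(NA_character_, n)

  ok_assay <- activities$assay_type == config$assay_type
  reason[is.na(reason) & !ok_assay] <- "assay_type"
  flagged <- activities$multi | activities$complex
  reason[is.na(reason) & flagged] <- "flagged"
  ok_type <- activities$type %in% config$allowed_types
  reason[is.na(reason) & !ok_type] <- "activity_type"

  is_log <- activities$type %in% config$log_types
  log_cut <- -log10(config$threshold_molar)

  # concentration types: need a supported unit
  conc <- !is_log
  factor <- .unit_factors[activities$unit]
  bad_unit <- conc & is.na(factor)
  reason[is.na(reason) & bad_unit] <- "unsupported_unit"

  molar <- activities$value * factor
  weak_conc <- conc & !is.na(factor) & !(molar <= config$threshold_molar)
  weak_log <- is_log & !(activities$value >= log_cut)
  reason[is.na(reason) & (weak_conc | weak_log)] <- "weak"

  bad_value <- !is.finite(activities$value)
  reason[bad_value & is.na(reason)] <- "missing_value"

  keep <- is.na(reason)
  rejections <- table(factor(reason[!keep],
                             levels = c("assay_type", "flagged", "activity_type",
                                        "unsupported_unit", "weak", "missing_value")))
  if (verbose) {
    for (r in names(rejections))
      if (rejections[[r]] > 0L)
        lig_log("INFO", "filter", sprintf("rejected %d record(s): %s",
                                          rejections[[r]], r))
    n_odd <- sum(keep & activities$type %in% intersect(config$log_types,
                                                       c("pA2", "pI", "pKa")))
    if (n_odd > 0L)
      lig_log("INFO", "filter",
              sprintf("%d kept record(s) have type pA2/pI/pKa, compared on the log-potency scale", n_odd))
  }
  out <- activities[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- c(rejections)
  out
}
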