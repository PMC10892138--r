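# Distribution-learning evaluation ---------------------------------------------------
#
# The standard distribution-learning summary of a generated set: validity
# (fraction of strings that parse), uniqueness (distinct canonical SMILES
# among the valid ones), novelty (distinct canonical SMILES absent from the
# training set) and mean QED over the valid molecules.  Denominators follow
# the GuacaMol convention: uniqueness over valid, novelty over unique-valid.

#' Compute validity / uniqueness / novelty / mean QED
#'
#' @param generated Character vector of generated SMILES (possibly invalid).
#' @param training_set Character vector of canonical training-set SMILES
#'   against which novelty is judged (membership on canonical strings).
#' @return A `metrics_report`: list with `validity`, `uniqueness`, `novelty`,
#'   `mean_qed`, `n_generated`.
#' @export
compute_metrics <- function(generated, training_set = character(0)) {
  stopifnot(is.character(generated), length(generated) >= 1L,
            is.character(training_set))
  valid <- is_valid_smiles(generated)
  n_valid <- sum(valid)
  if (n_valid == 0L) {
    report <- list(validity = 0, uniqueness = 0, novelty = 0,
                   mean_qed = NA_real_, n_generated = length(generated))
    class(report) <- "metrics_report"
    return(report)
  }
  canonical <- canonicalize_smiles(generated[valid])
  distinct <- unique(canonical)
  report <- list(
    validity = n_valid / length(generated),
    uniqueness = length(distinct) / n_valid,
    novelty = sum(!(distinct %in% training_set)) / length(distinct),
    mean_qed = mean(compute_qed(generated[valid])),
    n_generated = length(generated))
  class(report) <- "metrics_report"
  report
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> n =", x$n_generated, "\n")
  cat(sprintf("  validity    %.3f\n", x$validity))
  cat(sprintf("  uniqueness  %.3f\n", x$uniqueness))
  cat(sprintf("  novelty     %.3f\n", x$novelty))
  cat(sprintf("  mean QED    %.3f\n", x$mean_qed))
  invisible(x)
}

#' Physicochemical property report
#'
#' Per-molecule descriptor table (MW, logP, rings, HBD, HBA, rotatable
#' bonds) over the valid members of a generated set, with min/max/mean
#' summaries — the numbers behind property-distribution plots and
#' Rule-of-Five adherence checks.
#'
#' @param generated Character vector of SMILES; invalid entries are skipped
#'   (at least one must be valid).
#' @return A `property_report`: list with `table` (one row per valid
#'   molecule) and `summary` (min/max/mean per descriptor).
#' @export
property_report <- function(generated) {
  stopifnot(is.character(generated), length(generated) >= 1L)
  valid <- is_valid_smiles(generated)
  if (!any(valid)) {
    stop("property report needs at least one valid molecule")
  }
  tab <- compute_descriptors(generated[valid])
  num_cols <- c("mw", "logp", "hbd", "hba", "rotatable_bonds", "rings")
  summ <- t(vapply(num_cols, function(col) {
    c(min = min(tab[[col]]), max = max(tab[[col]]), mean = mean(tab[[col]]))
  }, numeric(3)))
  structure(list(table = tab, summary = as.data.frame(summ),
                 n_valid = sum(valid), n_input = length(generated)),
            class = "property_report")
}

#' @export
print.property_report <- function(x, ...) {
  cat("<property_report> ", x$n_valid, " valid of ", x$n_input,
      " molecules\n", sep = "")
  print(round(x$summary, 3))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_metrics_json <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a property table as TSV
#'
#' @param report A `property_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_property_tsv <- function(report, path) {
  stopifnot(inherits(report, "property_report"))
  utils::write.table(report$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
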