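## The four sample reports: absolute/relative read abundance, error
## profile, error distribution, and run parameters, plus the per-read
## truth table. JSON is the canonical machine format; TSV mirrors the
## tabular reports for spreadsheet use.

#' Build an abundance report table
#'
#' @param resolved a `resolved_abundance` from [resolve_abundances()].
#' @return data frame with columns `organism`, `absolute_RA`,
#'   `relative_RA_percent` (rounded to 3 decimals -- enough to
#'   represent abundances down to 0.0005% of the total) and `taxon`.
#' @export
abundance_report <- function(resolved) {
  stopifnot(inherits(resolved, "resolved_abundance"), resolved$total > 0)
  data.frame(
    organism = names(resolved$counts),
    absolute_RA = unname(resolved$counts),
    relative_RA_percent = round(100 * unname(resolved$counts) / resolved$total,
                                3),
    taxon = unname(resolved$taxon),
    stringsAsFactors = FALSE)
}

#' Build a run-parameters report
#'
#' A complete, replayable record of a run: the full design (feedable
#' back to [parse_design()]), the error profile actually used, the
#' effective seed, the resolved per-organism counts and the package
#' version. Re-running the simulator on this file reproduces the sample
#' byte for byte.
#'
#' @param design a [sample_design()].
#' @param profile the [error_profile()] used.
#' @param resolved the `resolved_abundance` used.
#' @param seed the effective seed of the run.
#' @return a plain list ready for JSON serialisation.
#' @export
run_parameters_report <- function(design, profile, resolved = NULL,
                                  seed = design$seed) {
  out <- list(
    tool = "nanomock",
    version = as.character(utils::packageVersion("nanomock")),
    seed = as.integer(seed),
    design = design_to_list(design),
    error_profile = unclass(profile))
  out$design$seed <- as.integer(seed) # replay uses the effective seed
  if (!is.null(resolved)) {
    out$resolved_counts <- as.list(resolved$counts)
    out$total_reads <- resolved$total
  }
  out
}

## Assemble the in-memory bundle returned by simulate_sample().
report_bundle <- function(design, resolved, profile, error_distribution,
                          seed, name) {
  ab <- abundance_report(resolved)
  stopifnot(sum(ab$absolute_RA) == resolved$total,
            abs(sum(ab$relative_RA_percent) - 100) <= 0.01)
  structure(list(
    name = name,
    abundance = ab,
    error_profile = profile,
    error_distribution = error_distribution,
    run_parameters = run_parameters_report(design, profile, resolved, seed)),
    class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>", x$name, "-", sum(x$abundance$absolute_RA),
      "reads over", nrow(x$abundance), "organism(s)\n")
  print(x$abundance)
  print(x$error_distribution)
  invisible(x)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  path
}

write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write a report bundle to disk
#'
#' Emits `<name>_abundance.tsv/.json` (with a totals row in the TSV),
#' `<name>_error_profile.json`, `<name>_error_distribution.tsv/.json`,
#' `<name>_run_parameters.json` and, when `truth` is given,
#' `<name>_truth.tsv`.
#'
#' @param bundle a `report_bundle`.
#' @param output_dir destination directory.
#' @param truth optional per-read truth data frame.
#' @return named character vector of the written paths, invisibly.
#' @export
write_report_bundle <- function(bundle, output_dir, truth = NULL) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(suffix) file.path(output_dir, paste0(bundle$name, suffix))

  ab <- bundle$abundance
  ab_tot <- rbind(ab, data.frame(organism = "TOTAL",
                                 absolute_RA = sum(ab$absolute_RA),
                                 relative_RA_percent = sum(ab$relative_RA_percent),
                                 taxon = NA_character_))
  files <- c(
    abundance_tsv = write_tsv_report(ab_tot, p("_abundance.tsv")),
    abundance_json = write_json_report(ab, p("_abundance.json")),
    error_profile = write_json_report(unclass(bundle$error_profile),
                                      p("_error_profile.json")),
    error_distribution_tsv = write_tsv_report(
      error_distribution_table(bundle$error_distribution),
      p("_error_distribution.tsv")),
    error_distribution_json = write_json_report(
      c(list(totals = as.list(bundle$error_distribution$totals),
             rates = as.list(bundle$error_distribution$rates)),
        unclass(bundle$error_distribution)[
          c("accuracy", "template_bases", "n_reads", "per_organism")]),
      p("_error_distribution.json")),
    run_parameters = write_json_report(bundle$run_parameters,
                                       p("_run_parameters.json")))
  if (!is.null(truth)) {
    cols <- c("read_id", "organism", "contig", "start", "end", "strand",
              "fragment_length", "n_sub", "n_ins", "n_del")
    files <- c(files, truth = write_tsv_report(truth[, cols], p("_truth.tsv")))
  }
  invisible(files)
}

error_distribution_table <- function(dist) {
  if (!is.null(dist$per_organism)) return(dist$per_organism)
  data.frame(organism = "ALL", n_reads = dist$n_reads,
             template_bases = dist$template_bases,
             n_sub = dist$totals[["n_sub"]], n_ins = dist$totals[["n_ins"]],
             n_del = dist$totals[["n_del"]], accuracy = dist$accuracy,
             stringsAsFactors = FALSE)
}
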