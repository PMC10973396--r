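#' Construct replicated Line x Tester trial data
#'
#' Validates plot-level observations from a balanced Line x Tester trial:
#' every line x tester x replication cell must be present for each trait.
#'
#' @param records Data frame with columns `line`, `tester`, `rep`, `trait`,
#'   `value` (long format, one row per plot observation per trait).
#' @return An object of class `trial_data`: the records tibble plus the design
#'   summary (`l` lines, `t` testers, `r` replications) as attributes,
#'   accessible via `design_summary()`.
#' @export
trial_data <- function(records) {
  records <- as_tibble(records)
  need <- c("line", "tester", "rep", "trait", "value")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Trial records need columns: ", toString(missing_cols)))
  }
  records <- records[need]
  records$line <- as.character(records$line)
  records$tester <- as.character(records$tester)
  records$rep <- as.integer(records$rep)
  if (!is.numeric(records$value) || anyNA(records$value)) {
    abort("Trial `value` must be numeric with no missing values.")
  }
  lines <- sort(unique(records$line))
  testers <- sort(unique(records$tester))
  reps <- sort(unique(records$rep))
  traits <- sort(unique(records$trait))

  full <- tidyr::expand_grid(line = lines, tester = testers,
                             rep = reps, trait = traits)
  got <- dplyr::distinct(records, .data$line, .data$tester, .data$rep,
                         .data$trait)
  missing_cells <- dplyr::anti_join(full, got,
                                    by = c("line", "tester", "rep", "trait"))
  if (nrow(missing_cells) > 0) {
    cells <- paste0("(", missing_cells$line, ", ", missing_cells$tester,
                    ", rep ", missing_cells$rep, ", ", missing_cells$trait, ")")
    abort(paste0("Unbalanced trial; missing plots: ",
                 toString(head(cells, 10)),
                 if (length(cells) > 10) " ..." else ""))
  }
  if (nrow(records) != nrow(full)) {
    abort("Duplicate plot observations present; expected exactly one value per line x tester x rep x trait.")
  }
  structure(records,
            class = c("trial_data", class(records)),
            design = list(l = length(lines), t = length(testers),
                          r = length(reps), lines = lines, testers = testers,
                          traits = traits))
}

#' Design summary of a trial
#'
#' @param trial A [trial_data()] object.
#' @return List with `l`, `t`, `r`, the line/tester ids and trait names.
#' @export
design_summary <- function(trial) {
  stopifnot(inherits(trial, "trial_data"))
  attr(trial, "design")
}

#' Read a Line x Tester trial from a long-format CSV/TSV
#'
#' @param path File with columns `line`, `tester`, `rep`, `trait`, `value`.
#' @return A validated [trial_data()] with inferred design dimensions.
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  trial_data(read_delim_auto(path))
}

#' Write trial records to CSV
#'
#' Rows are written in canonical order (line, tester, rep, trait) so that a
#' read/write round trip reproduces the records.
#'
#' @param trial A [trial_data()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "trial_data"))
  out <- dplyr::arrange(as_tibble(trial), .data$line, .data$tester,
                        .data$rep, .data$trait)
  readr::write_csv(out, path)
  invisible(path)
}
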