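#' Mid-parent heterosis
#'
#' Percent deviation of the F1 mean from the mid-parent value
#' `MP = (p1 + p2) / 2`: `100 * (f1 - MP) / MP`.
#'
#' @param f1 F1 cross mean(s).
#' @param p1,p2 The two parent means.
#' @return Heterosis in percent (vectorized).
#' @export
mid_parent_heterosis <- function(f1, p1, p2) {
  mp <- (p1 + p2) / 2
  if (any(mp == 0)) abort("Mid-parent value is zero; heterosis undefined.")
  100 * (f1 - mp) / mp
}

#' Better-parent heterosis (heterobeltiosis)
#'
#' Percent deviation of the F1 mean from the better parent, taken as the
#' larger parent mean regardless of whether a high or a low value is
#' agronomically desirable: `100 * (f1 - BP) / BP` with `BP = max(p1, p2)`.
#'
#' @inheritParams mid_parent_heterosis
#' @return Heterobeltiosis in percent (vectorized).
#' @export
better_parent_heterosis <- function(f1, p1, p2) {
  bp <- pmax(p1, p2)
  if (any(bp == 0)) abort("Better-parent value is zero; heterosis undefined.")
  100 * (f1 - bp) / bp
}

#' Heterosis table for all crosses and traits
#'
#' Joins per-cross F1 means with the two parents' means and computes
#' mid-parent (MPH) and better-parent (BPH) heterosis for every cross x
#' trait combination. Values are kept at full precision; round only for
#' reporting.
#'
#' @param parents Wide data frame: a `parent` id column plus one numeric
#'   column per trait.
#' @param hybrids Wide data frame: `line` and `tester` id columns plus one
#'   numeric column per trait (the F1 means).
#' @param design Optional [build_lxt_design()] tibble restricting which
#'   crosses are evaluated; by default all rows of `hybrids` are used.
#' @return A tibble of class `heterosis_tbl` with columns `line`, `tester`,
#'   `cross`, `trait`, `f1`, `p_line`, `p_tester`, `mp`, `bp`, `mph`, `bph`.
#' @export
heterosis_table <- function(parents, hybrids, design = NULL) {
  parents <- as_tibble(parents)
  hybrids <- as_tibble(hybrids)
  if (!"parent" %in% names(parents)) abort("`parents` needs a `parent` column.")
  if (!all(c("line", "tester") %in% names(hybrids))) {
    abort("`hybrids` needs `line` and `tester` columns.")
  }
  if (!is.null(design)) {
    hybrids <- dplyr::semi_join(hybrids, design, by = c("line", "tester"))
  }
  unknown <- setdiff(unique(c(hybrids$line, hybrids$tester)), parents$parent)
  if (length(unknown) > 0) {
    abort(paste0("Crosses reference unknown parents: ", toString(unknown)))
  }
  traits <- intersect(setdiff(names(hybrids), c("line", "tester", "cross")),
                      names(parents))
  pl <- tidyr::pivot_longer(parents[c("parent", traits)], -"parent",
                            names_to = "trait", values_to = "pv")
  out <- hybrids[c("line", "tester", traits)] |>
    tidyr::pivot_longer(-c("line", "tester"),
                        names_to = "trait", values_to = "f1") |>
    dplyr::left_join(setNames(pl, c("line", "trait", "p_line")),
                     by = c("line", "trait")) |>
    dplyr::left_join(setNames(pl, c("tester", "trait", "p_tester")),
                     by = c("tester", "trait")) |>
    dplyr::mutate(
      cross = cross_id(.data$tester, .data$line),
      mp = (.data$p_line + .data$p_tester) / 2,
      bp = pmax(.data$p_line, .data$p_tester),
      mph = mid_parent_heterosis(.data$f1, .data$p_line, .data$p_tester),
      bph = better_parent_heterosis(.data$f1, .data$p_line, .data$p_tester)
    ) |>
    dplyr::select("line", "tester", "cross", "trait", "f1", "p_line",
                  "p_tester", "mp", "bp", "mph", "bph")
  class(out) <- c("heterosis_tbl", class(out))
  out
}

#' Annotate a heterosis table with t-test significance
#'
#' Standard line-by-tester tests of the F1 against the mid- and better-parent
#' values: `t_MP = (F1 - MP) / sqrt(3 * MSE / (2 r))` and
#' `t_BP = (F1 - BP) / sqrt(2 * MSE / r)`, with two-sided p-values from the t
#' distribution on the error degrees of freedom. Stars: `*` for p < 0.05,
#' `**` for p < 0.01, `ns` otherwise.
#'
#' @param ht A [heterosis_table()] result.
#' @param mse Error mean square, either a single value applied to all traits
#'   or a data frame with columns `trait` and `mse`.
#' @param r Number of replications (>= 2).
#' @param error_df Error degrees of freedom of the trial ANOVA.
#' @return `ht` with columns `t_mph`, `p_mph`, `sig_mph`, `t_bph`, `p_bph`,
#'   `sig_bph` appended. With `mse = NULL` the annotation is skipped with a
#'   warning and the table is returned unchanged (printed mean tables carry
#'   no error variance).
#' @export
heterosis_significance <- function(ht, mse, r, error_df) {
  stopifnot(inherits(ht, "heterosis_tbl"))
  if (is.null(mse)) {
    warn("No error mean square supplied; significance annotation skipped.")
    return(ht)
  }
  if (r < 2) abort("`r` must be >= 2.")
  if (is.data.frame(mse)) {
    ht <- dplyr::left_join(ht, as_tibble(mse)[c("trait", "mse")], by = "trait")
  } else {
    if (any(mse <= 0)) abort("`mse` must be positive.")
    ht$mse <- mse
  }
  if (any(ht$mse <= 0, na.rm = TRUE)) abort("`mse` must be positive.")
  stars <- function(p) ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))
  out <- ht |>
    dplyr::mutate(
      t_mph = (.data$f1 - .data$mp) / sqrt(3 * .data$mse / (2 * r)),
      p_mph = 2 * pt(abs(.data$t_mph), df = error_df, lower.tail = FALSE),
      sig_mph = stars(.data$p_mph),
      t_bph = (.data$f1 - .data$bp) / sqrt(2 * .data$mse / r),
      p_bph = 2 * pt(abs(.data$t_bph), df = error_df, lower.tail = FALSE),
      sig_bph = stars(.data$p_bph)
    )
  class(out) <- c("heterosis_tbl", class(as_tibble(out)))
  out
}

#' Reshape a heterosis table to report layout
#'
#' One row per cross, MPH/BPH column pairs per trait, rounded to 2 decimals
#' as printed in field reports.
#'
#' @param ht A [heterosis_table()] result.
#' @param digits Rounding for report values.
#' @return A wide tibble.
#' @export
heterosis_wide <- function(ht, digits = 2) {
  stopifnot(inherits(ht, "heterosis_tbl"))
  ht |>
    dplyr::mutate(mph = round(.data$mph, digits),
                  bph = round(.data$bph, digits)) |>
    dplyr::select("cross", "trait", "mph", "bph") |>
    tidyr::pivot_wider(names_from = "trait",
                       values_from = c("mph", "bph"),
                       names_glue = "{trait}_{.value}")
}
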