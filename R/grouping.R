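#' Extract nested heterotic groups from a dendrogram
#'
#' Cuts the tree at `k_major` (the major populations, e.g. restorer vs
#' CMS/B/SFP material) and at `k_sub` (the fine heterotic groups) and checks
#' that the sub-clusters nest inside the major clusters, which is guaranteed
#' for cuts of the same tree.
#'
#' @param dend A [ward_d2_linkage()] result.
#' @param k_major Number of major clusters (default 2).
#' @param k_sub Number of sub-clusters (default 12).
#' @return Object of class `heterotic_grouping`: a tibble with columns
#'   `genotype`, `major`, `sub`.
#' @export
extract_heterotic_groups <- function(dend, k_major = 2, k_sub = 12) {
  stopifnot(inherits(dend, "ward_dendrogram"))
  if (!(k_major <= k_sub && k_sub <= dend$n)) {
    abort("Need k_major <= k_sub <= number of leaves.")
  }
  major <- cut_dendrogram(dend, k = k_major)
  sub <- cut_dendrogram(dend, k = k_sub)
  nesting <- table(sub, major)
  if (any(rowSums(nesting > 0) != 1)) {
    abort("Internal error: sub-clusters do not nest inside major clusters.")
  }
  out <- tibble(genotype = dend$labels, major = unname(major),
                sub = unname(sub))
  class(out) <- c("heterotic_grouping", class(out))
  out
}

#' Select one representative parent per heterotic group
#'
#' For each sub-cluster, picks the eligible genotype with the maximum value
#' of `trait` (by default seed yield per plant). Ties are broken towards the
#' lexicographically smallest genotype id.
#'
#' @param grouping A [extract_heterotic_groups()] result.
#' @param panel The [germplasm_panel()] the grouping was derived from.
#' @param trait Trait used as the selection criterion (default `"SYP"`).
#' @param eligible_types `NULL` (all line types eligible), a character vector
#'   applied to every sub-cluster, or a named list mapping major-cluster
#'   label to the allowed line types within it (e.g.
#'   `list("1" = "R", "2" = "CMS")`).
#' @return Tibble with one row per sub-cluster: `major`, `sub`, `genotype`,
#'   `line_type` and the selection trait value.
#' @export
select_group_representatives <- function(grouping, panel, trait = "SYP",
                                         eligible_types = NULL) {
  stopifnot(inherits(grouping, "heterotic_grouping"),
            inherits(panel, "germplasm_panel"))
  if (!trait %in% names(panel$traits)) {
    abort(paste0("Trait `", trait, "` not present in panel."))
  }
  df <- dplyr::inner_join(
    as_tibble(grouping),
    dplyr::bind_cols(panel$info, value = panel$traits[[trait]]),
    by = "genotype"
  )
  if (nrow(df) != nrow(grouping)) {
    abort("Grouping and panel genotypes do not match.")
  }
  eligible <- function(major, type) {
    if (is.null(eligible_types)) return(rep(TRUE, length(type)))
    if (is.list(eligible_types)) {
      allowed <- eligible_types[[as.character(major[1])]]
      if (is.null(allowed)) rep(TRUE, length(type)) else type %in% allowed
    } else {
      type %in% eligible_types
    }
  }
  picked <- df |>
    dplyr::group_by(.data$sub) |>
    dplyr::group_map(function(g, key) {
      ok <- g[eligible(g$major, g$line_type), , drop = FALSE]
      if (nrow(ok) == 0) {
        abort(paste0("Sub-cluster ", key$sub,
                     " has no genotype of an eligible line type."))
      }
      ok <- ok[order(-ok$value, ok$genotype), ]
      dplyr::bind_cols(sub = key$sub, ok[1, c("major", "genotype",
                                              "line_type", "value")])
    }) |>
    dplyr::bind_rows()
  names(picked)[names(picked) == "value"] <- trait
  dplyr::arrange(picked[c("major", "sub", "genotype", "line_type", trait)],
                 .data$sub)
}

#' Build a full-factorial Line x Tester cross design
#'
#' Every line (CMS female) is crossed with every tester (restorer male);
#' cross ids are rendered `"TESTER x LINE"` with a multiplication sign,
#' matching the usual field-book convention for these crosses.
#'
#' @param lines Character vector of line (female) parent ids.
#' @param testers Character vector of tester (male) parent ids, disjoint from
#'   `lines`.
#' @return Tibble with columns `line`, `tester`, `cross` and `length(lines) *
#'   length(testers)` rows.
#' @export
build_lxt_design <- function(lines, testers) {
  lines <- as.character(lines)
  testers <- as.character(testers)
  if (length(lines) == 0 || length(testers) == 0) {
    abort("`lines` and `testers` must be non-empty.")
  }
  overlap <- intersect(lines, testers)
  if (length(overlap) > 0) {
    abort(paste0("Parents cannot be both line and tester: ",
                 toString(overlap)))
  }
  out <- tidyr::expand_grid(line = lines, tester = testers)
  out$cross <- cross_id(out$tester, out$line)
  out
}

cross_id <- function(tester, line) paste(tester, "×", line)
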