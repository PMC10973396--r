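#' Construct and validate a germplasm panel
#'
#' A germplasm panel holds, in shared row order, one row per genotype:
#' an identifier, a line-type class (one of `r toString(line_type_levels)`),
#' a matrix of continuous agro-morphological traits, and optional binary
#' band-presence blocks for SSR markers and seed-protein profiles.
#'
#' @param info Data frame with columns `genotype` (unique ids) and `line_type`.
#' @param traits Data frame of non-negative numeric trait columns, same row
#'   order as `info`.
#' @param ssr,protein Optional data frames of 0/1 band indicator columns.
#' @param impute If `TRUE`, missing trait values are replaced by the column
#'   mean; by default missing values are rejected.
#'
#' @return An object of class `germplasm_panel`: a list with tibbles `info`,
#'   `traits`, `ssr`, `protein`.
#' @export
germplasm_panel <- function(info, traits, ssr = NULL, protein = NULL,
                            impute = FALSE) {
  info <- as_tibble(info)
  if (!all(c("genotype", "line_type") %in% names(info))) {
    abort("`info` must have columns `genotype` and `line_type`.")
  }
  info$genotype <- as.character(info$genotype)
  dup <- info$genotype[duplicated(info$genotype)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate genotype ids: ", toString(unique(dup))))
  }
  bad_type <- setdiff(unique(info$line_type), line_type_levels)
  if (length(bad_type) > 0) {
    abort(paste0("Unknown line types: ", toString(bad_type),
                 " (expected ", toString(line_type_levels), ")"))
  }
  n <- nrow(info)

  traits <- as_tibble(traits)
  if (nrow(traits) != n) abort("`traits` must have one row per genotype.")
  not_num <- names(traits)[!vapply(traits, is.numeric, logical(1))]
  if (length(not_num) > 0) {
    abort(paste0("Non-numeric trait columns: ", toString(not_num)))
  }
  if (anyNA(traits)) {
    if (impute) {
      traits <- dplyr::mutate(traits, dplyr::across(
        dplyr::everything(),
        ~ ifelse(is.na(.x), mean(.x, na.rm = TRUE), .x)
      ))
    } else {
      na_cols <- names(traits)[vapply(traits, anyNA, logical(1))]
      abort(paste0("Missing trait values in: ", toString(na_cols),
                   ". Set `impute = TRUE` to use column means."))
    }
  }
  if (any(as.matrix(traits) < 0) || any(!is.finite(as.matrix(traits)))) {
    abort("Trait values must be finite and non-negative.")
  }

  check_binary <- function(block, label) {
    if (is.null(block)) return(tibble(.rows = n))
    block <- as_tibble(block)
    if (nrow(block) != n) abort(paste0("`", label, "` must have one row per genotype."))
    m <- as.matrix(block)
    bad <- which(!(m %in% c(0, 1)) | is.na(m))
    if (length(bad) > 0) {
      ij <- arrayInd(bad, dim(m))
      cells <- paste0(info$genotype[ij[, 1]], "/", colnames(m)[ij[, 2]],
                      "=", m[bad])
      abort(paste0("Non-binary values in ", label, " block: ",
                   toString(head(cells, 10)),
                   if (length(cells) > 10) " ..." else ""))
    }
    dplyr::mutate(block, dplyr::across(dplyr::everything(), as.integer))
  }
  ssr <- check_binary(ssr, "ssr")
  protein <- check_binary(protein, "protein")

  structure(list(info = info, traits = traits, ssr = ssr, protein = protein),
            class = "germplasm_panel")
}

#' @export
print.germplasm_panel <- function(x, ...) {
  cat("<germplasm_panel> ", nrow(x$info), " genotypes\n", sep = "")
  cat("  line types: ",
      paste(names(table(x$info$line_type)), table(x$info$line_type),
            sep = "=", collapse = ", "), "\n", sep = "")
  cat("  traits: ", ncol(x$traits), " | ssr bands: ", ncol(x$ssr),
      " | protein bands: ", ncol(x$protein), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.germplasm_panel <- function(x, ...) {
  dplyr::bind_cols(x$info, x$traits, x$ssr, x$protein)
}

#' Default panel file schema
#'
#' Maps source-file column headers to the panel blocks. `traits` may be a
#' named character vector (`canonical = source_header`) to rename arbitrary
#' headers to the canonical trait abbreviations; `ssr_prefix`/`protein_prefix`
#' select band columns by header prefix unless explicit column vectors
#' `ssr`/`protein` are given.
#'
#' @param id,type Source column names for genotype id and line type.
#' @param traits Character vector of trait columns (optionally named by
#'   canonical trait name).
#' @param ssr,protein Explicit band column names, or `NULL` to use prefixes.
#' @param ssr_prefix,protein_prefix Header prefixes for band columns.
#' @return A list usable as the `schema` argument of [read_panel()].
#' @export
panel_schema <- function(id = "genotype", type = "line_type",
                         traits = trait_names,
                         ssr = NULL, protein = NULL,
                         ssr_prefix = "SSR_", protein_prefix = "PB_") {
  list(id = id, type = type, traits = traits, ssr = ssr, protein = protein,
       ssr_prefix = ssr_prefix, protein_prefix = protein_prefix)
}

#' Read a germplasm panel from CSV/TSV
#'
#' @param path Path to a delimited file (comma or tab, inferred from the
#'   extension: `.tsv`/`.txt` are read as tab-separated).
#' @param schema Column mapping from [panel_schema()].
#' @param impute Passed to [germplasm_panel()].
#' @return A validated [germplasm_panel()]; row order is preserved from file.
#' @export
read_panel <- function(path, schema = panel_schema(), impute = FALSE) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  df <- read_delim_auto(path)
  need <- c(schema$id, schema$type, unname(schema$traits))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Schema columns absent from file: ", toString(missing_cols)))
  }
  trait_src <- unname(schema$traits)
  trait_names_out <- if (is.null(names(schema$traits))) trait_src else {
    ifelse(names(schema$traits) == "", trait_src, names(schema$traits))
  }
  ssr_cols <- schema$ssr %||% grep(paste0("^", schema$ssr_prefix),
                                   names(df), value = TRUE)
  protein_cols <- schema$protein %||% grep(paste0("^", schema$protein_prefix),
                                           names(df), value = TRUE)
  traits <- setNames(df[trait_src], trait_names_out)
  germplasm_panel(
    info = tibble(genotype = df[[schema$id]], line_type = df[[schema$type]]),
    traits = traits,
    ssr = if (length(ssr_cols)) df[ssr_cols] else NULL,
    protein = if (length(protein_cols)) df[protein_cols] else NULL,
    impute = impute
  )
}

#' Write a germplasm panel to CSV
#'
#' Columns are written in canonical order (id, line type, traits, SSR bands,
#' protein bands) so that [read_panel()] of the output reproduces the panel.
#'
#' @param panel A [germplasm_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "germplasm_panel"))
  readr::write_csv(as_tibble(panel), path)
  invisible(path)
}

read_delim_auto <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
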