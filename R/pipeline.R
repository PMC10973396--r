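#' Run the heterotic-grouping workflow from one configuration
#'
#' Loads or simulates a germplasm panel, integrates its feature blocks,
#' runs the three clustering algorithms (Ward.D2 hierarchical, Lloyd
#' k-means, hybrid hkmeans), compares their resolution of the line-type
#' classes (purity, pairwise ARI), extracts the nested heterotic grouping
#' from the hierarchical tree, selects one representative parent per group,
#' and builds the Line x Tester cross design. All artifacts are written
#' under `out_dir` and returned invisibly.
#'
#' @param config Path to a YAML/JSON configuration file, or an equivalent
#'   named list. Recognised entries:
#'   \describe{
#'     \item{panel}{`list(path=, schema=)` to read a panel from file, or
#'       `list(simulate = list(...))` with [panel_config()] fields plus
#'       `seed`.}
#'     \item{preprocessing}{`list(yeo_johnson = TRUE)`.}
#'     \item{clustering}{`list(k_major = 2, k_sub = 12, seed = 1,
#'       n_init = 10)`.}
#'     \item{selection}{`list(trait = "SYP", eligible_types = "auto")`;
#'       `"auto"` restricts the restorer-dominated major cluster to R lines
#'       and the other to CMS lines.}
#'   }
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the panel, feature matrix, dendrogram,
#'   the three label sets, the comparison table, grouping, representatives
#'   and cross design.
#' @export
run_grouping <- function(config, out_dir) {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pc <- cfg$panel %||% list(simulate = list())
  if (!is.null(pc$path)) {
    schema <- if (is.null(pc$schema)) panel_schema() else
      do.call(panel_schema, pc$schema)
    panel <- read_panel(pc$path, schema)
    truth <- NULL
  } else {
    sim <- pc$simulate %||% list()
    seed <- sim$seed %||% 1L
    sim$seed <- NULL
    gen <- generate_panel(do.call(panel_config, sim), seed = seed)
    panel <- gen$panel
    truth <- gen$truth
  }

  yj <- cfg$preprocessing$yeo_johnson %||% TRUE
  feats <- integrate_features(panel, yeo_johnson = yj)

  cl <- cfg$clustering %||% list()
  k_major <- cl$k_major %||% 2L
  k_sub <- cl$k_sub %||% 12L
  if (k_sub > nrow(feats)) {
    abort("Configured k_sub exceeds the number of genotypes.")
  }
  dend <- ward_d2_linkage(pairwise_euclidean(feats))
  grouping <- extract_heterotic_groups(dend, k_major, k_sub)
  km <- lloyd_kmeans(feats, k = k_major, seed = cl$seed %||% 1L,
                     n_init = cl$n_init %||% 10L)
  hk <- hybrid_hkmeans(feats, k = k_sub)

  labels <- tibble(
    genotype = panel$info$genotype,
    line_type = panel$info$line_type,
    hierarchical_major = grouping$major,
    hierarchical_sub = grouping$sub,
    kmeans = unname(km$labels),
    hybrid = unname(hk$labels)
  )
  comparison <- dplyr::bind_rows(
    method_purity("hierarchical_sub", labels$hierarchical_sub, labels$line_type),
    method_purity("kmeans", labels$kmeans, labels$line_type),
    method_purity("hybrid", labels$hybrid, labels$line_type)
  )
  comparison$ari_vs_hierarchical <- c(
    1,
    adjusted_rand(labels$kmeans, labels$hierarchical_major),
    adjusted_rand(labels$hybrid, labels$hierarchical_sub)
  )

  sel <- cfg$selection %||% list()
  trait <- sel$trait %||% "SYP"
  elig <- sel$eligible_types %||% "auto"
  if (identical(elig, "auto")) elig <- auto_eligibility(grouping, panel)
  reps <- select_group_representatives(grouping, panel, trait, elig)
  r_ids <- reps$genotype[reps$line_type == "R"]
  cms_ids <- reps$genotype[reps$line_type == "CMS"]
  design <- if (length(r_ids) > 0 && length(cms_ids) > 0) {
    build_lxt_design(lines = cms_ids, testers = r_ids)
  } else NULL

  readr::write_csv(labels, file.path(out_dir, "labels.csv"))
  readr::write_csv(tidy(dend), file.path(out_dir, "merges.csv"))
  readr::write_csv(comparison, file.path(out_dir, "comparison.csv"))
  readr::write_csv(reps, file.path(out_dir, "parents.csv"))
  if (!is.null(design)) readr::write_csv(design, file.path(out_dir, "design.csv"))
  if (requireNamespace("ape", quietly = TRUE)) {
    write_newick(dend, file.path(out_dir, "dendrogram.newick"))
  }
  report <- list(
    n_genotypes = nrow(labels),
    n_features = ncol(feats),
    yeo_johnson = yj,
    lambda = as.list(attr(feats, "lambda")),
    k_major = k_major, k_sub = k_sub,
    kmeans = list(seed = km$seed, wss = km$wss),
    hybrid_wss = hk$wss,
    purity = setNames(as.list(comparison$purity), comparison$method)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(panel = panel, truth = truth, features = feats,
                 dendrogram = dend, labels = labels,
                 comparison = comparison, grouping = grouping,
                 representatives = reps, design = design))
}

method_purity <- function(method, labels, classes) {
  p <- cluster_purity(labels, classes)
  tibble(method = method, k = length(unique(labels)), purity = p$purity)
}

# restrict the restorer-dominated major cluster to R parents and the other
# major cluster(s) to CMS parents
auto_eligibility <- function(grouping, panel) {
  df <- dplyr::inner_join(as_tibble(grouping), panel$info, by = "genotype")
  r_frac <- tapply(df$line_type == "R", df$major, mean)
  r_major <- names(r_frac)[which.max(r_frac)]
  elig <- lapply(names(r_frac), function(mj) {
    if (mj == r_major) "R" else "CMS"
  })
  setNames(elig, names(r_frac))
}

#' Run the hybrid-evaluation workflow from one configuration
#'
#' Computes the full heterosis/heterobeltiosis table from parent and hybrid
#' means, and combining-ability analyses per trait. With replicated
#' plot-level trial data the Line x Tester ANOVA supplies the error
#' variance, so heterosis entries and GCA/SCA effects are annotated with
#' t-test stars; with means-only input significance is reported as
#' unavailable.
#'
#' @param config Path to a YAML/JSON file or named list. Recognised entries:
#'   \describe{
#'     \item{means}{`"fixture"` for the embedded sunflower tables, or
#'       `list(parents = path, hybrids = path)` of wide CSVs.}
#'     \item{trial}{`list(path=)` long-format replicated trial CSV
#'       (optional; enables ANOVA and significance).}
#'   }
#' @param out_dir Output directory.
#' @return Invisibly, a list with the heterosis table, per-trait `lxt_fit`
#'   objects and the ANOVA tables (when available).
#' @export
run_evaluation <- function(config, out_dir) {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ht <- NULL
  fits <- list()
  if (!is.null(cfg$means)) {
    if (identical(cfg$means, "fixture")) {
      fx <- sunflower_fixture()
      parents <- fx$parents; hybrids <- fx$hybrids; design <- fx$design
    } else {
      parents <- readr::read_csv(cfg$means$parents, show_col_types = FALSE)
      hybrids <- readr::read_csv(cfg$means$hybrids, show_col_types = FALSE)
      design <- NULL
    }
    ht <- heterosis_table(parents, hybrids, design)
    traits <- unique(ht$trait)
    fits <- lapply(setNames(traits, traits), function(tr) {
      sub <- ht[ht$trait == tr, c("line", "tester", "f1")]
      combining_ability(setNames(sub, c("line", "tester", "value")))
    })
  }
  if (!is.null(cfg$trial)) {
    trial <- read_trial(cfg$trial$path)
    des <- design_summary(trial)
    fits <- lapply(setNames(des$traits, des$traits), function(tr) {
      combining_ability(trial, tr)
    })
    if (!is.null(ht)) {
      mse_tb <- dplyr::bind_rows(lapply(fits, glance))[c("trait", "mse")]
      err_df <- (des$l * des$t - 1) * (des$r - 1)
      ht <- heterosis_significance(ht, mse_tb, des$r, err_df)
    }
  }

  if (!is.null(ht)) {
    readr::write_csv(ht, file.path(out_dir, "heterosis_long.csv"))
    readr::write_csv(heterosis_wide(ht), file.path(out_dir, "heterosis_wide.csv"))
  }
  if (length(fits) > 0) {
    gca <- dplyr::bind_rows(lapply(names(fits), function(tr) {
      dplyr::mutate(fits[[tr]]$gca, trait = tr, .before = 1)
    }))
    sca <- dplyr::bind_rows(lapply(names(fits), function(tr) {
      dplyr::mutate(fits[[tr]]$sca, trait = tr, .before = 1)
    }))
    readr::write_csv(gca, file.path(out_dir, "gca.csv"))
    readr::write_csv(sca, file.path(out_dir, "sca.csv"))
    anova_tb <- dplyr::bind_rows(lapply(names(fits), function(tr) {
      if (is.null(fits[[tr]]$anova)) return(NULL)
      dplyr::mutate(fits[[tr]]$anova, trait = tr, .before = 1)
    }))
    if (nrow(anova_tb) > 0) {
      readr::write_csv(anova_tb, file.path(out_dir, "anova.csv"))
    }
  }
  report <- list(
    n_crosses = if (!is.null(ht)) length(unique(ht$cross)) else 0,
    traits = if (length(fits)) names(fits) else character(0),
    significance = if (!is.null(cfg$trial)) "t-test vs error MS" else "unavailable"
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(heterosis = ht, fits = fits))
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("No such config file: ", config))
    if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  } else if (is.list(config)) {
    config
  } else {
    abort("`config` must be a file path or a named list.")
  }
}
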