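#' Configuration for the synthetic germplasm-panel generator
#'
#' Describes a panel with the structure the clustering analysis assumes:
#' `n_major` well-separated major populations (restorer material vs
#' CMS/B/SFP material), each split into `sub_per_major` sub-clusters.
#' Continuous traits are drawn Normal around sub-cluster means separated by
#' `delta` within-cluster standard deviations; binary SSR/protein bands are
#' Bernoulli draws around cluster-specific frequencies `0.5 +/- epsilon`.
#'
#' @param n Number of genotypes (default 109).
#' @param class_proportions Named proportions for the CMS/B/R/SFP line types
#'   (must sum to 1). The default puts ~28% restorers, mirroring a typical
#'   breeding panel with a restorer pool of about 31 in 109.
#' @param n_major Major populations (default 2).
#' @param sub_per_major Sub-clusters per major population (default 6).
#' @param delta Between-sub-cluster trait separation in within-cluster SD
#'   units (>= 0).
#' @param trait_sd Within-cluster trait standard deviation.
#' @param trait_base Baseline trait means (named by trait), defaults to
#'   agronomically plausible magnitudes for the nine canonical traits.
#' @param n_ssr,n_protein Number of binary SSR and protein band columns
#'   (defaults 40 and 14).
#' @param epsilon Band-frequency divergence between clusters, in
#'   `[0, 0.5]`: cluster band frequencies are `0.5 - epsilon` or
#'   `0.5 + epsilon`.
#' @param sub_band_flip Probability that a sub-cluster flips one of its major
#'   population's band-pattern bits; keeps sub-clusters of one population
#'   mutually closer than the two populations are to each other.
#' @return A `panel_config` list.
#' @export
panel_config <- function(n = 109,
                         class_proportions = c(CMS = 0.24, B = 0.24,
                                               R = 0.28, SFP = 0.24),
                         n_major = 2, sub_per_major = 6,
                         delta = 6, trait_sd = 1,
                         trait_base = c(DFI = 50, DFC = 60, PH = 170,
                                        LA = 190, HD = 15, SC = 25,
                                        LP = 30, HSW = 5, SYP = 50),
                         n_ssr = 40, n_protein = 14, epsilon = 0.4,
                         sub_band_flip = 0.1) {
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    abort("`class_proportions` must sum to 1.")
  }
  if (!setequal(names(class_proportions), line_type_levels)) {
    abort(paste0("`class_proportions` must be named by ",
                 toString(line_type_levels)))
  }
  if (delta < 0 || epsilon < 0 || epsilon > 0.5) {
    abort("Need delta >= 0 and epsilon in [0, 0.5].")
  }
  structure(list(n = n, class_proportions = class_proportions,
                 n_major = n_major, sub_per_major = sub_per_major,
                 delta = delta, trait_sd = trait_sd,
                 trait_base = trait_base,
                 n_ssr = n_ssr, n_protein = n_protein, epsilon = epsilon,
                 sub_band_flip = sub_band_flip),
            class = "panel_config")
}

#' Generate a synthetic germplasm panel with known cluster structure
#'
#' Restorer (R) genotypes are placed in the first major population and
#' CMS/B/SFP genotypes in the remaining population(s), mirroring the clean
#' separation of restorer from female-side material that heterotic-grouping
#' studies report. Within a major population, genotypes are dealt
#' round-robin across its sub-clusters. Traits are truncated at zero (means
#' are large relative to the SD, so truncation is essentially inactive at
#' the defaults).
#'
#' @param cfg A [panel_config()].
#' @param seed Integer seed; the generator is a deterministic function of
#'   `(cfg, seed)`.
#' @return List with `panel` (a [germplasm_panel()]) and `truth`, a tibble
#'   of the generating `major` and `sub` labels per genotype.
#' @export
generate_panel <- function(cfg = panel_config(), seed = 1L) {
  stopifnot(inherits(cfg, "panel_config"))
  n <- cfg$n
  counts <- round_proportions(cfg$class_proportions, n)
  types <- rep(names(counts), counts)
  k_sub <- cfg$n_major * cfg$sub_per_major
  withr::with_seed(as.integer(seed), {
    major <- rep(1L, n)
    if (cfg$n_major > 1) {
      nonr <- which(types != "R")
      major[nonr] <- 2L + (seq_along(nonr) - 1L) %% (cfg$n_major - 1L)
    }
    # round-robin sub-cluster assignment within each major population
    sub <- integer(n)
    for (mj in seq_len(cfg$n_major)) {
      ix <- which(major == mj)
      sub[ix] <- (mj - 1L) * cfg$sub_per_major +
        (seq_along(ix) - 1L) %% cfg$sub_per_major + 1L
    }
    n_traits <- length(cfg$trait_base)
    # two-level trait centres: major populations separated at 2*delta SD,
    # sub-clusters within a population at delta SD
    sub_major <- rep(seq_len(cfg$n_major), each = cfg$sub_per_major)
    major_shift <- matrix(rnorm(cfg$n_major * n_traits), cfg$n_major,
                          n_traits) * 2 * cfg$delta * cfg$trait_sd
    centres <- major_shift[sub_major, , drop = FALSE] +
      matrix(rnorm(k_sub * n_traits), k_sub, n_traits) *
        cfg$delta * cfg$trait_sd
    centres <- sweep(centres, 2, cfg$trait_base, "+")
    traits <- centres[sub, , drop = FALSE] +
      matrix(rnorm(n * n_traits, sd = cfg$trait_sd), n, n_traits)
    traits[traits < 0] <- 0
    colnames(traits) <- names(cfg$trait_base)
    n_bands <- cfg$n_ssr + cfg$n_protein
    # two-level band patterns: each major population has its own 0/1 pattern;
    # sub-clusters flip a small fraction of their population's bits, then
    # genotypes draw bands at frequency 0.5 +/- epsilon around the pattern
    major_pattern <- matrix(rbinom(cfg$n_major * n_bands, 1, 0.5),
                            cfg$n_major, n_bands)
    flips <- matrix(rbinom(k_sub * n_bands, 1, cfg$sub_band_flip),
                    k_sub, n_bands)
    pattern <- abs(major_pattern[sub_major, , drop = FALSE] - flips)
    freq <- 0.5 + (2 * pattern - 1) * cfg$epsilon
    bands <- matrix(rbinom(n * n_bands, 1, freq[sub, ]), n, n_bands)
    ssr <- bands[, seq_len(cfg$n_ssr), drop = FALSE]
    protein <- bands[, cfg$n_ssr + seq_len(cfg$n_protein), drop = FALSE]
    colnames(ssr) <- paste0("SSR_", seq_len(cfg$n_ssr))
    colnames(protein) <- paste0("PB_", seq_len(cfg$n_protein))
    ids <- sprintf("G%03d", seq_len(n))
    panel <- germplasm_panel(
      info = tibble(genotype = ids, line_type = types),
      traits = as_tibble(as.data.frame(traits)),
      ssr = as_tibble(as.data.frame(ssr)),
      protein = as_tibble(as.data.frame(protein))
    )
    list(panel = panel,
         truth = tibble(genotype = ids, line_type = types,
                        major = as.integer(major), sub = as.integer(sub)))
  })
}

round_proportions <- function(p, n) {
  raw <- p * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  setNames(as.integer(counts), names(p))
}

#' Ground truth for a synthetic Line x Tester trial
#'
#' Centers the supplied GCA vectors and SCA matrix (sum-to-zero over lines,
#' testers, and both SCA margins) so the generated trial follows
#' `y_ijk = mu + g_i + g_j + s_ij + rep_k + e_ijk` with identifiable effects.
#'
#' @param mu Grand mean.
#' @param g_line,g_tester Numeric GCA effect vectors (named or not).
#' @param s l x t numeric SCA matrix.
#' @param rep_sd SD of the replication (block) effects.
#' @param sigma Residual SD.
#' @return A `trial_truth` list with centered effects.
#' @export
trial_truth <- function(mu, g_line, g_tester, s, rep_sd = 0, sigma = 1) {
  s <- as.matrix(s)
  if (nrow(s) != length(g_line) || ncol(s) != length(g_tester)) {
    abort("`s` must be length(g_line) x length(g_tester).")
  }
  g_line <- g_line - mean(g_line)
  g_tester <- g_tester - mean(g_tester)
  s <- sweep(s, 1, rowMeans(s), "-")
  s <- sweep(s, 2, colMeans(s), "-")
  lines <- names(g_line) %||% sprintf("L%02d", seq_along(g_line))
  testers <- names(g_tester) %||% sprintf("T%02d", seq_along(g_tester))
  structure(list(mu = mu, g_line = setNames(g_line, lines),
                 g_tester = setNames(g_tester, testers),
                 s = structure(s, dimnames = list(lines, testers)),
                 rep_sd = rep_sd, sigma = sigma),
            class = "trial_truth")
}

#' Draw random trial ground truth
#'
#' @param l,t Numbers of lines and testers.
#' @param gca_sd,sca_sd SDs of the Normal draws for GCA and SCA effects
#'   (before centering).
#' @param mu Grand mean.
#' @param rep_sd,sigma Block-effect and residual SDs.
#' @param seed Integer seed.
#' @return A [trial_truth()].
#' @export
random_trial_truth <- function(l = 6, t = 6, gca_sd = 5, sca_sd = 3,
                               mu = 60, rep_sd = 2, sigma = 5, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    trial_truth(mu = mu,
                g_line = rnorm(l, sd = gca_sd),
                g_tester = rnorm(t, sd = gca_sd),
                s = matrix(rnorm(l * t, sd = sca_sd), l, t),
                rep_sd = rep_sd, sigma = sigma)
  })
}

#' Generate a balanced replicated Line x Tester trial
#'
#' `y_ijk = mu + g_i + g_j + s_ij + rep_k + e_ijk` with
#' `rep_k ~ N(0, rep_sd^2)` and `e_ijk ~ N(0, sigma^2)`.
#'
#' @param truth A [trial_truth()].
#' @param r Number of replications.
#' @param trait Trait name recorded on the observations.
#' @param seed Integer seed.
#' @return A balanced [trial_data()].
#' @export
generate_lxt_trial <- function(truth, r = 3, trait = "SYP", seed = 1L) {
  stopifnot(inherits(truth, "trial_truth"))
  l <- length(truth$g_line); t <- length(truth$g_tester)
  withr::with_seed(as.integer(seed), {
    rep_eff <- rnorm(r, sd = truth$rep_sd)
    grid <- tidyr::expand_grid(line = names(truth$g_line),
                               tester = names(truth$g_tester),
                               rep = seq_len(r))
    cell <- truth$mu + unname(truth$g_line[grid$line]) +
      unname(truth$g_tester[grid$tester]) +
      truth$s[cbind(grid$line, grid$tester)]
    grid$trait <- trait
    grid$value <- cell + rep_eff[grid$rep] +
      rnorm(nrow(grid), sd = truth$sigma)
    trial_data(grid)
  })
}

#' Embedded sunflower parent/hybrid fixture
#'
#' Published mean-performance tables for 12 sunflower parents (6 CMS lines,
#' 6 restorer testers) and their 36 Line x Tester F1 hybrids across the nine
#' canonical traits, together with the 6 x 6 cross design and the published
#' heterosis/heterobeltiosis values for cross-checking. All tables ship as
#' plain CSV inside the package.
#'
#' @return List with tibbles `parents` (columns `parent`, `role`, traits),
#'   `hybrids` (`tester`, `line`, traits), `design`, and
#'   `printed_heterosis` (`line`, `tester`, `trait`, `MPH`, `BPH`).
#' @export
sunflower_fixture <- function() {
  path <- function(f) system.file("extdata", f, package = "heterotic",
                                  mustWork = TRUE)
  parents <- readr::read_csv(path("sunflower_parent_means.csv"),
                             show_col_types = FALSE, progress = FALSE)
  hybrids <- readr::read_csv(path("sunflower_hybrid_means.csv"),
                             show_col_types = FALSE, progress = FALSE)
  printed <- readr::read_csv(path("sunflower_printed_heterosis.csv"),
                             show_col_types = FALSE, progress = FALSE)
  design <- build_lxt_design(lines = parents$parent[parents$role == "line"],
                             testers = parents$parent[parents$role == "tester"])
  list(parents = parents, hybrids = hybrids, design = design,
       printed_heterosis = printed)
}
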