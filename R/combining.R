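#' Cross means for one trait
#'
#' Averages plot observations over replications into the l x t table of cross
#' means, with line/tester marginal means and the grand mean.
#'
#' @param trial A [trial_data()] object, or a data frame of per-cross means
#'   with columns `line`, `tester`, `value` (in which case `r` is taken from
#'   the `r` argument and may be `NA` for means-only input).
#' @param trait Trait to extract (ignored for a means data frame).
#' @param r Replication count when `trial` is a means table.
#' @return Object of class `cross_means`: list with `matrix` (lines x
#'   testers), `line_means`, `tester_means`, `grand_mean`, `r`, `trait`.
#' @export
cross_means <- function(trial, trait = NULL, r = NA_integer_) {
  if (inherits(trial, "trial_data")) {
    des <- design_summary(trial)
    if (is.null(trait)) trait <- des$traits[1]
    if (!trait %in% des$traits) abort(paste0("Trait `", trait, "` not in trial."))
    sub <- dplyr::filter(as_tibble(trial), .data$trait == !!trait)
    cm <- sub |>
      dplyr::summarise(value = mean(.data$value),
                       .by = c("line", "tester"))
    r <- des$r
  } else {
    cm <- as_tibble(trial)
    if (!all(c("line", "tester", "value") %in% names(cm))) {
      abort("Means table needs columns `line`, `tester`, `value`.")
    }
  }
  wide <- tidyr::pivot_wider(cm[c("line", "tester", "value")],
                             names_from = "tester", values_from = "value")
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$line
  mat <- mat[order(rownames(mat)), order(colnames(mat)), drop = FALSE]
  if (anyNA(mat)) abort("Cross-mean table is incomplete (missing crosses).")
  structure(list(matrix = mat,
                 line_means = rowMeans(mat),
                 tester_means = colMeans(mat),
                 grand_mean = mean(mat),
                 r = r, trait = trait),
            class = "cross_means")
}

#' @export
print.cross_means <- function(x, ...) {
  cat("<cross_means> ", nrow(x$matrix), " lines x ", ncol(x$matrix),
      " testers", if (!is.na(x$r)) paste0(", r = ", x$r), "\n", sep = "")
  print(round(x$matrix, 3))
  invisible(x)
}

#' General combining ability effects
#'
#' GCA of parent i is its marginal mean deviation from the grand mean:
#' `g_i = ybar_i.. - ybar...` for lines and `g_j = ybar_.j. - ybar...` for
#' testers. Both effect sets sum to zero by construction.
#'
#' @param cm A [cross_means()] object.
#' @return Tibble with columns `parent`, `role` (line/tester), `gca`.
#' @export
gca_effects <- function(cm) {
  stopifnot(inherits(cm, "cross_means"))
  dplyr::bind_rows(
    tibble(parent = names(cm$line_means), role = "line",
           gca = unname(cm$line_means - cm$grand_mean)),
    tibble(parent = names(cm$tester_means), role = "tester",
           gca = unname(cm$tester_means - cm$grand_mean))
  )
}

#' Specific combining ability effects
#'
#' SCA of cross (i, j) is the interaction residual
#' `s_ij = ybar_ij. - ybar_i.. - ybar_.j. + ybar...`; every row and column of
#' the SCA matrix sums to zero.
#'
#' @param cm A [cross_means()] object.
#' @return Tibble with columns `line`, `tester`, `sca`.
#' @export
sca_effects <- function(cm) {
  stopifnot(inherits(cm, "cross_means"))
  s <- sweep(sweep(cm$matrix, 1, cm$line_means, "-"),
             2, cm$tester_means, "-") + cm$grand_mean
  as_tibble(as.data.frame.table(s, stringsAsFactors = FALSE)) |>
    setNames(c("line", "tester", "sca")) |>
    dplyr::arrange(.data$line, .data$tester)
}

#' Line x Tester analysis of variance
#'
#' Randomized-block partition for a balanced l x t x r trial of one trait:
#' replications (r - 1 df), crosses (lt - 1) split into lines (l - 1),
#' testers (t - 1) and line x tester ((l-1)(t-1)), and error by subtraction
#' ((lt - 1)(r - 1) df). F statistics test each mean square against the
#' error mean square.
#'
#' @param trial A [trial_data()] with `r >= 2`.
#' @param trait Trait to analyse.
#' @return Tibble with columns `term`, `df`, `sumsq`, `meansq`, `statistic`,
#'   `p.value`.
#' @export
lxt_anova <- function(trial, trait = NULL) {
  stopifnot(inherits(trial, "trial_data"))
  des <- design_summary(trial)
  if (is.null(trait)) trait <- des$traits[1]
  l <- des$l; t <- des$t; r <- des$r
  if (r < 2) abort("ANOVA needs r >= 2 replications (no error df otherwise).")
  sub <- dplyr::filter(as_tibble(trial), .data$trait == !!trait)
  y <- sub$value
  gm <- mean(y)
  rep_means <- tapply(y, sub$rep, mean)
  cm <- cross_means(trial, trait)
  ss_total <- sum((y - gm)^2)
  ss_rep <- l * t * sum((rep_means - gm)^2)
  ss_crosses <- r * sum((cm$matrix - gm)^2)
  ss_lines <- t * r * sum((cm$line_means - gm)^2)
  ss_testers <- l * r * sum((cm$tester_means - gm)^2)
  ss_lxt <- ss_crosses - ss_lines - ss_testers
  # the subtractions can leave a tiny negative residue on noiseless data
  ss_error <- max(ss_total - ss_rep - ss_crosses, 0)
  df <- c(r - 1, l * t - 1, l - 1, t - 1, (l - 1) * (t - 1),
          (l * t - 1) * (r - 1))
  ss <- c(ss_rep, ss_crosses, ss_lines, ss_testers, ss_lxt, ss_error)
  ms <- ss / df
  fstat <- c(NA, ms[2:5] / ms[6], NA)
  pval <- stats::pf(fstat, df, df[6], lower.tail = FALSE)
  tibble(term = c("replications", "crosses", "lines", "testers",
                  "line_x_tester", "error"),
         df = df, sumsq = ss, meansq = ms, statistic = fstat,
         p.value = pval)
}

#' Standard errors for combining-ability effects
#'
#' Standard line x tester formulas from the error mean square of the trial
#' ANOVA: `SE(g_line) = sqrt(mse / (r t))`, `SE(g_tester) = sqrt(mse / (r l))`,
#' `SE(s) = sqrt(mse / r)`; standard errors of differences are `sqrt(2)`
#' times each.
#'
#' @param mse Error mean square (>= 0).
#' @param l,t,r Design dimensions.
#' @return Tibble with columns `effect`, `se`, `se_diff`.
#' @export
effect_standard_errors <- function(mse, l, t, r) {
  if (mse < 0) abort("`mse` must be non-negative.")
  se <- c(gca_line = sqrt(mse / (r * t)),
          gca_tester = sqrt(mse / (r * l)),
          sca = sqrt(mse / r))
  tibble(effect = names(se), se = unname(se), se_diff = sqrt(2) * unname(se))
}

#' Full combining-ability analysis for one trait
#'
#' Runs the Line x Tester ANOVA (when replicated plot data are available),
#' estimates GCA and SCA effects from the cross means, attaches standard
#' errors and t-based significance stars, and reports the proportional
#' contributions of lines, testers and their interaction to the crosses sum
#' of squares. When only a cross-mean table is supplied no error variance
#' exists, so effects are returned with significance marked unavailable.
#'
#' @param trial A [trial_data()] object or a per-cross means data frame
#'   (columns `line`, `tester`, `value`).
#' @param trait Trait to analyse (for trial input).
#' @return Object of class `lxt_fit` with elements `trait`, `cross_means`,
#'   `gca`, `sca`, `anova`, `se`, `contributions`. [tidy()] returns the
#'   effect table, [glance()] a one-row model summary.
#' @export
combining_ability <- function(trial, trait = NULL) {
  cm <- cross_means(trial, trait)
  gca <- gca_effects(cm)
  sca <- sca_effects(cm)
  l <- nrow(cm$matrix); t <- ncol(cm$matrix)
  anova_tb <- NULL
  se <- NULL
  if (inherits(trial, "trial_data") && design_summary(trial)$r >= 2) {
    anova_tb <- lxt_anova(trial, cm$trait)
    mse <- anova_tb$meansq[anova_tb$term == "error"]
    error_df <- anova_tb$df[anova_tb$term == "error"]
    se <- effect_standard_errors(mse, l, t, cm$r)
    stars <- function(est, s) {
      p <- 2 * pt(abs(est / s), df = error_df, lower.tail = FALSE)
      ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))
    }
    gca$se <- ifelse(gca$role == "line", se$se[se$effect == "gca_line"],
                     se$se[se$effect == "gca_tester"])
    gca$significance <- stars(gca$gca, gca$se)
    sca$se <- se$se[se$effect == "sca"]
    sca$significance <- stars(sca$sca, sca$se)
  } else {
    gca$se <- NA_real_
    gca$significance <- "unavailable"
    sca$se <- NA_real_
    sca$significance <- "unavailable"
  }
  # proportional contributions of the crosses sum of squares
  ss_l <- t * sum((cm$line_means - cm$grand_mean)^2)
  ss_t <- l * sum((cm$tester_means - cm$grand_mean)^2)
  ss_s <- sum(sca$sca^2)
  contrib <- tibble(component = c("lines", "testers", "line_x_tester"),
                    proportion = c(ss_l, ss_t, ss_s) / (ss_l + ss_t + ss_s))
  structure(list(trait = cm$trait, cross_means = cm, gca = gca, sca = sca,
                 anova = anova_tb, se = se, contributions = contrib),
            class = "lxt_fit")
}

#' @export
print.lxt_fit <- function(x, ...) {
  cat("<lxt_fit> trait ", x$trait %||% "(unnamed)", ": ",
      nrow(x$cross_means$matrix), " lines x ", ncol(x$cross_means$matrix),
      " testers\n", sep = "")
  if (is.null(x$anova)) cat("  significance unavailable (means-only input)\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lxt_fit <- function(x, effects = c("gca", "sca"), ...) {
  effects <- match.arg(effects)
  if (effects == "gca") x$gca else x$sca
}

#' @exportS3Method generics::glance
glance.lxt_fit <- function(x, ...) {
  mse <- if (!is.null(x$anova)) x$anova$meansq[x$anova$term == "error"] else NA_real_
  f_lxt <- if (!is.null(x$anova)) {
    x$anova$statistic[x$anova$term == "line_x_tester"]
  } else NA_real_
  tibble(trait = x$trait %||% NA_character_,
         l = nrow(x$cross_means$matrix),
         t = ncol(x$cross_means$matrix),
         r = x$cross_means$r,
         grand_mean = x$cross_means$grand_mean,
         mse = mse,
         f_line_x_tester = f_lxt)
}
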