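# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: they recompute quantities from first
# principles (definitions, exhaustive enumeration) on small inputs.

# Ward.D2 agglomeration recomputed from raw coordinates at every step:
# the between-cluster criterion 2|A||B|/(|A|+|B|) * ||centroid_A-centroid_B||^2
# is evaluated exhaustively over all active pairs; heights on distance scale.
oracle_ward <- function(m) {
  clusters <- as.list(seq_len(nrow(m)))
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        a <- clusters[[i]]; b <- clusters[[j]]
        ca <- colMeans(m[a, , drop = FALSE])
        cb <- colMeans(m[b, , drop = FALSE])
        d2 <- 2 * length(a) * length(b) / (length(a) + length(b)) *
          sum((ca - cb)^2)
        key <- c(min(min(a), min(b)), max(min(a), min(b)))
        if (is.null(best) || d2 < best$d2 - 1e-12 ||
            (abs(d2 - best$d2) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d2 = d2, key = key)
        }
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges[[length(merges) + 1]] <- list(members = merged,
                                         height = sqrt(best$d2))
    clusters[[best$i]] <- merged
    clusters[[best$j]] <- NULL
  }
  merges
}

# member sets of each merge of a ward_dendrogram, sorted
dendrogram_merge_sets <- function(dend) {
  sets <- vector("list", length(dend$height))
  for (s in seq_along(dend$height)) {
    sets[[s]] <- sort(unlist(lapply(dend$merge[s, ], function(id) {
      if (id < 0) -id else sets[[id]]
    })))
  }
  sets
}

# adjusted Rand recomputed by explicit pair counting
oracle_ari <- function(a, b) {
  n <- length(a)
  ss <- sd_ <- ds <- dd <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a && same_b) ss <- ss + 1
      else if (same_a && !same_b) sd_ <- sd_ + 1
      else if (!same_a && same_b) ds <- ds + 1
      else dd <- dd + 1
    }
  }
  denom <- (ss + sd_) * (sd_ + dd) + (ss + ds) * (ds + dd)
  if (denom == 0) return(1)
  2 * (ss * dd - sd_ * ds) / denom
}

# Yeo-Johnson profile log-likelihood on a lambda grid, written independently
oracle_yj_grid <- function(x, n_grid = 10001, lo = -5, hi = 5) {
  psi <- function(x, l) {
    ifelse(x >= 0,
           if (abs(l) < 1e-12) log(x + 1) else ((x + 1)^l - 1) / l,
           if (abs(l - 2) < 1e-12) -log(1 - x) else
             -((1 - x)^(2 - l) - 1) / (2 - l))
  }
  grid <- seq(lo, hi, length.out = n_grid)
  ll <- vapply(grid, function(l) {
    z <- psi(x, l)
    s2 <- mean((z - mean(z))^2)
    -length(x) / 2 * log(s2) + (l - 1) * sum(sign(x) * log(abs(x) + 1))
  }, numeric(1))
  list(lambda = grid[which.max(ll)], loglik = max(ll))
}

# Line x Tester sums of squares from explicit definition-level loops
oracle_lxt_ss <- function(df) {
  lines <- sort(unique(df$line)); testers <- sort(unique(df$tester))
  reps <- sort(unique(df$rep))
  l <- length(lines); t <- length(testers); r <- length(reps)
  gm <- mean(df$value)
  ss_rep <- 0
  for (k in reps) ss_rep <- ss_rep + l * t * (mean(df$value[df$rep == k]) - gm)^2
  ss_crosses <- ss_lines <- ss_testers <- 0
  for (i in lines) {
    ss_lines <- ss_lines + t * r * (mean(df$value[df$line == i]) - gm)^2
    for (j in testers) {
      ss_crosses <- ss_crosses + r *
        (mean(df$value[df$line == i & df$tester == j]) - gm)^2
    }
  }
  for (j in testers) {
    ss_testers <- ss_testers + l * r * (mean(df$value[df$tester == j]) - gm)^2
  }
  ss_total <- sum((df$value - gm)^2)
  list(rep = ss_rep, crosses = ss_crosses, lines = ss_lines,
       testers = ss_testers, lxt = ss_crosses - ss_lines - ss_testers,
       error = ss_total - ss_rep - ss_crosses)
}

# toy 4-genotype panel used by several IO / selection tests
toy_panel <- function() {
  germplasm_panel(
    info = tibble::tibble(genotype = c("A1", "B2", "R3", "S4"),
                          line_type = c("CMS", "B", "R", "SFP")),
    traits = tibble::tibble(DFI = c(48, 50, 55, 52),
                            SYP = c(62.8, 68.2, 30.1, 41.5)),
    ssr = tibble::tibble(SSR_1 = c(1, 0, 1, 0), SSR_2 = c(0, 0, 1, 1)),
    protein = tibble::tibble(PB_1 = c(1, 1, 0, 0))
  )
}

# Null simulation for the mid-parent heterosis t-test, routed through the
# package's own significance annotation: every cross has true F1 mean equal
# to the true mid-parent value, so rejections are type-I errors. sigma^2 is
# known, hence the reference distribution is normal (error_df large).
null_mph_rejection_rate <- function(n_rep, sigma, r, seed) {
  withr::with_seed(seed, {
    p1 <- 50; p2 <- 60
    ids1 <- sprintf("A%05d", seq_len(n_rep))
    ids2 <- sprintf("B%05d", seq_len(n_rep))
    parents <- tibble::tibble(
      parent = c(ids1, ids2),
      SYP = c(rnorm(n_rep, p1, sigma / sqrt(r)),
              rnorm(n_rep, p2, sigma / sqrt(r)))
    )
    hybrids <- tibble::tibble(
      line = ids1, tester = ids2,
      SYP = rnorm(n_rep, (p1 + p2) / 2, sigma / sqrt(r))
    )
  })
  ht <- heterosis_table(parents, hybrids)
  ann <- heterosis_significance(ht, mse = sigma^2, r = r, error_df = 1e9)
  mean(ann$sig_mph != "ns")
}
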