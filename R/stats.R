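#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment implemented from the definition:
#' for sorted p-values `p(1) <= ... <= p(m)`,
#' `q(i) = min_{j >= i} (m * p(j) / j)`, clipped to 1 and returned in the
#' original input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || any(!is.finite(pvalues)) ||
      any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  }
  m <- length(pvalues)
  if (m == 0L) return(numeric(0))
  o <- order(pvalues)
  q_sorted <- pvalues[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))   # min over j >= i
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

.stars <- function(q) {
  ifelse(q < 0.001, "***", ifelse(q < 0.01, "**", ifelse(q < 0.05, "*", "")))
}

#' Assemble a long-format group table from per-larva metric tables
#'
#' @param metric_tables List of [cycle_metrics_table()] outputs (one per
#'   larva, `larva_id` already set).
#' @param genotypes Character vector of genotype labels, one per table.
#' @return Long data frame with columns `larva_id`, `genotype`,
#'   `cycle_index`, `metric`, `value`, restricted to retained cycles; one
#'   row per (larva, cycle, metric).
#' @export
group_table <- function(metric_tables, genotypes) {
  stopifnot(length(metric_tables) == length(genotypes))
  metrics <- c(max_tail_angle_deg = "max_tail_angle",
               normalized_integral_deg = "normalized_integral",
               pct_above_threshold = "pct_above_threshold")
  rows <- Map(function(tb, g) {
    tb <- tb[!tb$excluded, , drop = FALSE]
    do.call(rbind, lapply(names(metrics), function(col) {
      data.frame(larva_id = tb$larva_id, genotype = g,
                 cycle_index = tb$cycle_index, metric = metrics[[col]],
                 value = tb[[col]])
    }))
  }, metric_tables, genotypes)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-cycle genotype comparison with BH correction
#'
#' Fixed-effects two-factor analysis of one metric: an omnibus two-way ANOVA
#' (genotype x cycle, larvae as replicates) plus per-cycle two-group
#' contrasts (Welch t-tests) whose p-values are Benjamini-Hochberg adjusted
#' across cycles within the metric. This mirrors the per-cycle significance
#' stars of group figures in this assay; the repeated-measures structure
#' (the same larva contributes every cycle) is deliberately ignored, as in
#' the original analysis, and noted as a limitation.
#'
#' @param table Long table from [group_table()].
#' @param metric Metric name to analyze (e.g. `"normalized_integral"`).
#' @return An object of class `vsr_stats`: list with `metric`, `omnibus`
#'   (data frame of F and p for genotype, cycle and interaction) and
#'   `per_cycle` (data frame with group means/SEMs, raw p, BH q and stars).
#' @export
compare_groups <- function(table, metric) {
  tb <- table[table$metric == metric, , drop = FALSE]
  if (!nrow(tb)) stop("metric not found in table: ", metric, call. = FALSE)
  if (anyDuplicated(tb[, c("larva_id", "cycle_index", "metric")])) {
    stop("each (larva, cycle, metric) must appear at most once", call. = FALSE)
  }
  genos <- sort(unique(tb$genotype))
  cyc <- sort(unique(tb$cycle_index))
  if (length(genos) < 2L || length(cyc) < 2L) {
    stop("comparison needs >= 2 genotypes and >= 2 cycles", call. = FALSE)
  }
  counts <- table(tb$genotype, tb$cycle_index)
  if (any(counts == 0)) {
    bad <- which(counts == 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("missing cell: genotype %s has no larvae in cycle %s",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]),
         call. = FALSE)
  }
  if (any(tapply(tb$larva_id, tb$genotype, function(x) length(unique(x))) < 2L)) {
    stop("comparison needs >= 2 larvae per genotype", call. = FALSE)
  }

  tb$genotype_f <- factor(tb$genotype)
  tb$cycle_f <- factor(tb$cycle_index)
  fit <- stats::aov(value ~ genotype_f * cycle_f, data = tb)
  sm <- summary(fit)[[1L]]
  omnibus <- data.frame(
    term = c("genotype", "cycle", "interaction"),
    df = sm$Df[1:3], F = sm$`F value`[1:3], p = sm$`Pr(>F)`[1:3])

  if (length(genos) != 2L) {
    stop("per-cycle contrasts are defined for exactly 2 genotypes", call. = FALSE)
  }
  per <- do.call(rbind, lapply(cyc, function(cc) {
    x <- tb$value[tb$cycle_index == cc & tb$genotype == genos[1L]]
    y <- tb$value[tb$cycle_index == cc & tb$genotype == genos[2L]]
    p <- tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
    if (!is.finite(p)) p <- 1     # zero-variance degenerate cells
    data.frame(cycle_index = cc,
               mean_1 = mean(x), sem_1 = stats::sd(x) / sqrt(length(x)),
               mean_2 = mean(y), sem_2 = stats::sd(y) / sqrt(length(y)),
               p_raw = p)
  }))
  names(per)[2:5] <- c(paste0("mean_", genos[1L]), paste0("sem_", genos[1L]),
                       paste0("mean_", genos[2L]), paste0("sem_", genos[2L]))
  per$q_bh <- bh_adjust(per$p_raw)
  per$stars <- .stars(per$q_bh)
  structure(list(metric = metric, genotypes = genos, omnibus = omnibus,
                 per_cycle = per),
            class = "vsr_stats")
}

#' @export
print.vsr_stats <- function(x, ...) {
  cat(sprintf("VSR group comparison (%s): %s vs %s\n", x$metric,
              x$genotypes[1L], x$genotypes[2L]))
  print(x$omnibus, row.names = FALSE, digits = 4)
  cat(sprintf("  per-cycle contrasts: %d of %d with q < 0.05\n",
              sum(x$per_cycle$q_bh < 0.05), nrow(x$per_cycle)))
  invisible(x)
}

# D'Agostino-Pearson K^2 omnibus normality test: combines the D'Agostino
# (1970) transformed skewness Z and the Anscombe-Glynn (1983) transformed
# kurtosis Z into K^2 = Zs^2 + Zk^2 ~ chi^2(2). No installed package
# provides it, so it is implemented from the standard formulas.
dagostino_test <- function(x) {
  n <- length(x)
  if (n < 20L) {
    stop("D'Agostino-Pearson test needs n >= 20", call. = FALSE)
  }
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2
  # skewness
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  dlt <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Zs <- dlt * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis
  Eg2 <- 3 * (n - 1) / (n + 1)
  Vg2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - Eg2) / sqrt(Vg2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  Zk <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- Zs^2 + Zk^2
  list(statistic = K2, p.value = stats::pchisq(K2, df = 2, lower.tail = FALSE))
}

#' Normality screening of group values
#'
#' Report-only battery of four normality tests per group: Anderson-Darling,
#' D'Agostino-Pearson omnibus, Shapiro-Wilk, and Lilliefors-corrected
#' Kolmogorov-Smirnov (parameters are estimated from the data, so the
#' Lilliefors correction is the appropriate KS variant). Tests whose sample
#' size requirements are not met (`n >= 8` for Anderson-Darling, `n >= 20`
#' for D'Agostino-Pearson, `n >= 5` for Lilliefors) return `NA`. No gating
#' is performed on the results.
#'
#' @param values Numeric vector, or a named list of numeric vectors (one
#'   per group).
#' @return A data frame with columns `group`, `n`, `anderson_darling`,
#'   `dagostino_pearson`, `shapiro_wilk`, `kolmogorov_smirnov` (p-values).
#' @export
normality_screen <- function(values) {
  if (!is.list(values)) values <- list(group = values)
  if (is.null(names(values))) names(values) <- paste0("group", seq_along(values))
  rows <- lapply(names(values), function(g) {
    x <- values[[g]]
    n <- length(x)
    if (n < 3L) {
      stop("insufficient data for normality screening (n = ", n,
           " in group ", g, "; need >= 3)", call. = FALSE)
    }
    safe <- function(min_n, f) {
      if (n < min_n) return(NA_real_)
      tryCatch(f(x)$p.value, error = function(e) NA_real_)
    }
    data.frame(group = g, n = n,
               anderson_darling = safe(8L, nortest::ad.test),
               dagostino_pearson = safe(20L, dagostino_test),
               shapiro_wilk = safe(3L, stats::shapiro.test),
               kolmogorov_smirnov = safe(5L, nortest::lillie.test))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
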