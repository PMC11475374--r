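# Independent oracles and small fixture builders used across the suite.

# Brute-force one-way ANOVA from explicit sums of squares.
anova_oracle <- function(values, labels) {
  labels <- factor(labels)
  grand <- mean(values)
  ssb <- sum(tapply(values, labels, function(g) length(g) * (mean(g) - grand)^2))
  ssw <- sum(tapply(values, labels, function(g) sum((g - mean(g))^2)))
  df1 <- nlevels(labels) - 1
  df2 <- length(values) - nlevels(labels)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE), df = c(df1, df2))
}

# Exhaustive-grid RSS oracle over the bounded box of a combo's free
# parameters, honouring the elementwise volume constraint. Direct residual
# computation, independent of the fitter.
grid_rss_oracle <- function(cohort, model, combo, n_per_dim = 201L) {
  y <- cohort$fA_EM
  a <- (1 - cohort$fM_EM) * cohort[[paste0("fAW_", model)]]
  fM <- cohort$fM_EM
  e1 <- as.numeric(cohort$group == 1L)
  e2 <- as.numeric(cohort$group == 2L)
  free <- combo$free
  s_fix <- if (is.null(combo$fixed_s)) 1 else combo$fixed_s
  axes <- list(U1 = seq(0, 1, length.out = n_per_dim),
               U2 = seq(0, 1, length.out = n_per_dim),
               s = seq(0, 2, length.out = n_per_dim))
  if (length(free) == 0L) {
    pred <- a * s_fix
    return(sum((y - pred)^2))
  }
  g <- do.call(expand.grid, axes[free])
  sv <- if ("s" %in% free) g$s else rep(s_fix, nrow(g))
  u1 <- if ("U1" %in% free) g$U1 else rep(0, nrow(g))
  u2 <- if ("U2" %in% free) g$U2 else rep(0, nrow(g))
  pred <- outer(a, sv) - outer(e1, u1) - outer(e2, u2)
  feasible <- colSums(pred + fM - 1 > 1e-9) == 0
  if (!any(feasible)) return(Inf)
  res <- (y - pred)^2
  min(colSums(res)[feasible])
}

# Replace ANOVA-derived grouping with the generator's ground-truth groups.
assign_truth_groups <- function(cohort) {
  tr <- cohort_truth(cohort)
  cohort$group <- tr$group[match(paste(cohort$mouse_id, cohort$roi),
                                 paste(tr$mouse_id, tr$roi))]
  cohort
}

# Tiny hand-buildable cohort for I/O and validation tests.
tiny_cohort_df <- function() {
  data.frame(
    mouse_id = rep(c("m1", "m2"), each = 2),
    genotype = rep(c("Control", "Tsc2"), each = 2),
    roi = rep(c("genu", "fornix"), 2),
    fA_EM = c(0.35, 0.33, 0.10, 0.12),
    fM_EM = c(0.30, 0.31, 0.10, 0.11),
    fAW_WMTI = c(0.62, 0.60, 0.40, 0.42),
    fAW_NODDI = c(0.55, 0.53, 0.35, 0.37),
    stringsAsFactors = FALSE)
}
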