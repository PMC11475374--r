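# Genotype pooling. Calibration offsets are estimated per *group*, not per
# genotype; groups are derived from the data by testing which genotypes
# differ in the EM axonal volume fraction and merging the indistinguishable
# ones. On the study design this pools Controls/Pten/Rictor (group 1)
# against Tsc2 (group 2), giving N1 = 48 and N2 = 12 observations.

#' Classical one-way ANOVA
#'
#' @param values numeric response (here: `fA_EM` per observation).
#' @param labels grouping factor (genotype), >= 2 levels with >= 2
#'   observations each.
#' @return list with `F`, `p`, and `df` (numerator, denominator).
#' @export
one_way_anova <- function(values, labels) {
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L || any(table(labels) < 2L)) {
    stop("one_way_anova needs >= 2 groups with >= 2 observations each",
         call. = FALSE)
  }
  ft <- stats::oneway.test(values ~ labels, var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value),
       df = unname(ft$parameter))
}

#' Pairwise genotype differences
#'
#' Post-hoc companion to [one_way_anova()]. By default Tukey's HSD (a
#' multiplicity-adjusted all-pairs procedure); unadjusted pooled-SD pairwise
#' t-tests are available via `method = "t"`.
#'
#' @inheritParams one_way_anova
#' @param alpha significance level for the returned flags (default 0.05).
#' @param method `"tukey"` (default) or `"t"` (unadjusted pairwise t-tests).
#' @return list with symmetric matrices `p` (adjusted p-values, `NA` on the
#'   diagonal) and `significant` (logical, `p < alpha`), plus `alpha` and
#'   `method`.
#' @export
pairwise_differences <- function(values, labels, alpha = 0.05,
                                 method = c("tukey", "t")) {
  method <- match.arg(method)
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2L || any(table(labels) < 2L)) {
    stop("pairwise_differences needs >= 2 groups with >= 2 observations each",
         call. = FALSE)
  }
  lev <- levels(labels)
  p <- matrix(NA_real_, nlevels(labels), nlevels(labels),
              dimnames = list(lev, lev))
  if (method == "tukey") {
    tk <- stats::TukeyHSD(stats::aov(values ~ labels))$labels
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (i in seq_along(pairs)) {
      a <- pairs[[i]][1]; b <- pairs[[i]][2]
      p[a, b] <- p[b, a] <- tk[i, "p adj"]
    }
  } else {
    pt <- stats::pairwise.t.test(values, labels, p.adjust.method = "none",
                                 pool.sd = TRUE)$p.value
    for (a in rownames(pt)) for (b in colnames(pt)) {
      if (!is.na(pt[a, b])) p[a, b] <- p[b, a] <- pt[a, b]
    }
  }
  list(p = p, significant = p < alpha, alpha = alpha, method = method)
}

# connected components of an undirected adjacency matrix (tiny graphs)
components_of <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    frontier <- i
    while (length(frontier) > 0L) {
      comp[frontier] <- k
      nb <- which(apply(adj[frontier, , drop = FALSE], 2, any) & is.na(comp))
      frontier <- nb
    }
  }
  split(rownames(adj), comp)
}

#' Pool genotypes into calibration groups
#'
#' Builds the graph whose edges connect genotypes that are *not*
#' significantly different and takes its connected components. Exactly two
#' components are expected; group 1 is anchored to the component containing
#' Control. Any other component structure is ambiguous and raises an error
#' carrying the components, unless `override` supplies an explicit mapping.
#'
#' @param pairwise result of [pairwise_differences()].
#' @param override optional named integer vector genotype -> group in
#'   \{1, 2\}, used verbatim when pooling is ambiguous (or instead of it).
#' @return list of class `group_assignment`: `mapping` (named integer
#'   vector), `alpha`, `components`.
#' @export
pool_groups <- function(pairwise, override = NULL) {
  if (!is.null(override)) {
    stopifnot(all(override %in% c(1L, 2L)))
    return(structure(list(mapping = override, alpha = pairwise$alpha,
                          components = NULL, overridden = TRUE),
                     class = "group_assignment"))
  }
  sig <- pairwise$significant
  adj <- !sig
  diag(adj) <- TRUE
  comps <- components_of(adj)
  if (length(comps) != 2L) {
    err <- structure(
      class = c("axocal_pooling_ambiguous", "error", "condition"),
      list(message = sprintf(
        "pooling ambiguous: %d component(s) [%s]; supply an override mapping",
        length(comps),
        paste(vapply(comps, paste, "", collapse = "+"), collapse = " | ")),
        call = NULL, components = comps))
    stop(err)
  }
  first <- if ("Control" %in% comps[[1]]) 1L else 2L
  mapping <- integer(0)
  for (g in comps[[first]]) mapping[g] <- 1L
  for (g in comps[[-first + 3L]]) mapping[g] <- 2L
  structure(list(mapping = mapping, alpha = pairwise$alpha,
                 components = comps, overridden = FALSE),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  for (g in c(1L, 2L)) {
    cat(sprintf("group %d: %s\n", g,
                paste(names(x$mapping)[x$mapping == g], collapse = ", ")))
  }
  invisible(x)
}

#' Assign calibration groups to a cohort
#'
#' Runs the ANOVA + pairwise + pooling chain on a cohort's `fA_EM` values
#' and writes the resulting `group` column.
#'
#' @param cohort an `axon_cohort`.
#' @param alpha significance level (default 0.05).
#' @param method pairwise procedure, see [pairwise_differences()].
#' @param override optional explicit genotype -> group mapping.
#' @return the cohort with a `group` column, plus attribute `group_assignment`.
#' @export
assign_groups <- function(cohort, alpha = 0.05, method = "tukey",
                          override = NULL) {
  stopifnot(inherits(cohort, "axon_cohort"))
  pw <- pairwise_differences(cohort$fA_EM, cohort$genotype,
                             alpha = alpha, method = method)
  ga <- pool_groups(pw, override = override)
  cohort$group <- unname(ga$mapping[cohort$genotype])
  attr(cohort, "group_assignment") <- ga
  attr(cohort, "anova") <- one_way_anova(cohort$fA_EM, cohort$genotype)
  cohort
}

#' Group sizes of an assigned cohort
#' @param cohort an `axon_cohort` with a `group` column.
#' @return integer vector `c(N1, N2)`.
#' @export
group_sizes <- function(cohort) {
  stopifnot("group" %in% names(cohort))
  c(N1 = sum(cohort$group == 1L), N2 = sum(cohort$group == 2L))
}
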