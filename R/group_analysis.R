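#' Two-sided Wilcoxon rank-sum comparison of two groups
#'
#' Compares independent samples with the Wilcoxon--Mann--Whitney test.
#' The exact null distribution is enumerated when the combined sample size
#' is at most 12 and there are no ties; otherwise the normal approximation
#' with tie and continuity corrections is used. Summaries report medians
#' and interquartile ranges (linear-interpolation quartiles) per side and
#' the difference of group medians (`median_b - median_a`).
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return a one-row `data.frame` (class `comparison_result`) with columns
#'   `statistic`, `p_value`, `median_a`, `iqr_lo_a`, `iqr_hi_a`,
#'   `median_b`, `iqr_lo_b`, `iqr_hi_b`, `median_diff`, `n_a`, `n_b`,
#'   `method`.
#' @export
rank_sum_test <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  all_vals <- c(values_a, values_b)
  ties <- anyDuplicated(all_vals) > 0L
  if (length(unique(all_vals)) == 1L) {
    warning("all values identical; p = 1")
    return(comparison_row(NA_real_, 1, values_a, values_b,
                          "rank-sum (degenerate)"))
  }
  exact <- (length(all_vals) <= 12L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            exact = exact, correct = TRUE))
  method <- if (exact) "rank-sum (exact)" else "rank-sum (normal approx.)"
  comparison_row(unname(wt$statistic), wt$p.value, values_a, values_b,
                 method)
}

#' Two-sided Wilcoxon signed-rank comparison of paired measurements
#'
#' Zero differences are dropped before ranking. Exact enumeration of the
#' sign patterns is used for at most 12 nonzero differences without tied
#' absolute values; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param paired_a,paired_b numeric vectors of equal length.
#' @return a one-row `data.frame` as in [rank_sum_test()].
#' @export
signed_rank_test <- function(paired_a, paired_b) {
  stopifnot(length(paired_a) == length(paired_b), length(paired_a) >= 2L)
  d <- paired_b - paired_a
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    warning("all paired differences are zero; p = 1")
    return(comparison_row(NA_real_, 1, paired_a, paired_b,
                          "signed-rank (degenerate)"))
  }
  if (length(nz) < 2L) {
    warning("fewer than 2 nonzero differences; p = 1")
    return(comparison_row(NA_real_, 1, paired_a, paired_b,
                          "signed-rank (degenerate)"))
  }
  exact <- (length(nz) <= 12L) && !anyDuplicated(abs(nz))
  wt <- suppressWarnings(stats::wilcox.test(nz, exact = exact,
                                            correct = TRUE))
  method <- if (exact) "signed-rank (exact)" else
    "signed-rank (normal approx.)"
  comparison_row(unname(wt$statistic), wt$p.value, paired_a, paired_b,
                 method)
}

comparison_row <- function(statistic, p, a, b, method) {
  qa <- stats::quantile(a, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  qb <- stats::quantile(b, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  out <- data.frame(statistic = statistic, p_value = p,
                    median_a = qa[2], iqr_lo_a = qa[1], iqr_hi_a = qa[3],
                    median_b = qb[2], iqr_lo_b = qb[1], iqr_hi_b = qb[3],
                    median_diff = qb[2] - qa[2],
                    n_a = length(a), n_b = length(b), method = method)
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' Depot-wise group and depot comparison table
#'
#' Reproduces the structure of a two-group depot comparison study: for
#' every depot and composition parameter, group A vs group B is tested
#' with the rank-sum test; within each group, depot pairs (VAT vs SAT and
#' dSAT vs sSAT) are tested with the signed-rank test on
#' pairwise-complete subjects. Raw (unadjusted) p-values are reported
#' throughout.
#'
#' @param table `data.frame` with columns `subject`, `group` (two
#'   levels), `depot`, and the parameters `fsfa`, `fmufa`, `fpufa`,
#'   `ndb`, `nmidb` (a subset is allowed).
#' @param params parameter columns to compare.
#' @return list with `group_comparison` (tidy table: depot x parameter,
#'   medians/IQRs per group, median difference B - A, p-value, test) and
#'   `depot_comparison` (within-group depot pairs).
#' @export
depot_comparison_table <- function(table,
                                   params = c("fsfa", "fmufa", "fpufa",
                                              "ndb", "nmidb")) {
  stopifnot(nrow(table) > 0, all(c("subject", "group", "depot")
                                 %in% names(table)))
  params <- intersect(params, names(table))
  groups <- sort(unique(table$group))
  stopifnot(length(groups) == 2L)
  depots <- unique(table$depot)
  grows <- list()
  for (d in depots) for (p in params) {
    a <- table[table$depot == d & table$group == groups[1L], p]
    b <- table[table$depot == d & table$group == groups[2L], p]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L)
      stop("fewer than 2 subjects per group for depot ", d)
    res <- rank_sum_test(a, b)
    grows[[length(grows) + 1L]] <- cbind(
      data.frame(depot = d, parameter = p,
                 group_a = groups[1L], group_b = groups[2L]), res)
  }
  pairs <- list(c("vat", "sat"), c("dsat", "ssat"))
  drows <- list()
  for (g in groups) for (pr in pairs) {
    if (!all(pr %in% depots)) next
    ta <- table[table$group == g & table$depot == pr[1L], ]
    tb <- table[table$group == g & table$depot == pr[2L], ]
    common <- intersect(ta$subject, tb$subject)
    dropped <- setdiff(union(ta$subject, tb$subject), common)
    if (length(dropped))
      message(length(dropped), " subject(s) lacking both depots '",
              pr[1L], "'/'", pr[2L], "' excluded pairwise in group ", g)
    if (length(common) < 2L) next
    ta <- ta[match(common, ta$subject), ]
    tb <- tb[match(common, tb$subject), ]
    for (p in params) {
      res <- signed_rank_test(ta[[p]], tb[[p]])
      drows[[length(drows) + 1L]] <- cbind(
        data.frame(group = g, depot_a = pr[1L], depot_b = pr[2L],
                   parameter = p), res)
    }
  }
  list(group_comparison = do.call(rbind, grows),
       depot_comparison = if (length(drows)) do.call(rbind, drows) else
         NULL)
}

#' Per-subject depot composition table from fitted cohort images
#'
#' Runs segmentation, ROI refinement and ROI averaging for one subject's
#' fitted maps and returns the rows of the subject-depot table.
#'
#' @param fac a `fac_maps` object for the subject.
#' @param truth the subject's phantom truth (for the manual outlines:
#'   cavity polygon, fascia polygon and SAT seed), as produced by
#'   [generate_phantom()].
#' @param subject,group identifiers copied into the rows.
#' @param growth_threshold fat-fraction threshold of the SAT region
#'   growing.
#' @param ff_min,t2star_min ROI refinement thresholds.
#' @return `data.frame` with one row per depot (`sat`, `vat`, `dsat`,
#'   `ssat`).
#' @export
subject_depot_rows <- function(fac, truth, subject, group,
                               growth_threshold = 0.5, ff_min = 0.9,
                               t2star_min = 0.020) {
  ff <- as_slice(fac$fat_fraction)
  t2s <- as_slice(fac$t2star)
  sat <- region_grow_sat(ff, seed = truth$seed_voxel,
                         growth_threshold = growth_threshold)
  vat <- delineate_vat(truth$cavity_polygon, sat, ff)
  sp <- split_sat_depots(sat, truth$fascia_polygon)
  masks <- list(sat = sat, vat = vat, dsat = sp$dsat, ssat = sp$ssat)
  fac2 <- fac
  for (nm in c("fsfa", "fmufa", "fpufa", "fat_fraction", "t2star", "ndb",
               "nmidb", "valid"))
    fac2[[nm]] <- as_slice(fac[[nm]])
  rows <- lapply(names(masks), function(d) {
    roi <- refine_roi(masks[[d]], ff, t2s, ff_min = ff_min,
                      t2star_min = t2star_min)
    cbind(data.frame(subject = subject, group = group, depot = d),
          depot_mean_fac(fac2, roi))
  })
  do.call(rbind, rows)
}
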