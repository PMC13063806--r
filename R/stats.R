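## Replicate-level aggregation and the study-level statistics: mean +/- sd
## over independent replicates, classical one-way ANOVA with vs-control
## contrasts, Pearson correlation, and fold-change (ratio) tables for
## strong-binding times.

#' Aggregate replicate values to mean +/- sd
#'
#' Unbiased sd (n-1 denominator).  Groups with a single replicate get
#' `sd = NA` and `single_replicate = TRUE`.
#'
#' @param table data.frame of replicate-level values.
#' @param value name of the value column.
#' @param by character vector of grouping columns.
#' @return data.frame with the grouping columns plus `mean`, `sd`, `n`,
#'   `single_replicate`.
#' @export
aggregate_replicates <- function(table, value = "value",
                                 by = c("system", "species", "metric")) {
  by <- intersect(by, names(table))
  if (!length(by)) stop_input("no grouping columns present")
  if (!value %in% names(table)) stop_input("value column '%s' missing", value)
  key <- interaction(table[by], drop = TRUE, sep = "\r")
  sp <- split(table[[value]], key)
  meta <- table[!duplicated(key), by, drop = FALSE]
  meta <- meta[match(names(sp), key[!duplicated(key)]), , drop = FALSE]
  out <- cbind(meta,
               mean = vapply(sp, mean, 0),
               sd = vapply(sp, function(x)
                 if (length(x) > 1) stats::sd(x) else NA_real_, 0),
               n = vapply(sp, length, 0L))
  out$single_replicate <- out$n == 1
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with vs-control contrasts
#'
#' Classical (equal-variance) one-way F test across all groups, plus
#' two-sided Welch t tests of each non-control group against the control,
#' flagged at 0.05 and 0.01.  Contrast p values are uncorrected by
#' default; `p_adjust = "bonferroni"` applies a Dunnett-style Bonferroni
#' correction.
#'
#' @param values numeric vector of observations.
#' @param groups factor/character of group labels (same length).
#' @param control label of the control group (default: first group in
#'   sort order); set `NULL` or `NA` to skip the contrasts.
#' @param p_adjust `"none"` or `"bonferroni"` for the vs-control p values.
#' @return object of class `anova_comparison`: list with `f`, `p`,
#'   `df`, `group_stats` (mean/sd/n per group) and `contrasts`
#'   (group, p, sig_0.05, sig_0.01).
#' @export
one_way_anova <- function(values, groups, control,
                          p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  sp <- split(values, groups)
  if (length(sp) < 2) stop_input("need >= 2 groups")
  if (any(vapply(sp, length, 0L) < 2))
    stop_input("every group needs >= 2 values")
  if (all(vapply(sp, stats::var, 0) == 0))
    stop_input("zero within-group variance everywhere; F undefined")
  ft <- stats::oneway.test(values ~ factor(groups), var.equal = TRUE)
  group_stats <- data.frame(group = names(sp),
                            mean = vapply(sp, mean, 0),
                            sd = vapply(sp, stats::sd, 0),
                            n = vapply(sp, length, 0L))
  rownames(group_stats) <- NULL
  contrasts <- NULL
  if (missing(control)) control <- names(sp)[1]
  if (!is.null(control) && !is.na(control) && control %in% names(sp)) {
    other <- setdiff(names(sp), control)
    pv <- vapply(other, function(g)
      stats::t.test(sp[[g]], sp[[control]])$p.value, 0)
    if (p_adjust == "bonferroni") pv <- pmin(1, pv * length(other))
    contrasts <- data.frame(group = other, p = unname(pv),
                            sig_0.05 = unname(pv < 0.05),
                            sig_0.01 = unname(pv < 0.01),
                            p_adjust = p_adjust)
  }
  structure(list(f = unname(ft$statistic), p = unname(ft$p.value),
                 df = unname(ft$parameter), group_stats = group_stats,
                 contrasts = contrasts, control = control),
            class = "anova_comparison")
}

#' @export
print.anova_comparison <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%g, %g) = %.4f, p = %.4g\n",
              x$df[1], x$df[2], x$f, x$p))
  print(x$group_stats)
  if (!is.null(x$contrasts)) {
    cat(sprintf("vs-control ('%s') Welch t tests (%s):\n", x$control,
                x$contrasts$p_adjust[1]))
    print(x$contrasts[, c("group", "p", "sig_0.05", "sig_0.01")])
  }
  invisible(x)
}

#' Pearson correlation with t-based p value
#'
#' @param x,y numeric vectors, length >= 3.
#' @return list with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop_input("x and y lengths differ")
  if (length(x) < 3) stop_input("need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_input("non-finite values")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Fold-change table of strong-binding times against a control compound
#'
#' Fold changes are computed on replicate means (mean time of each
#' compound divided by the mean time of the control, per membrane/lipid),
#' reported rounded to one decimal alongside the full-precision value.
#'
#' @param binding_times data.frame with columns `membrane`, `lipid`,
#'   `compound`, `mean` (ns) -- e.g. an aggregated set of
#'   [strong_binding_time()] results, or a published reference table.
#' @param control compound label to divide by.
#' @return data.frame with `membrane`, `lipid`, `compound`,
#'   `fold_change` (full precision) and `fold_change_1dp`.
#' @export
ratio_table <- function(binding_times, control) {
  need <- c("membrane", "lipid", "compound", "mean")
  missing_cols <- setdiff(need, names(binding_times))
  if (length(missing_cols))
    stop_input("binding_times missing column(s): %s",
               paste(missing_cols, collapse = ", "))
  if (!control %in% binding_times$compound)
    stop_input("control compound '%s' not present", control)
  key <- paste(binding_times$membrane, binding_times$lipid)
  ctl <- binding_times[binding_times$compound == control, ]
  ctl_mean <- ctl$mean[match(key, paste(ctl$membrane, ctl$lipid))]
  fc <- binding_times$mean / ctl_mean
  data.frame(membrane = binding_times$membrane,
             lipid = binding_times$lipid,
             compound = binding_times$compound,
             fold_change = fc,
             fold_change_1dp = round(fc, 1))
}

#' Reference strong-binding times of three polyphenols (published values)
#'
#' Strong lipid binding times (ns; mean +/- sd over three replicates of
#' 500 ns atomistic simulations) of epicatechin (EC) and two dimeric
#' polyphenols (ECG dimer, EGCG dimer) in Ld (POPC) and Lo (PSM + CHOL)
#' membranes, as published for these systems.  Shipped as a plain-text
#' table; used as the worked-example input for [ratio_table()].
#'
#' @return data.frame with `membrane`, `lipid`, `compound`, `mean`, `sd`.
#' @export
reference_binding_times <- function() {
  utils::read.delim(system.file("extdata", "strong_binding_times.tsv",
                                package = "lipidraft"),
                    stringsAsFactors = FALSE)
}

#' Reference membrane metrics of the pure Lo and Ld systems
#'
#' Published structural/dynamic metrics of the pure liquid-disordered
#' (POPC) and liquid-ordered (PSM/CHOL 1:2) bilayers: area per lipid,
#' thickness, lateral diffusion coefficient and area compressibility
#' modulus.
#'
#' @return data.frame with `membrane`, `metric`, `value`, `sd`, `unit`.
#' @export
reference_membrane_metrics <- function() {
  utils::read.delim(system.file("extdata", "membrane_metrics.tsv",
                                package = "lipidraft"),
                    stringsAsFactors = FALSE)
}
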