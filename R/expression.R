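# Efficiency-adjusted qPCR relative quantification (Pfaffl-type), spike-in
# QC, one-way ANOVA with Fisher's LSD, pooled t-tests, fold changes of
# group means, ELISA total-protein normalization and box-plot summaries.

#' Efficiency-adjusted relative expression (Pfaffl-type ratio)
#'
#' \deqn{ratio = E_t^{\Delta Ct_t} / E_r^{\Delta Ct_r}, \quad
#'       \Delta Ct = Ct_{calibrator} - Ct_{sample}}
#' With both efficiencies at 2 this reduces exactly to
#' \eqn{2^{-\Delta\Delta Ct}}. Targets with Ct above the detectability
#' cutoff are reported as missing (NA), not zero. Vectorized over samples.
#'
#' @param ct_target,ct_ref sample Ct of the target and reference analyte.
#' @param e_target,e_ref amplification efficiencies in (1, 2.2].
#' @param calibrator_ct_target,calibrator_ct_ref calibrator (mean) Ct of the
#'   target and reference analyte.
#' @param ct_cutoff detectability cutoff (default 40 cycles).
#' @return numeric ratio vector (> 0, NA where undetectable).
#' @export
relative_expression <- function(ct_target, ct_ref, e_target = 2, e_ref = 2,
                                calibrator_ct_target, calibrator_ct_ref,
                                ct_cutoff = 40) {
  if (any(e_target <= 1 | e_target > 2.2) || any(e_ref <= 1 | e_ref > 2.2)) {
    stop("efficiencies must lie in (1, 2.2]", call. = FALSE)
  }
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_ref))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  ratio <- e_target^(calibrator_ct_target - ct_target) /
    e_ref^(calibrator_ct_ref - ct_ref)
  ratio[ct_target > ct_cutoff] <- NA_real_
  ratio
}

#' Per-sample relative expression for one compartment of a Ct table
#'
#' For every target analyte (everything except the reference and spike-in),
#' computes the Pfaffl-type ratio against the per-sample reference Ct, with
#' the calibrator defined as the mean target / reference Ct of the
#' designated calibrator group (plasma: control; tissue: peritumoral).
#'
#' @param ct_data tibble with columns \code{sample_id}, \code{group},
#'   \code{analyte}, \code{ct}, \code{efficiency} (single compartment).
#' @param reference_analyte endogenous normalizer id (default "U6").
#' @param calibrator_group value of \code{group_col} defining the
#'   calibrator.
#' @param group_col column holding the calibrator grouping (use
#'   \code{"compartment"} for tissue).
#' @param spike_analyte spike-in id excluded from quantification.
#' @param ct_cutoff detectability cutoff.
#' @return tibble \code{sample_id}, \code{group}, \code{analyte},
#'   \code{ratio}.
#' @export
relative_expression_table <- function(ct_data, reference_analyte = "U6",
                                      calibrator_group = "control",
                                      group_col = "group",
                                      spike_analyte = "cel-miR-39-3p",
                                      ct_cutoff = 40) {
  require_columns(ct_data, c("sample_id", group_col, "analyte", "ct",
                             "efficiency"), "Ct table")
  ref <- ct_data[ct_data$analyte == reference_analyte, ]
  if (nrow(ref) == 0L) stop("reference analyte '", reference_analyte,
                            "' not found", call. = FALSE)
  # reference Ct per (sample, stratum): tissue tables repeat sample ids
  # across compartments
  ref_key <- paste(ref$sample_id, ref[[group_col]])
  ref_ct <- stats::setNames(ref$ct, ref_key)
  e_ref <- stats::setNames(ref$efficiency, ref_key)

  targets <- ct_data[!ct_data$analyte %in% c(reference_analyte,
                                             spike_analyte), ]
  cal <- targets[targets[[group_col]] == calibrator_group, ]
  if (nrow(cal) == 0L) stop("no rows in calibrator group '",
                            calibrator_group, "'", call. = FALSE)
  cal_target <- tapply(cal$ct[cal$ct <= ct_cutoff],
                       cal$analyte[cal$ct <= ct_cutoff], mean)
  cal_ref_ct <- mean(ref$ct[ref[[group_col]] == calibrator_group])

  key <- paste(targets$sample_id, targets[[group_col]])
  ratio <- rep(NA_real_, nrow(targets))
  known <- targets$analyte %in% names(cal_target)
  ratio[known] <- relative_expression(
    ct_target = targets$ct[known],
    ct_ref = ref_ct[key[known]],
    e_target = targets$efficiency[known],
    e_ref = e_ref[key[known]],
    calibrator_ct_target = cal_target[targets$analyte[known]],
    calibrator_ct_ref = cal_ref_ct,
    ct_cutoff = ct_cutoff)
  tibble::tibble(sample_id = targets$sample_id,
                 group = targets[[group_col]],
                 analyte = targets$analyte,
                 ratio = unname(ratio))
}

#' Spike-in quality control
#'
#' Flags samples whose spike-in Ct deviates from the cohort mean by more
#' than \code{max_dev} cohort SDs. Flagged samples are reported, not
#' dropped. With fewer than 3 samples the QC is skipped with a warning.
#'
#' @param spike_cts numeric spike-in Ct values, optionally named by sample.
#' @param max_dev deviation rule in cohort SDs (default 2).
#' @return tibble \code{sample_id}, \code{ct}, \code{deviation},
#'   \code{pass} (logical, NA when skipped).
#' @export
spike_in_qc <- function(spike_cts, max_dev = 2) {
  ids <- names(spike_cts) %||% as.character(seq_along(spike_cts))
  if (length(spike_cts) < 3L) {
    warning("fewer than 3 samples; spike-in QC skipped")
    return(tibble::tibble(sample_id = ids, ct = unname(spike_cts),
                          deviation = NA_real_, pass = NA))
  }
  dev <- spike_cts - mean(spike_cts)
  s <- stats::sd(spike_cts)
  pass <- if (s == 0) rep(TRUE, length(spike_cts)) else abs(dev) <= max_dev * s
  tibble::tibble(sample_id = ids, ct = unname(spike_cts),
                 deviation = unname(dev), pass = unname(pass))
}

#' One-way ANOVA with Fisher's LSD post hoc
#'
#' Fixed-effects one-way ANOVA computed from the between/within mean
#' squares, followed by Fisher's least-significant-difference pairwise
#' t-tests that share the pooled within-group MSE and its degrees of
#' freedom. No multiplicity adjustment is applied to the pairwise p-values
#' (the LSD definition). With exactly two groups, F equals the squared
#' pooled-variance t.
#'
#' @param values numeric response (relative expression).
#' @param groups grouping factor (>= 2 groups, each with >= 2 values).
#' @return object of class \code{group_comparison}: list with \code{means},
#'   \code{n}, \code{F}, \code{df}, \code{p_overall}, \code{mse} and a
#'   \code{pairwise} tibble (\code{group1}, \code{group2}, \code{diff},
#'   \code{t}, \code{p}, \code{fold} = mean1/mean2).
#' @export
anova_lsd <- function(values, groups) {
  keep <- !is.na(values)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  k <- nlevels(groups)
  ni <- tabulate(groups)
  if (k < 2L || any(ni < 2L)) {
    stop("need at least 2 groups with at least 2 values each", call. = FALSE)
  }
  n_tot <- length(values)
  mi <- tapply(values, groups, mean)
  grand <- mean(values)
  ssb <- sum(ni * (mi - grand)^2)
  ssw <- sum((values - mi[groups])^2)
  df1 <- k - 1L
  df2 <- n_tot - k
  msw <- ssw / df2
  if (msw == 0) stop("zero within-group variance everywhere; F undefined",
                     call. = FALSE)
  f_stat <- (ssb / df1) / msw
  p_overall <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)

  pairs <- utils::combn(levels(groups), 2L)
  pw <- vapply(seq_len(ncol(pairs)), function(cidx) {
    pr <- pairs[, cidx]
    i <- pr[1]; j <- pr[2]
    se <- sqrt(msw * (1 / ni[match(i, levels(groups))] +
                        1 / ni[match(j, levels(groups))]))
    tt <- (mi[[i]] - mi[[j]]) / se
    c(diff = mi[[i]] - mi[[j]], t = tt,
      p = 2 * stats::pt(abs(tt), df2, lower.tail = FALSE),
      fold = mi[[i]] / mi[[j]])
  }, numeric(4))
  pairwise <- tibble::tibble(group1 = pairs[1L, ], group2 = pairs[2L, ],
                             diff = pw["diff", ], t = pw["t", ],
                             p = pw["p", ], fold = pw["fold", ])
  structure(list(means = mi, n = stats::setNames(ni, levels(groups)),
                 F = f_stat, df = c(df1 = df1, df2 = df2),
                 p_overall = p_overall, mse = msw, pairwise = pairwise),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> F(%d, %d) = %.4g, p = %.4g\n",
              x$df[["df1"]], x$df[["df2"]], x$F, x$p_overall))
  print(x$pairwise)
  invisible(x)
}

#' Two-sample t-test (pooled variance by default)
#'
#' @param x,y the two arms (e.g. tumor and peritumoral values), each with at
#'   least 2 observations.
#' @param paired paired mode for patient-matched samples.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
two_sample_t <- function(x, y, paired = FALSE) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each arm needs at least 2 observations", call. = FALSE)
  }
  ht <- stats::t.test(x, y, paired = paired, var.equal = !paired)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Fold change of group means, with reporting rounding
#'
#' Ratio of group means of relative expression, rounded half-up to
#' \code{round_to} decimals for reporting; the unrounded value is retained.
#'
#' @param group_means named numeric vector of group means.
#' @param numerator_group,denominator_group group names.
#' @param round_to reporting decimals (default 2).
#' @return list with \code{fold} (rounded) and \code{unrounded}.
#' @export
group_fold_change <- function(group_means, numerator_group,
                              denominator_group, round_to = 2L) {
  if (!all(c(numerator_group, denominator_group) %in% names(group_means))) {
    stop("group not found in group_means", call. = FALSE)
  }
  den <- group_means[[denominator_group]]
  if (!is.finite(den) || den <= 0) {
    stop("denominator group mean must be positive", call. = FALSE)
  }
  raw <- group_means[[numerator_group]] / den
  list(fold = round_half_up(raw, round_to), unrounded = raw)
}

#' Normalize an ELISA concentration to total protein
#'
#' Converts an assay concentration (pg/mL) to the analyte mass in the
#' assayed volume and divides by the total protein mass (ng), giving pg/ng
#' of total protein. Concentrations outside the kit's detection range are
#' flagged, not dropped.
#'
#' @param concentration concentration(s) in pg/mL.
#' @param assay_volume_ml assayed volume in mL.
#' @param total_protein_ng total protein in the assayed volume, ng.
#' @param detection_range kit detection range in pg/mL (default
#'   \code{c(9.38, 600)}).
#' @return tibble \code{concentration}, \code{normalized} (pg/ng),
#'   \code{in_range}.
#' @export
elisa_normalize <- function(concentration, assay_volume_ml,
                            total_protein_ng,
                            detection_range = c(9.38, 600)) {
  if (any(total_protein_ng <= 0)) {
    stop("total protein must be positive", call. = FALSE)
  }
  pg <- concentration * assay_volume_ml
  tibble::tibble(
    concentration = concentration,
    normalized = pg / total_protein_ng,
    in_range = concentration >= detection_range[1] &
      concentration <= detection_range[2])
}

#' Box-plot summary statistics
#'
#' Median, quartiles (R default quantile type 7), whiskers at the most
#' extreme values within 1.5 IQR of the quartiles, outliers beyond the
#' whiskers, and the mean.
#'
#' @param values numeric vector (NAs dropped).
#' @return list \code{n}, \code{mean}, \code{median}, \code{q1}, \code{q3},
#'   \code{whisker_low}, \code{whisker_high}, \code{outliers}.
#' @export
boxplot_summary <- function(values) {
  v <- values[!is.na(values)]
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- v[v >= lo_fence & v <= hi_fence]
  list(n = length(v), mean = mean(v), median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(v[v < lo_fence | v > hi_fence]))
}
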