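# Plate-count arithmetic and CFU label-claim auditing: triplicate pour-plate
# means, above/below-claim comparison on the log10 scale, the
# potency-basis group test, and the DNA-yield cell-equivalence calculation
# used for limit-of-detection bookkeeping.

#' CFU/g from triplicate plate counts
#'
#' Colony counts are multiplied by the dilution factor and averaged across
#' the replicates; the standard deviation is the sample SD of the three
#' scaled counts. All-zero plates are flagged below detection.
#'
#' @param colonies integer vector of 3 colony counts (>= 0).
#' @param dilution_factor scalar multiplier (> 0).
#' @return object of class `plate_count`: colonies, dilution_factor,
#'   cfu_per_g (mean), cfu_sd, below_detection.
#' @export
#' @examples
#' cfu_from_plates(c(100, 110, 120), 1e8)$cfu_per_g # 1.1e10
cfu_from_plates <- function(colonies, dilution_factor) {
  stopifnot(length(colonies) == 3L, all(colonies >= 0), dilution_factor > 0)
  scaled <- colonies * dilution_factor
  structure(list(colonies = colonies, dilution_factor = dilution_factor,
                 cfu_per_g = mean(scaled), cfu_sd = sd(scaled),
                 below_detection = all(colonies == 0)),
            class = "plate_count")
}

#' Compare a measured CFU count to a label claim
#'
#' log10_diff = log10(measured) - log10(claimed). Measured equal to the
#' claim counts as "above" (the product meets its claim); an excess of more
#' than one log is flagged.
#'
#' @param measured measured CFU/g (> 0).
#' @param claim a `label_claim`, or a claimed CFU/g scalar.
#' @return object of class `cfu_comparison`: product_id, measured_cfu,
#'   claimed_cfu, log10_diff, status ("above"/"below"), excess_gt_1log.
#' @export
compare_claim <- function(measured, claim) {
  if (inherits(claim, "label_claim")) {
    claimed <- claim$claimed_cfu_per_g
    product_id <- claim$product_id
  } else {
    claimed <- claim
    product_id <- NA_character_
  }
  stopifnot(measured > 0, claimed > 0)
  diff <- log10(measured) - log10(claimed)
  structure(list(product_id = product_id, measured_cfu = measured,
                 claimed_cfu = claimed, log10_diff = diff,
                 status = if (diff >= 0) "above" else "below",
                 excess_gt_1log = diff > 1),
            class = "cfu_comparison")
}

#' Tabulate CFU comparisons for a product cohort
#' @param comparisons list of `cfu_comparison` objects.
#' @return data.frame with one row per product plus summary attributes
#'   `n_above` and `pct_above` (one decimal).
#' @export
summarize_cfu_audit <- function(comparisons) {
  df <- do.call(rbind, lapply(comparisons, function(x) {
    data.frame(product_id = x$product_id, measured_cfu = x$measured_cfu,
               claimed_cfu = x$claimed_cfu, log10_diff = x$log10_diff,
               status = x$status, excess_gt_1log = x$excess_gt_1log,
               stringsAsFactors = FALSE)
  }))
  attr(df, "n_above") <- sum(df$status == "above")
  attr(df, "pct_above") <- round(100 * sum(df$status == "above") / nrow(df), 1)
  df
}

#' Two-sample test of CFU between potency-basis groups
#'
#' Welch two-sample t-test on log10 CFU (products labeled at time of
#' manufacture vs through expiration). Pooled-variance and raw-scale
#' variants are exposed.
#'
#' @param group_a,group_b numeric CFU vectors (each n >= 2).
#' @param log_scale test on log10 CFU (default TRUE).
#' @param var_equal pooled-variance t-test instead of Welch.
#' @return list with `statistic` and `p_value`.
#' @export
potency_basis_test <- function(group_a, group_b, log_scale = TRUE,
                               var_equal = FALSE) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  if (log_scale) {
    stopifnot(all(group_a > 0), all(group_b > 0))
    group_a <- log10(group_a)
    group_b <- log10(group_b)
  }
  ht <- t.test(group_a, group_b, var.equal = var_equal)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Cell equivalence of a DNA concentration
#'
#' Scales a DNA concentration to a cell count through a yield calibration
#' (cells in -> ng/uL out), reported to 2 significant figures. With the
#' calibration 1.2e10 cells -> 51.8 ng/uL, a 1 pg/uL working concentration
#' corresponds to 2.3e5 cells of starting material.
#'
#' @param target_conc_pg target DNA concentration in pg/uL (> 0).
#' @param cells_in cells used in the calibration (> 0).
#' @param dna_conc_out_ng calibration DNA yield in ng/uL (> 0).
#' @return cell count, rounded to 2 significant figures.
#' @export
#' @examples
#' cells_per_concentration(1, 1.2e10, 51.8) # 2.3e5
cells_per_concentration <- function(target_conc_pg, cells_in = 1.2e10,
                                    dna_conc_out_ng = 51.8) {
  if (target_conc_pg <= 0 || cells_in <= 0 || dna_conc_out_ng <= 0) {
    stop("all concentrations and cell counts must be positive")
  }
  cells <- target_conc_pg / (dna_conc_out_ng * 1000) * cells_in
  signif(cells, 2)
}

#' Export a CFU comparison report as a tab-separated table
#'
#' @param comparisons list of `cfu_comparison` objects.
#' @param claims optional list of matching `label_claim` objects supplying
#'   months_to_expiration and potency_basis columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cfu_report <- function(comparisons, path, claims = NULL) {
  df <- summarize_cfu_audit(comparisons)
  if (!is.null(claims)) {
    idx <- match(df$product_id,
                 vapply(claims, function(cl) cl$product_id, ""))
    df$months_to_expiration <-
      vapply(claims[idx], function(cl) cl$months_to_expiration, 0)
    df$potency_basis <- vapply(claims[idx], function(cl) cl$potency_basis, "")
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
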