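#' Exact two-sided Wilcoxon signed-rank test for paired data
#'
#' Exact p-value from the permutation null over all sign assignments of the
#' nonzero paired differences. Zero differences are dropped before ranking
#' (reducing n); ties among absolute differences receive midranks. The null
#' distribution of the positive-rank sum is computed exactly by convolution
#' over the (doubled, hence integer) midranks, so ties and any n are handled
#' without approximation; the two-sided p is twice the smaller tail
#' probability, capped at 1. With 8 pairs all changed in the same direction
#' this yields 2/2^8 = 0.0078125, the most extreme attainable value —
#' unreachable by the normal approximation.
#'
#' @param before,after paired numeric vectors of equal length.
#' @return The exact two-sided p-value. If all differences are zero, returns
#'   1 with attribute `degenerate = TRUE`.
#' @examples
#' wilcoxon_exact(1:8, 1:8 + 1)   # all shifts positive: 2/256
#' @export
wilcoxon_exact <- function(before, after) {
  if (length(before) != length(after))
    stop("'before' and 'after' must have equal length", call. = FALSE)
  if (length(before) < 1L) stop("need at least one pair", call. = FALSE)
  d <- after - before
  d <- d[d != 0]
  if (length(d) == 0L) {
    p <- 1
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  ranks2 <- as.integer(round(2 * rank(abs(d))))  # doubled midranks: integers
  W2 <- sum(ranks2[d > 0])
  # exact null of the (doubled) positive-rank sum by convolution
  total <- sum(ranks2)
  f <- numeric(total + 1L)  # f[s + 1] = #assignments with doubled sum s
  f[1L] <- 1
  for (r2 in ranks2) {
    idx <- (total + 1L):(r2 + 1L)
    f[idx] <- f[idx] + f[idx - r2]
  }
  f <- f / 2^length(d)
  lo <- sum(f[seq_len(W2 + 1L)])          # P(W <= w)
  hi <- sum(f[(W2 + 1L):(total + 1L)])    # P(W >= w)
  min(1, 2 * min(lo, hi))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending, scale `p_(i) * m / i`, enforce
#' monotonicity by a cumulative minimum from the largest rank, cap at 1, and
#' return in input order. Thin validated surface over the standard step-up
#' implementation. Adjustment is always applied to unrounded p-values.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, each `>=` its raw p and `<= 1`.
#' @examples
#' bh_adjust(c(0.00781, 0.0391, 0.742))
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvals, method = "BH")
}

#' Relative change in total receptor number
#'
#' Under the assumption that the intrinsic binding constant is unchanged by
#' treatment, the apparent dissociation constant is inversely proportional
#' to the total receptor number, so the relative receptor change is
#' `Delta = K1'_before / K1'_after - 1`
#' (equivalently `(1/K1'_after - 1/K1'_before) / (1/K1'_before)`).
#' Negative values mean the receptor count decreased.
#'
#' @param K1p_before,K1p_after apparent dissociation constants (> 0);
#'   vectorized.
#' @return Delta (dimensionless).
#' @examples
#' delta_receptor(0.005, 0.011)  # ~ -0.55: a 55% receptor decrease
#' @export
delta_receptor <- function(K1p_before, K1p_after) {
  if (any(K1p_before <= 0) || any(K1p_after <= 0))
    stop("dissociation constants must be > 0", call. = FALSE)
  K1p_before / K1p_after - 1
}

#' Peak observed glucose of a record
#'
#' @param record a `subject_record`.
#' @return Maximum of the observed glucose series (g/L).
#' @export
gmax <- function(record) max(record$G)

#' Assemble a per-visit parameter table
#'
#' One row per subject, one column per fitted parameter plus `G_max`
#' (computed from the observed glucose series of the matching record).
#'
#' @param fits named list of [profile_fit()] results (names = subject ids).
#' @param records named list of the corresponding `subject_record`s.
#' @return A data frame (rownames = subject ids) with the fitted-parameter
#'   columns and `G_max`.
#' @export
parameter_table <- function(fits, records) {
  stopifnot(length(fits) == length(records))
  cols <- c("V_1", "V_ii", "V_h", "K_id", "k_degI", "k_degE", "k_in",
            "K1_prime", "b_G", "V_id")
  rows <- lapply(seq_along(fits), function(i) {
    th <- fits[[i]]$theta_hat
    v <- vapply(cols, function(nm) th[[nm]], numeric(1))
    c(v, G_max = gmax(records[[i]]))
  })
  tab <- as.data.frame(do.call(rbind, rows))
  rownames(tab) <- if (!is.null(names(fits))) names(fits) else
    vapply(records, function(r) r$subject_id, character(1))
  tab
}

#' Before/after cohort comparison
#'
#' Per parameter: before/after means and SDs, the exact two-sided Wilcoxon
#' signed-rank p-value over the paired per-subject values, and the BH FDR
#' adjustment across all columns jointly. The receptor change Delta is
#' reported in two ways: the mean (and SD) of per-subject Delta values, and
#' the Delta of the cohort-mean apparent dissociation constants.
#'
#' @param before,after aligned data frames from [parameter_table()]
#'   (identical subject rownames and column sets).
#' @return An object of class `cohort_summary`: list with `comparison`
#'   (data frame: parameter, before/after mean and SD, `p`, `fdr`) and
#'   `delta` (list `av_delta`, `sd_delta`, `delta_of_means`).
#' @export
summarize_cohort <- function(before, after) {
  if (!identical(sort(rownames(before)), sort(rownames(after))) ||
      !identical(sort(colnames(before)), sort(colnames(after))))
    stop("before/after tables are not aligned (subjects or columns differ)",
         call. = FALSE)
  after <- after[rownames(before), colnames(before), drop = FALSE]
  cols <- colnames(before)
  p <- vapply(cols, function(nm) wilcoxon_exact(before[[nm]], after[[nm]]),
              numeric(1))
  comparison <- data.frame(
    parameter = cols,
    before_mean = vapply(cols, function(nm) mean(before[[nm]]), numeric(1)),
    before_sd = vapply(cols, function(nm) sd(before[[nm]]), numeric(1)),
    after_mean = vapply(cols, function(nm) mean(after[[nm]]), numeric(1)),
    after_sd = vapply(cols, function(nm) sd(after[[nm]]), numeric(1)),
    p = p,
    fdr = bh_adjust(p),
    row.names = NULL)
  delta <- NULL
  if ("K1_prime" %in% cols) {
    ds <- delta_receptor(before[["K1_prime"]], after[["K1_prime"]])
    delta <- list(av_delta = mean(ds), sd_delta = sd(ds),
                  delta_of_means = delta_receptor(mean(before[["K1_prime"]]),
                                                  mean(after[["K1_prime"]])))
  }
  structure(list(comparison = comparison, delta = delta),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, digits = 3, ...) {
  tab <- x$comparison
  for (nm in c("before_mean", "before_sd", "after_mean", "after_sd", "p", "fdr"))
    tab[[nm]] <- signif(tab[[nm]], digits)
  print(tab, row.names = FALSE)
  if (!is.null(x$delta))
    cat(sprintf("\nReceptor change: AV(Delta) = %.2f +/- %.2f; Delta of cohort means = %.2f\n",
                x$delta$av_delta, x$delta$sd_delta, x$delta$delta_of_means))
  invisible(x)
}
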