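# Between-arm comparison of accumulated burden.
#
# The comparison statistic is the difference in arm-level cumulative AUCs.
# Significance is assessed by a two-sided label-permutation test: arm labels
# are shuffled over patients, both arm AUCs (including the per-week risk
# sets) are recomputed for every shuffle, and the add-one-corrected p-value
# p = (1 + #{|diff_perm| >= |diff_obs|}) / (1 + n_permutations) is reported.
# Permutation is used because the burden AUC is the comparison statistic of
# the method itself and per-patient burdens are highly skewed; no
# distributional assumption is made. A Wilcoxon rank-sum test on per-patient
# AUCs is available as a sensitivity option.

# Dense per-patient matrices used by the permutation loop:
#   B[i, w] = burden of patient i in week w (0 off risk),
#   R[i, w] = TRUE if patient i is at risk in week w.
patient_week_matrices <- function(episodes, patients, grid, weights = NULL,
                                  term_filter = NULL) {
  patients <- patient_records(patients)
  if (is.null(grid)) grid <- study_week_grid(patients)
  weights <- weight_map(weights)
  n <- nrow(patients)
  W <- grid$n_weeks
  B <- matrix(0, nrow = n, ncol = W, dimnames = list(patients$patient_id, NULL))
  tw <- term_week_grades(episodes, grid, term_filter)
  if (nrow(tw) > 0) {
    contribution <- weight_for(tw$term, weights) * tw$grade
    i <- match(tw$patient_id, patients$patient_id)
    if (anyNA(i)) {
      validation_error("episode(s) reference unknown patient_id(s)")
    }
    cell <- (tw$week - 1L) * n + i
    add <- tapply(contribution, cell, sum)
    B[as.integer(names(add))] <- as.numeric(add)
  }
  first_day <- (seq_len(W) - 1L) * grid$week_length + 1L
  R <- outer(patients$last_study_day, first_day, `>=`)
  list(B = B, R = R, patients = patients, grid = grid)
}

# Arm AUC for a logical membership vector over the precomputed matrices.
auc_from_matrices <- function(B, R, member, min_risk_set = 0L) {
  tot <- colSums(B[member, , drop = FALSE])
  nar <- colSums(R[member, , drop = FALSE])
  keep <- nar > 0 & nar >= min_risk_set
  sum(tot[keep] / nar[keep])
}

#' Compare the accumulated burden of two treatment arms
#'
#' Computes the cumulative burden AUC of each arm and a two-sided
#' label-permutation p-value for the difference (see Details in the package
#' vignette). The risk sets are recomputed for every permuted labelling, so
#' differential dropout is part of the resampled statistic.
#'
#' @inheritParams burden_matrix
#' @param n_permutations Number of label permutations, at least 99.
#' @param seed Integer seed; required, so that every reported p-value is
#'   reproducible. The caller's RNG state is restored on exit.
#' @param method `"permutation"` (default) or `"wilcoxon"` (rank-sum test on
#'   per-patient AUCs, a distribution-free sensitivity check that ignores
#'   risk-set weighting).
#' @param min_risk_set Minimum weekly risk-set size; weeks below it
#'   contribute 0 to the AUC (default 0, keep all weeks).
#' @return An object of class `both_comparison`: a list with elements
#'   `arms`, `auc` (named length-2), `observed_diff` (first arm minus
#'   second, arms in lexicographic order), `p_value`, `n_permutations`,
#'   `seed`, `method`, `term_filter`, `n_patients`.
#' @export
compare_arms <- function(patients, episodes, grid = NULL, weights = NULL,
                         term_filter = NULL, n_permutations = 9999L,
                         seed, method = c("permutation", "wilcoxon"),
                         min_risk_set = 0L) {
  method <- match.arg(method)
  if (missing(seed) || is.null(seed)) {
    config_error("seed is required for the resampling comparison")
  }
  patients <- patient_records(patients, require_two_arms = TRUE)
  n_permutations <- as_integerish(n_permutations)
  if (method == "permutation" && (is.na(n_permutations) || n_permutations < 99L)) {
    config_error("n_permutations must be at least 99")
  }
  arms <- sort(unique(patients$arm))
  if (min(table(patients$arm)) < 2L) {
    validation_error("each arm needs at least 2 patients")
  }
  m <- patient_week_matrices(episodes, patients, grid, weights, term_filter)
  member_a <- patients$arm == arms[1]
  auc_a <- auc_from_matrices(m$B, m$R, member_a, min_risk_set)
  auc_b <- auc_from_matrices(m$B, m$R, !member_a, min_risk_set)
  observed <- auc_a - auc_b

  all_zero <- all(m$B == 0)
  p_value <- NA_real_
  if (method == "permutation") {
    if (all_zero) {
      warn("all burden scores are zero in both arms; p-value set to 1")
      p_value <- 1
    } else {
      old_seed <- get0(".Random.seed", envir = globalenv())
      on.exit({
        if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
      }, add = TRUE)
      set.seed(as.integer(seed))
      obs_abs <- abs(observed)
      n <- length(member_a)
      hits <- 0L
      # permute the label vector itself: the same RNG draws are used
      # whichever arm is named first, so the p-value is exactly invariant
      # to swapping the two arm labels
      for (i in seq_len(n_permutations)) {
        z <- member_a[sample.int(n)]
        d <- auc_from_matrices(m$B, m$R, z, min_risk_set) -
          auc_from_matrices(m$B, m$R, !z, min_risk_set)
        if (abs(d) >= obs_abs - 1e-12) hits <- hits + 1L
      }
      p_value <- (1 + hits) / (1 + n_permutations)
    }
  } else {
    pa <- per_patient_auc(episodes, patients, m$grid, weights, term_filter)
    if (all_zero) {
      warn("all burden scores are zero in both arms; p-value set to 1")
      p_value <- 1
    } else {
      p_value <- wilcox.test(
        pa$auc[pa$arm == arms[1]], pa$auc[pa$arm == arms[2]],
        exact = FALSE
      )$p.value
    }
    n_permutations <- NA_integer_
  }

  structure(
    list(
      arms = arms,
      auc = setNames(c(auc_a, auc_b), arms),
      observed_diff = observed,
      p_value = p_value,
      n_permutations = n_permutations,
      seed = as.integer(seed),
      method = method,
      term_filter = term_filter,
      n_patients = setNames(
        c(sum(member_a), sum(!member_a)), arms
      )
    ),
    class = "both_comparison"
  )
}

#' @export
print.both_comparison <- function(x, ...) {
  filt <- if (is.null(x$term_filter)) "all terms" else {
    paste0("terms: ", paste(x$term_filter, collapse = ", "))
  }
  cat("Burden-of-therapy arm comparison (", filt, ")\n", sep = "")
  cat(sprintf("  %s: AUC = %.4f (n = %d)\n",
              x$arms[1], x$auc[1], x$n_patients[1]))
  cat(sprintf("  %s: AUC = %.4f (n = %d)\n",
              x$arms[2], x$auc[2], x$n_patients[2]))
  cat(sprintf("  difference (%s - %s) = %.4f\n",
              x$arms[1], x$arms[2], x$observed_diff))
  if (x$method == "permutation") {
    cat(sprintf("  two-sided permutation p = %.4f (%d permutations, seed %d)\n",
                x$p_value, x$n_permutations, x$seed))
  } else {
    cat(sprintf("  Wilcoxon rank-sum on per-patient AUCs: p = %.4f\n",
                x$p_value))
  }
  invisible(x)
}

#' One-row tidy summary of a comparison
#'
#' @param x A `both_comparison`.
#' @return A one-row tibble.
#' @export
tidy_comparison <- function(x) {
  stopifnot(inherits(x, "both_comparison"))
  tibble::tibble(
    term = if (is.null(x$term_filter)) "overall" else {
      paste(x$term_filter, collapse = "+")
    },
    arm_a = x$arms[1],
    arm_b = x$arms[2],
    auc_a = unname(x$auc[1]),
    auc_b = unname(x$auc[2]),
    observed_diff = x$observed_diff,
    p_value = x$p_value,
    method = x$method,
    n_permutations = x$n_permutations,
    seed = x$seed
  )
}

#' Per-term burden comparison report
#'
#' Runs [compare_arms()] once per adverse-event term plus one overall
#' (unfiltered) comparison. Per-term p-values are unadjusted by default;
#' Holm adjustment can be requested and is flagged in the output.
#'
#' @inheritParams compare_arms
#' @param terms Character vector of terms to report (normalized with
#'   [normalize_term()]); a term matching no episodes yields both AUCs 0 and
#'   a warning.
#' @param adjust `"none"` (default) or `"holm"`; applied to the per-term
#'   p-values only (the overall row is not part of the family).
#' @return A tibble with one row per term plus an `"overall"` row, columns
#'   as in [tidy_comparison()] plus `p_adjusted` and `adjust_method`. The
#'   underlying `both_comparison` objects are attached as attribute
#'   `"comparisons"`.
#' @export
term_report <- function(patients, episodes, grid = NULL, weights = NULL,
                        terms, n_permutations = 999L, seed,
                        method = c("permutation", "wilcoxon"),
                        adjust = c("none", "holm"), min_risk_set = 0L) {
  adjust <- match.arg(adjust)
  method <- match.arg(method)
  if (missing(seed) || is.null(seed)) {
    config_error("seed is required for the resampling comparison")
  }
  terms <- normalize_term(terms)
  if (length(terms) == 0) config_error("terms must be non-empty")
  eps <- ae_episodes(episodes)
  comparisons <- vector("list", length(terms) + 1L)
  rows <- vector("list", length(terms) + 1L)
  for (i in seq_along(terms)) {
    if (!terms[i] %in% eps$term) {
      warn(sprintf("term '%s' matches no episodes; both AUCs are 0", terms[i]))
    }
    cmp <- compare_arms(
      patients, eps, grid = grid, weights = weights,
      term_filter = terms[i], n_permutations = n_permutations,
      seed = as.integer(seed) + i, method = method,
      min_risk_set = min_risk_set
    )
    comparisons[[i]] <- cmp
    rows[[i]] <- tidy_comparison(cmp)
  }
  overall <- compare_arms(
    patients, eps, grid = grid, weights = weights, term_filter = NULL,
    n_permutations = n_permutations, seed = as.integer(seed),
    method = method, min_risk_set = min_risk_set
  )
  comparisons[[length(terms) + 1L]] <- overall
  rows[[length(terms) + 1L]] <- tidy_comparison(overall)

  out <- dplyr::bind_rows(rows)
  p_term <- out$p_value[seq_along(terms)]
  out$p_adjusted <- c(
    if (adjust == "holm") p.adjust(p_term, method = "holm") else p_term,
    out$p_value[length(terms) + 1L]
  )
  out$adjust_method <- adjust
  attr(out, "comparisons") <- comparisons
  out
}
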