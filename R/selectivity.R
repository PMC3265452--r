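# Cross-receptor comparison: fold selectivity and rank-order potency
# correlation between the mosquito receptor and its human counterpart.

#' Fold selectivity from paired potencies
#'
#' For each compound with uncensored IC50s at both receptors,
#' `fold_selectivity = ic50_reference / ic50_target`, so values above 1
#' mean the compound is more potent at the target (mosquito) receptor
#' than at the reference (human) receptor. Censored inputs are flagged
#' not-computable rather than ratioed.
#'
#' @param pairs Tibble with columns `compound_id`, `ic50_target_M`,
#'   `ic50_reference_M`, and optional logical `censored_target` /
#'   `censored_reference`.
#' @return The input with `fold_selectivity` (machine precision),
#'   `fold_selectivity_report` (2 significant figures), and `computable`.
#' @export
compute_fold_selectivity <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("compound_id", "ic50_target_M", "ic50_reference_M") %in% names(pairs)))
  cen_t <- if ("censored_target" %in% names(pairs)) pairs$censored_target else FALSE
  cen_r <- if ("censored_reference" %in% names(pairs)) pairs$censored_reference else FALSE
  computable <- !cen_t & !cen_r &
    is.finite(pairs$ic50_target_M) & is.finite(pairs$ic50_reference_M) &
    pairs$ic50_target_M > 0 & pairs$ic50_reference_M > 0
  fold <- ifelse(computable, pairs$ic50_reference_M / pairs$ic50_target_M, NA_real_)
  pairs$fold_selectivity <- fold
  pairs$fold_selectivity_report <- signif(fold, 2)
  pairs$computable <- computable
  pairs
}

#' Tie-aware rank-order potency correlation
#'
#' Spearman correlation computed explicitly as the Pearson correlation of
#' mid-ranks (ties receive average ranks), squared to an R-squared, with
#' a permutation p-value for the two-sided test of no monotone
#' association. The permutation is exhaustive up to `n <= 7` pairs and
#' Monte-Carlo (on one margin) beyond that.
#'
#' @param x,y Paired potencies (>= 4 complete pairs required). Any
#'   strictly monotone transform of either vector leaves the result
#'   unchanged.
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param seed Seed for the Monte-Carlo permutation draw.
#' @return A list with `rho` (mid-rank Pearson correlation),
#'   `r_squared`, `p_value`, `n`, and `method`.
#' @export
rank_order_correlation <- function(x, y, n_perm = 10000, seed = 1L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  if (n <= 7) {
    perms <- permutations_of(n)
    stats_all <- apply(perms, 1, function(p) abs(stats::cor(rx, ry[p])))
    p_val <- mean(stats_all >= abs(rho) - 1e-12)
    method <- "exhaustive permutation"
  } else {
    p_val <- with_seed(seed, {
      hits <- sum(vapply(seq_len(n_perm), function(i) {
        abs(stats::cor(rx, sample(ry))) >= abs(rho) - 1e-12
      }, logical(1)))
      (hits + 1) / (n_perm + 1)  # add-one so p is never exactly 0
    })
    method <- sprintf("Monte-Carlo permutation (%d draws)", n_perm)
  }
  list(rho = rho, r_squared = rho^2, p_value = p_val, n = n, method = method)
}

# All permutations of 1..n (used for exhaustive permutation tests; n <= 7).
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (j in seq_len(nrow(sub))) {
      out[r, ] <- c(i, rest[sub[j, ]])
      r <- r + 1L
    }
  }
  out
}

#' Selectivity analysis of paired potency estimates
#'
#' Convenience wrapper joining two [summarize_experiments()] tables on
#' `compound_id`, computing fold selectivity per compound and the
#' rank-order correlation of uncensored potencies.
#'
#' @param target,reference Potency-estimate tibbles for the target and
#'   reference receptors.
#' @return A list with `records` (fold-selectivity table) and
#'   `correlation` ([rank_order_correlation()] result, or `NULL` when
#'   fewer than 4 computable pairs exist).
#' @export
selectivity_analysis <- function(target, reference) {
  pairs <- dplyr::inner_join(
    tibble::tibble(compound_id = target$compound_id,
                   ic50_target_M = target$potency_M,
                   censored_target = target$censored),
    tibble::tibble(compound_id = reference$compound_id,
                   ic50_reference_M = reference$potency_M,
                   censored_reference = reference$censored),
    by = "compound_id")
  records <- compute_fold_selectivity(pairs)
  ok <- records$computable
  corr <- if (sum(ok) >= 4) {
    rank_order_correlation(records$ic50_target_M[ok], records$ic50_reference_M[ok])
  }
  list(records = records, correlation = corr)
}
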