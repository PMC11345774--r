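#' ROC analysis of a labeled ranked screen
#'
#' Computes the area under the ROC curve by the rank-sum (Mann-Whitney)
#' estimator with ties contributing 1/2, the threshold-sweep ROC curve, and
#' enrichment factors at the requested list fractions. The AUC equals the
#' probability that a randomly chosen active outranks a randomly chosen
#' decoy.
#'
#' @param screen a data.frame with columns `score` and `label`
#'   (`"active"`/`"decoy"`; other labels are ignored), or a `ranked_screen`.
#' @param ef_fractions list fractions at which to report enrichment factors.
#' @param hit_threshold score above which an entry counts as a hit for the
#'   sensitivity / false-positive summary.
#' @return a `roc_result` list: `auc`, `auc_rounded` (two decimals), `curve`
#'   (fpr/tpr data.frame), `ef` (named vector), `sensitivity_at_threshold`,
#'   `n_hits`, `n_fp`.
#' @export
roc_validation <- function(screen, ef_fractions = c(0.01, 0.05), hit_threshold = 0) {
  stopifnot(all(c("score", "label") %in% names(screen)))
  keep <- screen$label %in% c("active", "decoy")
  score <- screen$score[keep]
  is_act <- screen$label[keep] == "active"
  nA <- sum(is_act); nD <- sum(!is_act)
  if (nA == 0L || nD == 0L)
    stop("ROC needs at least one active and one decoy")
  r <- rank(score, ties.method = "average")
  auc <- (sum(r[is_act]) - nA * (nA + 1) / 2) / (nA * nD)

  ord <- order(-score)
  tp <- cumsum(is_act[ord]); fp <- cumsum(!is_act[ord])
  curve <- data.frame(fpr = c(0, fp / nD), tpr = c(0, tp / nA))
  n <- nA + nD
  ef <- vapply(ef_fractions, function(f) {
    top <- max(1L, ceiling(f * n))
    (tp[top] / top) / (nA / n)
  }, 0)
  names(ef) <- paste0("EF", ef_fractions * 100)

  n_hits <- sum(score > hit_threshold)
  n_recovered <- sum(score > hit_threshold & is_act)
  structure(list(auc = auc, auc_rounded = round(auc, 2), curve = curve, ef = ef,
                 sensitivity_at_threshold = n_recovered / nA,
                 n_hits = n_hits, n_fp = n_hits - n_recovered),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC %.4f (%.2f), %d hits / %d FP, EF: %s>\n",
              x$auc, x$auc_rounded, x$n_hits, x$n_fp,
              paste(sprintf("%s=%.1f", names(x$ef), x$ef), collapse = ", ")))
  invisible(x)
}

#' Sensitivity and false positives from recovery counts
#'
#' @param n_recovered actives retrieved among the hits.
#' @param n_actives total actives screened.
#' @param n_hits total hits retrieved.
#' @return list with `sensitivity_pct` (rounded to the nearest whole
#'   percent), `sensitivity` (exact fraction) and `n_fp`.
#' @export
confusion_stats <- function(n_recovered, n_actives, n_hits) {
  if (n_recovered > n_actives) stop("n_recovered exceeds n_actives")
  if (n_recovered > n_hits) stop("n_recovered exceeds n_hits")
  if (n_actives < 1) stop("n_actives must be positive")
  sens <- n_recovered / n_actives
  list(sensitivity_pct = round(100 * sens), sensitivity = sens,
       n_fp = n_hits - n_recovered)
}

#' Exact AUC of a partially specified rank list
#'
#' Materializes the full active/decoy label vector implied by a
#' [partial_rank_list] and returns its exact rank-sum AUC. On a tie-free
#' ranked list this equals the trapezoidal area under the ROC curve.
#'
#' @param p a [partial_rank_list].
#' @return list with `auc` (exact), `auc_rounded` (two decimals) and
#'   `labels` (the materialized vector).
#' @export
auc_from_partial_ranks <- function(p) {
  lab <- materialize_labels(p)
  n <- length(lab)
  # rank 1 = best; score = n - rank so the rank-sum estimator applies directly
  screen <- data.frame(score = n - seq_len(n), label = lab)
  r <- roc_validation(screen)
  list(auc = r$auc, auc_rounded = r$auc_rounded, labels = lab)
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' `Ki = IC50 / (1 + L / Kd)` for a competition binding assay with
#' radioligand concentration `L` and radioligand dissociation constant `Kd`.
#'
#' @param ic50 measured IC50 (nM).
#' @param radioligand_conc radioligand concentration L (nM), >= 0.
#' @param kd radioligand Kd (nM), > 0.
#' @return Ki in nM.
#' @export
cheng_prusoff <- function(ic50, radioligand_conc, kd) {
  if (any(ic50 <= 0)) stop("ic50 must be positive")
  if (any(radioligand_conc < 0)) stop("radioligand concentration must be >= 0")
  if (any(kd <= 0)) stop("kd must be positive")
  ic50 / (1 + radioligand_conc / kd)
}

#' Screened library composition accounting
#'
#' The seven screened component libraries with their compound counts: three
#' natural-product collections and four synthetic collections. Shares are
#' recomputed from the counts; the stored printed shares are retained for
#' comparison, and the synthetic share as printed (98.46%) is flagged as
#' inconsistent with the table's own counts.
#'
#' @return data.frame with columns `library`, `category`, `n_molecules`.
#' @export
library_composition <- function() {
  data.frame(
    library = c("NATx (Analyticon)", "MEGx (Analyticon)",
                "Natural product library (Selleckchem)",
                "Advanced Collection (Enamine)", "Functional Collection (Enamine)",
                "HTS Collection (Enamine)", "Premium Collection (Enamine)"),
    category = c(rep("natural_product", 3L), rep("synthetic", 4L)),
    n_molecules = c(33717L, 6541L, 2724L, 640219L, 119088L, 2146100L, 41281L)
  )
}

#' @rdname library_composition
#' @param printed_np_share,printed_syn_share the shares as printed alongside
#'   the table, for the consistency check.
#' @return for `library_shares`: list with `total`, `np_share_pct`,
#'   `syn_share_pct` (both recomputed and rounded to two decimals) and
#'   `printed_syn_share_consistent` (FALSE: the printed synthetic share does
#'   not match the table's own counts).
#' @export
library_shares <- function(printed_np_share = 1.44, printed_syn_share = 98.46) {
  comp <- library_composition()
  total <- sum(comp$n_molecules)
  np <- sum(comp$n_molecules[comp$category == "natural_product"])
  np_pct <- round(100 * np / total, 2)
  syn_pct <- round(100 * (total - np) / total, 2)
  list(total = total, np_share_pct = np_pct, syn_share_pct = syn_pct,
       printed_np_share_consistent = isTRUE(all.equal(np_pct, printed_np_share)),
       printed_syn_share_consistent = isTRUE(all.equal(syn_pct, printed_syn_share)))
}
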