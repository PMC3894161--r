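#' Mean squared error of log substitution rates
#'
#' \eqn{(1/N) \sum_i (\log \rho_i - \log \hat\rho_i)^2}.  Working on the log
#' scale emphasizes differences between low rates, which is where
#' conservation signal lives.
#'
#' @param true_rates positive numeric vector (or a [block_rate_field()]).
#' @param est_rates positive numeric vector of the same length.
#' @return The mean squared log-rate error (>= 0).
#' @export
log_rate_loss <- function(true_rates, est_rates) {
  if (inherits(true_rates, "rate_field")) true_rates <- true_rates$rates
  if (length(true_rates) != length(est_rates))
    stop("length mismatch between true and estimated rates")
  if (any(true_rates <= 0) || any(est_rates <= 0))
    stop("rates must be positive")
  mean((log(true_rates) - log(est_rates))^2)
}

#' ROC curve for functional-site detection
#'
#' Sites are ranked by estimated substitution rate, ascending: a low rate
#' predicts a functional site.  Ties are handled by grouping equal scores,
#' so the trapezoidal AUC equals the tie-corrected Mann-Whitney statistic
#' P(score_pos < score_neg) + 0.5 P(equal).
#'
#' @param mask logical vector, `TRUE` for truly functional (positive) sites.
#' @param scores per-site estimated rates (or any score).
#' @param positives_are_low if `TRUE` (default) low scores predict
#'   positives.
#' @return A list with `points` (data.frame of `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(mask, scores, positives_are_low = TRUE) {
  mask <- as.logical(mask)
  if (length(mask) != length(scores)) stop("length mismatch")
  n_pos <- sum(mask); n_neg <- sum(!mask)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC undefined: 'mask' must contain both classes")
  s <- if (positives_are_low) scores else -scores
  ord <- order(s)
  s <- s[ord]; m <- mask[ord]
  # group ties so tied sites move along a diagonal segment
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(tapply(m, grp, sum))
  fp <- cumsum(tapply(!m, grp, sum))
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' The k most conserved sites
#'
#' @param est_rates per-site estimated rates.
#' @param k how many sites (<= number of sites).
#' @return Indices of the `k` smallest rates, sorted by rate ascending; ties
#'   are broken deterministically in favor of the smaller site index.
#' @export
top_k_conserved <- function(est_rates, k) {
  if (k > length(est_rates)) stop("'k' exceeds the number of sites")
  if (k < 1) stop("'k' must be at least 1")
  order(est_rates, seq_along(est_rates))[seq_len(k)]
}

#' Replicate-level comparison of two rate estimators
#'
#' Scores matched replicate estimates from two methods against ground
#' truth: per-replicate log-rate losses and AUCs, a paired Wilcoxon
#' signed-rank test on the losses, and a pooled ROC obtained by vertical
#' averaging of the replicate ROC curves on a fixed false-positive-rate
#' grid.
#'
#' @param true_rates list of per-replicate true rate vectors (or
#'   [block_rate_field()]s).
#' @param mask list of per-replicate functional masks (may be omitted when
#'   `true_rates` are rate fields).
#' @param est_a,est_b lists of per-replicate estimated rate vectors.
#' @param labels names of the two methods.
#' @param fpr_grid grid for ROC vertical averaging.
#' @return An object of class `method_comparison`: list with `table` (one
#'   row per replicate), `wilcoxon` (the paired test on losses, or `NULL`
#'   when degenerate), and `mean_roc` per method.
#' @export
compare_methods <- function(true_rates, est_a, est_b, mask = NULL,
                            labels = c("gp", "iid"),
                            fpr_grid = seq(0, 1, by = 0.01)) {
  n <- length(true_rates)
  if (length(est_a) != n || length(est_b) != n)
    stop("methods must score the same replicates")
  if (is.null(mask)) {
    if (!all(vapply(true_rates, inherits, logical(1), "rate_field")))
      stop("'mask' required unless 'true_rates' are rate fields")
    mask <- lapply(true_rates, `[[`, "functional_mask")
  }
  rows <- vector("list", n)
  roc_a <- matrix(NA_real_, n, length(fpr_grid))
  roc_b <- matrix(NA_real_, n, length(fpr_grid))
  for (i in seq_len(n)) {
    tr <- if (inherits(true_rates[[i]], "rate_field"))
      true_rates[[i]]$rates else true_rates[[i]]
    ra <- roc_curve(mask[[i]], est_a[[i]])
    rb <- roc_curve(mask[[i]], est_b[[i]])
    roc_a[i, ] <- approx(ra$points$fpr, ra$points$tpr, xout = fpr_grid,
                         ties = max, rule = 2)$y
    roc_b[i, ] <- approx(rb$points$fpr, rb$points$tpr, xout = fpr_grid,
                         ties = max, rule = 2)$y
    rows[[i]] <- data.frame(replicate = i,
                            loss_a = log_rate_loss(tr, est_a[[i]]),
                            loss_b = log_rate_loss(tr, est_b[[i]]),
                            auc_a = ra$auc, auc_b = rb$auc)
  }
  tab <- do.call(rbind, rows)
  names(tab) <- c("replicate", paste0("loss_", labels), paste0("auc_", labels))
  d <- tab[[2]] - tab[[3]]
  wil <- if (all(d == 0)) NULL else
    suppressWarnings(wilcox.test(tab[[2]], tab[[3]], paired = TRUE))
  structure(list(table = tab, wilcoxon = wil, labels = labels,
                 mean_roc = data.frame(fpr = fpr_grid,
                                       tpr_a = colMeans(roc_a),
                                       tpr_b = colMeans(roc_b))),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  la <- x$labels[1]; lb <- x$labels[2]
  cat("Method comparison over ", nrow(x$table), " replicates\n", sep = "")
  cat(sprintf("  median loss: %s = %.4g, %s = %.4g\n", la,
              median(x$table[[2]]), lb, median(x$table[[3]])))
  cat(sprintf("  mean AUC:    %s = %.4g, %s = %.4g\n", la,
              mean(x$table[[4]]), lb, mean(x$table[[5]])))
  if (is.null(x$wilcoxon)) {
    cat("  paired Wilcoxon: degenerate (all loss differences are zero)\n")
  } else {
    cat(sprintf("  paired Wilcoxon on losses: V = %g, p = %.3g\n",
                x$wilcoxon$statistic, x$wilcoxon$p.value))
  }
  invisible(x)
}
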