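# reshape one index of the long study table into a blocks x treatments
# matrix (subjects x levels of `across`), fixing `within` at one level
study_matrix <- function(study, index, across, rows = "subject") {
  sub <- study[study$index == index, , drop = FALSE]
  subjects <- sort(unique(sub$subject))
  levels_ <- if (across == "condition") sort(unique(sub$condition))
             else angle_columns()[angle_columns() %in% unique(sub$angle)]
  m <- matrix(NA_real_, length(subjects), length(levels_),
              dimnames = list(subjects, levels_))
  for (i in seq_len(nrow(sub)))
    m[as.character(sub$subject[i]), as.character(sub[[across]][i])] <-
      if (is.na(m[as.character(sub$subject[i]),
                  as.character(sub[[across]][i])]))
        sub$value[i] else NA_real_ # duplicate cell -> poison with NA
  m
}

check_crossing <- function(study) {
  need <- c("subject", "condition", "angle", "index", "value")
  miss <- setdiff(need, names(study))
  if (length(miss))
    np_stop("napscope_design_error", "study table misses column(s): %s",
            paste(miss, collapse = ", "))
  counts <- table(study$subject, study$condition, study$angle, study$index)
  if (any(counts != 1))
    np_stop("napscope_design_error",
            "incomplete design: need exactly one value per subject x condition x angle x index cell")
  invisible(study)
}

pairwise_wilcoxon <- function(mat, scope, index, fixed, alpha) {
  cols <- colnames(mat)
  pairs <- utils::combn(cols, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    res <- tryCatch(wilcoxon_signed_rank(mat[, a], mat[, b]),
                    napscope_data_error = function(e) NULL)
    data.frame(scope = scope, index = index, fixed = fixed,
               comparison = paste(a, "vs", b),
               statistic = if (is.null(res)) NA_real_ else res$w_plus,
               z = if (is.null(res)) NA_real_ else res$z,
               p = if (is.null(res)) NA_real_ else res$p,
               effect_r = if (is.null(res)) NA_real_ else res$r,
               note = if (is.null(res)) "all_differences_zero" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- bonferroni(out$p[ok])
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  # effect sizes are reported for significant comparisons only
  out$effect_r[!out$significant] <- NA_real_
  out
}

#' Condition-comparison analysis of a movement-index study
#'
#' Runs the full nonparametric repeated-measures design on a long study
#' table (columns `subject`, `condition`, `angle`, `index`, `value`):
#' for each index, (a) a per-angle Friedman test across conditions and
#' (b) a per-condition Friedman test across angles; (c) Bonferroni-corrected
#' Wilcoxon signed-rank post hocs wherever an omnibus test is significant
#' (family = the pairwise comparisons within that omnibus: all condition
#' pairs, or all angle pairs); and (d) Spearman correlations of body weight
#' against the per-angle index within each condition. Effect sizes
#' (Kendall's W, r) are attached to significant results only.
#'
#' @param study Long data.frame: `subject`, `condition`, `angle`, `index`,
#'   `value`, one value per cell of the full crossing.
#' @param weights Optional data.frame (`subject`, `body_weight`) or named
#'   vector of body weights.
#' @param alpha Significance level (default 0.050).
#' @return list of class `analysis_report`: data.frames `omnibus`,
#'   `posthoc`, `correlations`, plus `alpha`.
#' @export
condition_comparison <- function(study, weights = NULL, alpha = 0.050) {
  check_crossing(study)
  if (is.data.frame(weights))
    weights <- stats::setNames(weights$body_weight, weights$subject)
  omnibus <- list(); posthoc <- list(); corrs <- list()
  for (idx in unique(study$index)) {
    sub <- study[study$index == idx, , drop = FALSE]
    # (a) across conditions, separately per angle
    for (a in intersect(angle_columns(), unique(sub$angle))) {
      m <- study_matrix(sub[sub$angle == a, , drop = FALSE], idx, "condition")
      fr <- friedman_w(m)
      sig <- fr$p < alpha
      omnibus[[length(omnibus) + 1]] <- data.frame(
        scope = "conditions_within_angle", index = idx, fixed = a,
        statistic = fr$chi2, df = fr$df, p = fr$p,
        effect_W = if (sig) fr$W else NA_real_, significant = sig,
        stringsAsFactors = FALSE)
      if (sig)
        posthoc[[length(posthoc) + 1]] <-
          pairwise_wilcoxon(m, "conditions_within_angle", idx, a, alpha)
    }
    # (b) across angles, separately per condition
    for (cond in sort(unique(sub$condition))) {
      m <- study_matrix(sub[sub$condition == cond, , drop = FALSE], idx,
                        "angle")
      fr <- friedman_w(m)
      sig <- fr$p < alpha
      omnibus[[length(omnibus) + 1]] <- data.frame(
        scope = "angles_within_condition", index = idx, fixed = cond,
        statistic = fr$chi2, df = fr$df, p = fr$p,
        effect_W = if (sig) fr$W else NA_real_, significant = sig,
        stringsAsFactors = FALSE)
      if (sig)
        posthoc[[length(posthoc) + 1]] <-
          pairwise_wilcoxon(m, "angles_within_condition", idx, cond, alpha)
    }
    # (d) body weight vs index, per condition and angle
    if (!is.null(weights)) {
      for (cond in sort(unique(sub$condition))) {
        for (a in intersect(angle_columns(), unique(sub$angle))) {
          cell <- sub[sub$condition == cond & sub$angle == a, , drop = FALSE]
          cell <- cell[order(cell$subject), ]
          res <- tryCatch(
            spearman_cor(weights[as.character(cell$subject)], cell$value),
            napscope_data_error = function(e) NULL)
          corrs[[length(corrs) + 1]] <- data.frame(
            index = idx, condition = cond, angle = a,
            rho = if (is.null(res)) NA_real_ else res$rho,
            p = if (is.null(res)) NA_real_ else res$p,
            n = if (is.null(res)) NA_integer_ else res$n,
            significant = if (is.null(res)) FALSE else res$p < alpha,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(
    list(omnibus = do.call(rbind, omnibus),
         posthoc = if (length(posthoc)) do.call(rbind, posthoc) else NULL,
         correlations = if (length(corrs)) do.call(rbind, corrs) else NULL,
         alpha = alpha),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.analysis_report <- function(x, ...) {
  out <- c(sprintf("Condition-comparison report (alpha = %.3f)", x$alpha), "")
  om <- x$omnibus
  for (i in seq_len(nrow(om))) {
    r <- om[i, ]
    out <- c(out, sprintf(
      "%s [%s, %s]: chi2(%d) = %.3f, p = %.3f%s",
      r$scope, r$index, r$fixed, r$df, r$statistic, r$p,
      if (r$significant) sprintf(", W = %.3f *", r$effect_W) else ""))
  }
  if (!is.null(x$posthoc)) {
    sig <- x$posthoc[x$posthoc$significant, , drop = FALSE]
    out <- c(out, "", sprintf("significant post hocs (%d of %d):",
                              nrow(sig), nrow(x$posthoc)))
    for (i in seq_len(nrow(sig))) {
      r <- sig[i, ]
      out <- c(out, sprintf(
        "  %s [%s, %s] %s: z = %.3f, p_adj = %.3f, r = %.2f",
        r$scope, r$index, r$fixed, r$comparison, r$z, r$p_adj, r$effect_r))
    }
  }
  if (!is.null(x$correlations)) {
    sig <- x$correlations[x$correlations$significant, , drop = FALSE]
    out <- c(out, "", sprintf(
      "significant body-weight correlations (%d of %d):",
      nrow(sig), nrow(x$correlations)))
    for (i in seq_len(nrow(sig))) {
      r <- sig[i, ]
      out <- c(out, sprintf("  [%s, %s, %s]: rho = %.3f, p = %.3f",
                            r$index, r$condition, r$angle, r$rho, r$p))
    }
  }
  out
}

#' Write an analysis report to disk
#'
#' Serializes the report as `omnibus.csv`, `posthoc.csv`,
#' `correlations.csv` (when present) and a human-readable `summary.txt`
#' under `dir`.
#'
#' @param report An `analysis_report` from [condition_comparison()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$omnibus, file.path(dir, "omnibus.csv"),
                   row.names = FALSE)
  if (!is.null(report$posthoc))
    utils::write.csv(report$posthoc, file.path(dir, "posthoc.csv"),
                     row.names = FALSE)
  if (!is.null(report$correlations))
    utils::write.csv(report$correlations, file.path(dir, "correlations.csv"),
                     row.names = FALSE)
  writeLines(format(report), file.path(dir, "summary.txt"))
  invisible(dir)
}
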