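#' 2x2 diagnostic contingency table
#'
#' Counts of an index test call (disease / no disease) against the
#' pathological reference standard.
#'
#' @param tp,fp,fn,tn Non-negative integer counts (true positive, false
#'   positive, false negative, true negative); total must be positive.
#' @param label Optional name of the test/sequence (e.g. `"plain"`).
#' @return An object of class `"contingency_table"`.
#' @examples
#' t1 <- contingency_table(tp = 118, fp = 4, fn = 19, tn = 9, label = "plain")
#' sensitivity(t1)
#' @export
contingency_table <- function(tp, fp, fn, tn, label = NA_character_) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) <= 0) stop("table is empty", call. = FALSE)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 label = label),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table>%s  n = %d\n",
              if (is.na(x$label)) "" else paste0(" [", x$label, "]"),
              x$tp + x$fp + x$fn + x$tn))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2,
              dimnames = list(test = c("positive", "negative"),
                              reference = c("positive", "negative")))
  print(m)
  invisible(x)
}

total_n <- function(t) t$tp + t$fp + t$fn + t$tn

#' Sensitivity, specificity and accuracy (as percentages)
#'
#' `sensitivity = 100 * tp / (tp + fn)`,
#' `specificity = 100 * tn / (tn + fp)`,
#' `accuracy = 100 * (tp + tn) / n`.  Returned unrounded; display rounding
#' (half-up, 2 decimals) is applied by the print methods only.
#'
#' @param t A [contingency_table].
#' @return Percentage in `[0, 100]`.
#' @export
sensitivity <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$tp + t$fn <= 0) stop("no reference-positive cases", call. = FALSE)
  100 * t$tp / (t$tp + t$fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$tn + t$fp <= 0) stop("no reference-negative cases", call. = FALSE)
  100 * t$tn / (t$tn + t$fp)
}

#' @rdname sensitivity
#' @export
accuracy <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  100 * (t$tp + t$tn) / total_n(t)
}

#' Cohen's kappa for a 2x2 table
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` with
#' `po = (tp + tn)/n` and
#' `pe = ((tp+fp)(tp+fn) + (fn+tn)(fp+tn)) / n^2`.
#'
#' @param t A [contingency_table].
#' @return Kappa in `[-1, 1]`; degenerate margins (`pe = 1`) raise an error.
#' @export
cohen_kappa <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  n <- total_n(t)
  po <- (t$tp + t$tn) / n
  pe <- ((t$tp + t$fp) * (t$tp + t$fn) +
           (t$fn + t$tn) * (t$fp + t$tn)) / n^2
  if (pe >= 1) stop("kappa undefined: degenerate margins (pe = 1)", call. = FALSE)
  (po - pe) / (1 - pe)
}

kappa_band <- function(kappa) {
  if (kappa >= 0.7) "good" else if (kappa >= 0.4) "acceptable" else "poor"
}

#' Compare two diagnostic tables with Pearson's chi-square
#'
#' Builds the 2x2 cross-sequence table of correct/incorrect calls (for
#' `statistic = "accuracy"`), detected/missed among reference positives
#' (`"sensitivity"`) or correctly excluded/not among reference negatives
#' (`"specificity"`), and returns the Pearson chi-square statistic on 1
#' degree of freedom without continuity correction, computed as
#' `N (ad - bc)^2 / (r1 r2 c1 c2)`.
#'
#' The two sequences are treated as independent samples; a paired
#' (McNemar) alternative is available via [mcnemar_compare()] but is not
#' the default.
#'
#' @param a,b [contingency_table]s.
#' @param statistic Which proportion to compare.
#' @return List with `chi2`, `p`, and the underlying 2x2 `table`.
#' @export
chi_square_compare <- function(a, b,
                               statistic = c("accuracy", "sensitivity",
                                             "specificity")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(a, "contingency_table"), inherits(b, "contingency_table"))
  pick <- function(t) switch(statistic,
    accuracy = c(hit = t$tp + t$tn, miss = t$fp + t$fn),
    sensitivity = c(hit = t$tp, miss = t$fn),
    specificity = c(hit = t$tn, miss = t$fp))
  m <- rbind(pick(a), pick(b))
  rownames(m) <- c(if (is.na(a$label)) "a" else a$label,
                   if (is.na(b$label)) "b" else b$label)
  N <- sum(m)
  rs <- rowSums(m); cs <- colSums(m)
  expected <- outer(rs, cs) / N
  if (any(expected == 0)) {
    stop("zero expected cell; use an exact test instead", call. = FALSE)
  }
  chi2 <- N * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
    (rs[1] * rs[2] * cs[1] * cs[2])
  list(chi2 = unname(chi2),
       p = stats::pchisq(unname(chi2), df = 1, lower.tail = FALSE),
       table = m)
}

#' McNemar's test on discordant pairs
#'
#' Paired alternative to [chi_square_compare()] for two tests applied to
#' the same patients.  Requires the discordant-pair counts, which cannot be
#' recovered from two marginal 2x2 tables; hence it is off by default.
#'
#' @param n01,n10 Discordant counts (test A correct / B wrong, and vice
#'   versa).
#' @param correct Apply the continuity correction.
#' @return List with `chi2` and `p`.
#' @export
mcnemar_compare <- function(n01, n10, correct = FALSE) {
  stopifnot(n01 >= 0, n10 >= 0, n01 + n10 > 0)
  d <- abs(n01 - n10) - if (correct) 1 else 0
  chi2 <- max(d, 0)^2 / (n01 + n10)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Accuracy summary of a contingency table
#'
#' Bundles sensitivity, specificity, accuracy (percentages), Cohen's kappa
#' and its consistency band (`"good"` for kappa >= 0.7, `"acceptable"` for
#' kappa >= 0.4, `"poor"` otherwise).
#'
#' @param t A [contingency_table].
#' @return A list of class `"accuracy_summary"` with unrounded values;
#'   the print method displays percentages rounded half-up to 2 decimals.
#' @export
accuracy_summary <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  k <- cohen_kappa(t)
  structure(list(label = t$label,
                 sensitivity = sensitivity(t),
                 specificity = specificity(t),
                 accuracy = accuracy(t),
                 kappa = k,
                 kappa_band = kappa_band(k),
                 n = total_n(t)),
            class = "accuracy_summary")
}

#' @export
summary.contingency_table <- function(object, ...) accuracy_summary(object)

#' @export
print.accuracy_summary <- function(x, ...) {
  cat(sprintf("<accuracy_summary>%s  n = %d\n",
              if (is.na(x$label)) "" else paste0(" [", x$label, "]"), x$n))
  cat(sprintf("  sensitivity %.2f%%  specificity %.2f%%  accuracy %.2f%%\n",
              round_half_up(x$sensitivity), round_half_up(x$specificity),
              round_half_up(x$accuracy)))
  cat(sprintf("  kappa %.4f (%s consistency)\n", x$kappa, x$kappa_band))
  invisible(x)
}

#' Read contingency tables from a CSV file
#'
#' Expected columns: `sequence, tp, fp, fn, tn`.
#'
#' @param path CSV file path.
#' @return Named list of [contingency_table]s.
#' @export
read_contingency_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sequence", "tp", "fp", "fn", "tn")
  if (!all(need %in% names(df))) {
    stop("CSV must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    contingency_table(df$tp[i], df$fp[i], df$fn[i], df$tn[i],
                      label = df$sequence[i])
  })
  names(out) <- df$sequence
  out
}

#' The shipped MRI-sequence contingency tables
#'
#' The three 2x2 tables of index-test calls (prostate cancer vs benign
#' hyperplasia) against pathology for the plain (T2-weighted) scan, the
#' diffusion-weighted sequence and the dynamic contrast-enhanced sequence,
#' on the same 150 patients (137 cancer, 13 benign).
#'
#' @return Named list of [contingency_table]s (`plain`, `DWI`, `DCE`).
#' @export
mri_sequence_tables <- function() {
  read_contingency_csv(system.file("extdata", "mri_sequence_tables.csv",
                                   package = "rlre", mustWork = TRUE))
}

# Values as printed in the source report for the shipped tables.
printed_reference_values <- function() {
  data.frame(
    sequence = c("plain", "DWI", "DCE"),
    sensitivity = c(86.13, 91.97, 97.08),
    specificity = c(69.23, 76.92, 92.31),
    accuracy = c(84.67, 91.33, 96.67),
    kappa = c(0.469, 0.547, 0.678))
}

#' Discrepancies between printed statistics and the printed cell counts
#'
#' Recomputes every statistic from the shipped contingency tables and
#' compares it with the value printed in the source report.  Two printed
#' quantities are not reproducible from their own tables: the kappa values
#' (printed 0.469 / 0.547 / 0.678 vs formula 0.3637 / 0.5389 / 0.8095) and
#' the DWI accuracy (printed 91.33% vs 136/150 = 90.67%).  This package
#' reports the formula-true values; this function surfaces the mismatches
#' rather than hiding them.
#'
#' @param tolerance Absolute difference above which a value is flagged.
#' @return `data.frame` with one row per (sequence, statistic) holding the
#'   formula value, the printed value, and a `note` for mismatches.
#' @export
diagnostic_discrepancies <- function(tolerance = 0.005) {
  tabs <- mri_sequence_tables()
  ref <- printed_reference_values()
  rows <- list()
  for (i in seq_len(nrow(ref))) {
    t <- tabs[[ref$sequence[i]]]
    comp <- c(sensitivity = sensitivity(t), specificity = specificity(t),
              accuracy = accuracy(t), kappa = cohen_kappa(t))
    prt <- c(sensitivity = ref$sensitivity[i], specificity = ref$specificity[i],
             accuracy = ref$accuracy[i], kappa = ref$kappa[i])
    for (stat in names(comp)) {
      mism <- abs(comp[[stat]] - prt[[stat]]) > tolerance
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = ref$sequence[i], statistic = stat,
        computed = unname(comp[[stat]]), printed = unname(prt[[stat]]),
        note = if (mism) {
          sprintf("printed value %.4g is not reproducible from the printed cells (formula gives %.4g)",
                  prt[[stat]], comp[[stat]])
        } else ""
      )
    }
  }
  do.call(rbind, rows)
}
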