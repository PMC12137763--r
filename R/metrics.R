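#' Bland-Altman agreement between two paired measurement series
#'
#' Differences are oriented first minus second (`a - b`); the orientation is
#' recorded in the labels. Limits of agreement are mean difference +/- 1.96
#' sample standard deviations (n-1 denominator).
#'
#' @param values_a,values_b Paired measurements, equal length >= 2.
#' @param label_a,label_b Provenance labels recorded in the result.
#' @return An object of class `agreement_stats` with `n_pairs`, `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, the labels, and the raw `diffs`.
#' @export
#' @examples
#' bland_altman(c(10, 20, 30), c(12, 18, 33))
bland_altman <- function(values_a, values_b, label_a = "a", label_b = "b") {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) != length(b))
    stop("pairing error: series lengths differ (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  if (length(a) < 2)
    stop("insufficient data: need at least 2 pairs", call. = FALSE)
  d <- a - b
  m <- mean(d)
  s <- sd(d)
  structure(list(n_pairs = length(d), mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 label_a = label_a, label_b = label_b,
                 means = (a + b) / 2, diffs = d),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> %s - %s (n = %d): mean diff %.4f, SD %.4f, LoA [%.4f, %.4f]\n",
              x$label_a, x$label_b, x$n_pairs, x$mean_diff, x$sd_diff,
              x$loa_low, x$loa_high))
  invisible(x)
}

#' Dice overlap coefficient between two masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}. Two empty masks score 1.0 (perfect
#' agreement by convention); one empty mask scores 0.0.
#'
#' @param mask_a,mask_b [organ_mask()] objects or binary arrays of equal
#'   shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  ga <- if (inherits(mask_a, "organ_mask")) mask_a$grid else mask_a
  gb <- if (inherits(mask_b, "organ_mask")) mask_b$grid else mask_b
  if (!identical(dim(ga), dim(gb)))
    stop("masks are misaligned: ", paste(dim(ga), collapse = "x"), " vs ",
         paste(dim(gb), collapse = "x"), call. = FALSE)
  a <- ga >= 0.5; b <- gb >= 0.5
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1.0)
  2 * sum(a & b) / (na + nb)
}

#' Repeat-acquisition consistency report
#'
#' For k repeated acquisitions of the same subject and organ, reports all
#' k(k-1)/2 pairwise mean-T2* differences (oriented earlier minus later),
#' the centile band of every repeat when a normative model store is given,
#' and a stability flag that is true iff all repeats fall in one band.
#'
#' @param summaries List of `organ_summary` objects for the same organ, in
#'   acquisition order (length >= 2).
#' @param models Optional `normative_models` store for band assignment.
#' @return An object of class `consistency_report` with `organ`,
#'   `n_repeats`, `pairwise` (data frame: repeat_a, repeat_b, diff_ms),
#'   `mean_t2star` per repeat, `bands`, and `stable`.
#' @export
repeat_consistency <- function(summaries, models = NULL) {
  if (length(summaries) < 2)
    stop("insufficient data: need at least 2 repeats", call. = FALSE)
  stopifnot(all(vapply(summaries, inherits, TRUE, "organ_summary")))
  organs <- vapply(summaries, `[[`, "", "organ")
  if (length(unique(organs)) != 1)
    stop("all repeats must be of the same organ; got: ",
         paste(unique(organs), collapse = ", "), call. = FALSE)
  k <- length(summaries)
  t2 <- vapply(summaries, `[[`, 0, "mean_t2star")
  pairs <- utils::combn(k, 2)
  pairwise <- data.frame(repeat_a = pairs[1, ], repeat_b = pairs[2, ],
                         diff_ms = t2[pairs[1, ]] - t2[pairs[2, ]])
  bands <- rep(NA_character_, k)
  if (!is.null(models)) {
    key <- paste(organs[1], "mean_t2star", sep = ".")
    model <- models[[key]]
    if (is.null(model))
      stop("no normative model for ", key, call. = FALSE)
    for (i in seq_len(k))
      bands[i] <- classify(model, summaries[[i]]$ga_weeks, t2[i])$band
  }
  stable <- if (all(is.na(bands))) NA else length(unique(bands)) == 1
  structure(list(organ = organs[1], n_repeats = k, mean_t2star = t2,
                 pairwise = pairwise, bands = bands, stable = stable),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("<consistency_report> ", x$organ, ", ", x$n_repeats, " repeats\n",
      sep = "")
  for (i in seq_len(nrow(x$pairwise)))
    cat(sprintf("  repeat %d - repeat %d: %.3f ms\n",
                x$pairwise$repeat_a[i], x$pairwise$repeat_b[i],
                x$pairwise$diff_ms[i]))
  if (!all(is.na(x$bands)))
    cat("  bands: ", paste(x$bands, collapse = ", "),
        if (isTRUE(x$stable)) " (stable)" else " (band change)", "\n",
        sep = "")
  invisible(x)
}
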