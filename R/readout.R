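#' Min-max normalization of a signal vector
#'
#' Maps a vector affinely onto `[0, 1]`: `(v - min) / (max - min)`. This is
#' the normalization applied to fluorescence endpoints for display; raw
#' values are retained everywhere and rounding to two decimals happens only
#' in print methods.
#'
#' @param values numeric vector with `max > min`.
#' @return vector in `[0, 1]`.
#' @export
normalize_signal <- function(values) {
  rng <- range(values)
  if (rng[1] == rng[2]) {
    stop("cannot normalize: max equals min", call. = FALSE)
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Full-scale percent error of a distance factor
#'
#' The module-level error convention: the absolute deviation of the final
#' distance-factor concentration from its ideal value, expressed as a percent
#' of the input range maximum (full scale), not of the ideal value — so a
#' 0.43 nM residual on a 10 nM range is 4.30% even when the ideal value is 0.
#'
#' @param final,ideal concentrations in nM (vectorized).
#' @param range_max input range maximum in nM.
#' @return percent error(s).
#' @export
distance_error <- function(final, ideal, range_max) {
  stopifnot(range_max > 0)
  100 * abs(final - ideal) / range_max
}

#' Call a diagnosis from reporter endpoints
#'
#' Reads the final fluorescent reporter concentrations Y_l from a simulated
#' trajectory, assigns the class with the largest output, and flags the call
#' undetermined when the outputs cannot be normalized (all equal, e.g. a
#' fully symmetric tie), when the normalized top output is below 0.5, or when
#' the top two outputs are within 10% relative of each other.
#'
#' @param result a `crn_sim` of a compiled diagnostic network.
#' @param classes optional class labels per output index l; defaults to the
#'   labels stored in the network metadata.
#' @return object of class `lvq_diagnosis`: list with `y` (final Y_l, nM),
#'   `normalized` (min-max), `predicted`, `margin` (relative gap of the top
#'   two) and `undetermined`.
#' @export
call_diagnosis <- function(result, classes = NULL) {
  stopifnot(inherits(result, "crn_sim"))
  rep_sp <- grep("^FLUOR\\[", result$species, value = TRUE)
  if (!length(rep_sp)) stop("no reporter species in network", call. = FALSE)
  l_idx <- as.integer(sub("^FLUOR\\[l=(\\d+)\\]$", "\\1", rep_sp))
  y <- stats::setNames(result$final[rep_sp][order(l_idx)],
                       paste0("Y_", sort(l_idx)))
  if (is.null(classes)) classes <- result$crn$metadata$classes
  if (is.null(classes)) classes <- paste0("class_", seq_along(y))
  norm <- if (max(y) > min(y)) normalize_signal(y) else
    stats::setNames(rep(NA_real_, length(y)), names(y))
  top <- order(y, decreasing = TRUE)
  rel_gap <- if (y[top[1L]] > 0)
    (y[top[1L]] - y[top[2L]]) / y[top[1L]] else 0
  undetermined <- anyNA(norm) || norm[top[1L]] < 0.5 || rel_gap < 0.1
  structure(list(
    y = y,
    normalized = norm,
    predicted = if (undetermined) NA_character_ else classes[top[1L]],
    margin = rel_gap,
    undetermined = undetermined,
    classes = classes
  ), class = "lvq_diagnosis")
}

#' @export
print.lvq_diagnosis <- function(x, ...) {
  cat("Molecular diagnosis\n")
  cat("  reporter endpoints Y_l (nM):",
      paste(sprintf("%s = %.2f", names(x$y), x$y), collapse = ", "), "\n")
  if (!anyNA(x$normalized)) {
    cat("  normalized:",
        paste(sprintf("%.2f", x$normalized), collapse = ", "), "\n")
  }
  if (x$undetermined) {
    cat("  call: UNDETERMINED (relative gap ",
        sprintf("%.1f%%", 100 * x$margin), ")\n", sep = "")
  } else {
    cat(sprintf("  call: %s (relative gap %.1f%%)\n", x$predicted,
                100 * x$margin))
  }
  invisible(x)
}

#' Confusion-matrix statistics for binary predictions
#'
#' Standard 2-by-2 tallies: accuracy, sensitivity (recall of the positive
#' class) and specificity.
#'
#' @param predictions,labels vectors of equal length over exactly two
#'   classes (labels define the class set; NA predictions count as errors).
#' @param positive which class is "positive"; defaults to the second level.
#' @return list with `table`, `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_stats <- function(predictions, labels, positive = NULL) {
  if (length(predictions) != length(labels)) {
    stop("length mismatch", call. = FALSE)
  }
  labels <- as.factor(labels)   # keep declared levels of factor input
  if (nlevels(labels) != 2L) stop("binary classes required", call. = FALSE)
  predictions <- factor(as.character(predictions), levels = levels(labels))
  if (is.null(positive)) positive <- levels(labels)[2L]
  tab <- table(predicted = predictions, truth = labels, useNA = "no")
  tp <- sum(predictions == positive & labels == positive, na.rm = TRUE)
  tn <- sum(predictions != positive & labels != positive &
              !is.na(predictions))
  acc <- mean(!is.na(predictions) & predictions == labels)
  pos_n <- sum(labels == positive)
  neg_n <- sum(labels != positive)
  list(table = tab,
       accuracy = acc,
       sensitivity = tp / pos_n,
       specificity = tn / neg_n,
       positive = positive)
}
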